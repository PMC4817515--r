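# Dollo-parsimony reconstruction of gene-family gains and losses on a rooted
# strain tree.
#
# Under the Dollo model each family is gained exactly once and may be lost
# repeatedly. Given the observed leaves, the loss-minimizing single-gain
# reconstruction is: gain on the branch into the MRCA of all possessing
# leaves; one loss on the branch into every maximal subtree below the gain
# node that contains no possessing leaf.

#' Clustering thresholds for the gain/loss family set
#'
#' The gain/loss reconstruction conventionally uses a looser family
#' definition than the pan-genome clustering: 50% identity over at least 50%
#' of both protein sequences.
#'
#' @param pid_min,cov_min identity and both-sequence coverage floors.
#' @param e_max E-value ceiling.
#' @return a [similarity_thresholds()] object.
#' @export
gain_loss_thresholds <- function(pid_min = 0.50, cov_min = 0.50, e_max = 1e-4) {
  similarity_thresholds(e_max = e_max, pid_min = pid_min, cov_min = cov_min)
}

# children lookup for a phylo: list indexed by node number
children_list <- function(tree) {
  n_nodes <- max(tree$edge)
  ch <- vector("list", n_nodes)
  for (r in seq_len(nrow(tree$edge))) {
    ch[[tree$edge[r, 1]]] <- c(ch[[tree$edge[r, 1]]], tree$edge[r, 2])
  }
  ch
}

# postorder node sequence (children before parents)
postorder_nodes <- function(tree) {
  ord <- ape::reorder.phylo(tree, "postorder")
  c(ord$edge[, 2][!duplicated(ord$edge[, 2])], length(tree$tip.label) + 1L)
}

#' Dollo-parsimony reconstruction
#'
#' @param tree rooted ape `phylo` whose tips are the matrix's genomes;
#'   internal nodes are labeled `n1..` when unlabeled.
#' @param pa a [pa_matrix()] (families x genomes).
#' @return an object of class `"dollo_reconstruction"`: `gain` (named vector,
#'   family -> name of the node whose incoming branch carries the gain),
#'   `losses` (named list of node names whose incoming branches carry
#'   losses), `presence` (families x node-name logical matrix of inferred
#'   presence at every node), and `tree`.
#' @export
dollo_reconstruct <- function(tree, pa) {
  if (!inherits(tree, "phylo")) stop_param("tree must be a 'phylo' object")
  if (!ape::is.rooted(tree)) {
    stop_param("tree must be rooted; use root_tree() (outgroup or midpoint) first")
  }
  if (!setequal(tree$tip.label, colnames(pa))) {
    stop_input("tree leaf set differs from the matrix genome set")
  }
  if (any(rowSums(pa) == 0)) {
    stop_input("family '%s' is absent from every genome",
               rownames(pa)[rowSums(pa) == 0][1])
  }
  if (is.null(tree$node.label) || !all(nzchar(tree$node.label))) {
    tree$node.label <- sprintf("n%d", seq_len(tree$Nnode))
  }
  ntip <- length(tree$tip.label)
  ch <- children_list(tree)
  post <- postorder_nodes(tree)
  all_names <- c(tree$tip.label, tree$node.label)
  fams <- rownames(pa)
  m <- unclass(pa)[, tree$tip.label, drop = FALSE]

  gain <- character(length(fams))
  losses <- vector("list", length(fams))
  presence <- matrix(FALSE, length(fams), length(all_names),
                     dimnames = list(fams, all_names))

  for (fi in seq_along(fams)) {
    poss <- m[fi, ]
    cnt <- integer(length(all_names))
    cnt[seq_len(ntip)] <- as.integer(poss)
    for (nd in post) {
      if (nd > ntip) cnt[nd] <- sum(cnt[ch[[nd]]])
    }
    total <- cnt[ntip + 1L]
    # descend from the root to the MRCA of possessing leaves
    gn <- ntip + 1L
    repeat {
      if (gn <= ntip) break
      kids <- ch[[gn]]
      carrier <- kids[cnt[kids] == total]
      if (length(carrier) == 1 && cnt[carrier] == total) gn <- carrier else break
    }
    gain[fi] <- all_names[gn]
    # losses: maximal empty subtrees below the gain node; presence elsewhere
    loss_nodes <- character(0)
    stack <- gn
    while (length(stack)) {
      nd <- stack[1]
      stack <- stack[-1]
      presence[fi, nd] <- TRUE
      if (nd > ntip) {
        for (k in ch[[nd]]) {
          if (cnt[k] == 0) loss_nodes <- c(loss_nodes, all_names[k])
          else stack <- c(stack, k)
        }
      }
    }
    losses[[fi]] <- loss_nodes
  }
  names(gain) <- fams
  names(losses) <- fams
  structure(list(gain = gain, losses = losses, presence = presence,
                 tree = tree),
            class = "dollo_reconstruction")
}

#' @export
print.dollo_reconstruction <- function(x, ...) {
  cat(sprintf("<dollo_reconstruction> %d families on %d leaves; total losses %d\n",
              length(x$gain), length(x$tree$tip.label),
              sum(lengths(x$losses))))
  invisible(x)
}

#' Per-node acquisition/inheritance summary, overall and per functional label
#'
#' For every node: families acquired on the branch into the node, families
#' inherited from the parent (present at the parent and not lost), and their
#' sum, the families present at the node. With labels, acquired counts are
#' additionally broken down per label (family labels by majority vote of
#' member genes; ties count as `"ambiguous"`).
#'
#' @param recon a [dollo_reconstruct()] result.
#' @param family_labels optional named vector family_id -> label (see
#'   [majority_family_labels()]).
#' @return a list with `summary` (data frame: node, n_acquired, n_inherited,
#'   n_present) and, when labels are given, `acquired_by_label` (node x label
#'   count data frame, wide).
#' @export
node_acquisition_summary <- function(recon, family_labels = NULL) {
  nodes <- colnames(recon$presence)
  present <- colSums(recon$presence)
  acquired <- table(factor(recon$gain, nodes))
  summary <- data.frame(node = nodes,
                        n_acquired = as.integer(acquired),
                        n_inherited = as.integer(present - acquired),
                        n_present = as.integer(present),
                        stringsAsFactors = FALSE)
  stopifnot(all(summary$n_acquired + summary$n_inherited == summary$n_present))
  out <- list(summary = summary)
  if (!is.null(family_labels)) {
    lab <- family_labels[names(recon$gain)]
    lab[is.na(lab)] <- "unlabeled"
    tab <- table(factor(recon$gain, nodes), lab)
    out$acquired_by_label <- as.data.frame.matrix(tab)
  }
  out
}

#' Majority-vote functional labels for gene families
#'
#' @param gfs a [gene_family_set()].
#' @param ann named vector gene_id -> label (see [read_annotation_table()]);
#'   genes missing from it count as `"unlabeled"`.
#' @return named vector family_id -> label; ties yield `"ambiguous"`.
#' @export
majority_family_labels <- function(gfs, ann) {
  vapply(gfs$families, function(gids) {
    tab <- sort(table(annotation_label(ann, gids)), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) "ambiguous" else names(tab)[1]
  }, character(1))
}
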