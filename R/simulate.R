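# Seeded strain-pangenome simulator with complete ground truth.
#
# The generative model mirrors the structure the downstream analyses assume:
# a clonal strain tree (pure-birth), a core family set present at the root,
# accessory families gained exactly once on a branch (Dollo-compatible) and
# lost independently along descendant branches, i.i.d. per-site protein
# substitution with codon re-encoding, optional within-genome duplication,
# and alien-composition (HGT) genes private to leaves.

GENETIC_CODE_TAB <- local({
  gc <- Biostrings::GENETIC_CODE
  gc
})
SENSE_CODONS <- names(GENETIC_CODE_TAB)[GENETIC_CODE_TAB != "*"]
STOP_CODONS <- names(GENETIC_CODE_TAB)[GENETIC_CODE_TAB == "*"]
CODON_AA <- GENETIC_CODE_TAB[SENSE_CODONS]
AA_LETTERS <- sort(unique(unname(CODON_AA)))

# Codon weights under an i.i.d. base model with the given GC fraction.
# codon_bias > 0 adds a translational-style preference: within each
# synonymous set a fixed preferred codon (alphabetically first) receives
# that extra probability mass. The base composition is then re-tuned by
# root-finding so the table's GC3 still matches the plain model at `gc`,
# keeping `gc` meaningful independently of the bias strength.
codon_weights <- function(gc, codon_bias = 0) {
  iid <- function(theta) {
    p <- c(A = (1 - theta) / 2, C = theta / 2, G = theta / 2, T = (1 - theta) / 2)
    w <- vapply(SENSE_CODONS, function(cd) {
      b <- strsplit(cd, "")[[1]]
      p[b[1]] * p[b[2]] * p[b[3]]
    }, numeric(1))
    w / sum(w)
  }
  gc3_of <- function(w) {
    third <- substr(SENSE_CODONS, 3, 3)
    sum(w[third %in% c("G", "C")])
  }
  # per amino acid, the most-AT- and most-GC-ending synonymous codons
  # (ties broken alphabetically); the bias mass is split between them with
  # a theta-dependent mix so GC3 is continuous and tunable
  gc3_count <- as.integer(substr(SENSE_CODONS, 3, 3) %in% c("G", "C"))
  names(gc3_count) <- SENSE_CODONS
  pref_at <- vapply(unique(CODON_AA), function(aa) {
    syn <- sort(SENSE_CODONS[CODON_AA == aa])
    syn[order(gc3_count[syn])][1]
  }, character(1))
  pref_gc <- vapply(unique(CODON_AA), function(aa) {
    syn <- sort(SENSE_CODONS[CODON_AA == aa])
    syn[order(-gc3_count[syn])][1]
  }, character(1))
  biased <- function(theta) {
    w0 <- iid(theta)
    aa_marg <- tapply(w0, CODON_AA, sum)
    ws <- w0
    for (aa in unique(CODON_AA)) {
      syn <- SENSE_CODONS[CODON_AA == aa]
      cond <- w0[syn] / sum(w0[syn])
      cond <- (1 - codon_bias) * cond +
        codon_bias * (theta * (syn == pref_gc[[aa]]) +
                        (1 - theta) * (syn == pref_at[[aa]]))
      ws[syn] <- aa_marg[[aa]] * cond
    }
    ws
  }
  if (codon_bias == 0) return(iid(gc))
  target <- gc3_of(iid(gc))
  theta <- stats::uniroot(function(t) gc3_of(biased(t)) - target,
                          lower = 0.02, upper = 0.98, tol = 1e-9)$root
  biased(theta)
}

# Sample one codon for each residue of a protein from the synonymous subsets
# of a codon weight vector.
encode_protein <- function(prot, weights) {
  res <- strsplit(prot, "")[[1]]
  codons <- vapply(res, function(aa) {
    syn <- SENSE_CODONS[CODON_AA == aa]
    if (length(syn) == 1) return(syn)
    sample(syn, 1, prob = weights[syn])
  }, character(1))
  paste(codons, collapse = "")
}

random_protein <- function(len, weights) {
  aa_marg <- tapply(weights, CODON_AA, sum)
  paste(sample(AA_LETTERS, len, replace = TRUE,
               prob = aa_marg[AA_LETTERS]), collapse = "")
}

# Sample a whole alien gene: i.i.d. codons from the alien codon distribution.
random_alien_gene <- function(len, weights) {
  codons <- sample(SENSE_CODONS, len, replace = TRUE, prob = weights)
  list(prot = paste(unname(CODON_AA[codons]), collapse = ""),
       dna = paste(codons, collapse = ""))
}

# Per-site substitution on a protein with codon re-encoding of changed sites.
mutate_gene <- function(prot, dna, p_sub, weights) {
  if (p_sub <= 0) return(list(prot = prot, dna = dna))
  res <- strsplit(prot, "")[[1]]
  hit <- which(stats::runif(length(res)) < p_sub)
  if (!length(hit)) return(list(prot = prot, dna = dna))
  dnav <- strsplit(dna, "")[[1]]
  for (i in hit) {
    new_aa <- sample(setdiff(AA_LETTERS, res[i]), 1)
    res[i] <- new_aa
    syn <- SENSE_CODONS[CODON_AA == new_aa]
    cd <- if (length(syn) == 1) syn else sample(syn, 1, prob = weights[syn])
    dnav[(3 * i - 2):(3 * i)] <- strsplit(cd, "")[[1]]
  }
  list(prot = paste(res, collapse = ""), dna = paste(dnav, collapse = ""))
}

# Functional label pool, loosely mirroring a saccharolytic gut bacterium:
# a handful of glycosyl hydrolase families on top of eggNOG category letters.
FAMILY_LABEL_POOL <- c(
  GH13 = 0.010, GH43 = 0.008, GH23 = 0.006, GH25 = 0.006, GH3 = 0.005,
  GH36 = 0.005, GH42 = 0.004, GH77 = 0.003,
  J = 0.06, K = 0.07, L = 0.06, C = 0.05, G = 0.12, E = 0.10, F = 0.03,
  H = 0.03, I = 0.02, P = 0.05, M = 0.05, O = 0.03, T = 0.02, V = 0.02,
  R = 0.08, S = 0.06, hypothetical = 0.107
)

#' Parameters of the strain-pangenome simulator
#'
#' Defaults define the desk-scale study conditions used throughout the
#' package: 12 strains, 400 root (core) families, gains at rate 3 and a
#' per-family loss hazard of 0.3 per unit branch length, 1% per-site protein
#' divergence per unit branch length, native GC 0.60 with alien (HGT) genes
#' at GC 0.45.
#'
#' @param n_genomes number of strains (>= 2).
#' @param n_core_root gene families present at the root.
#' @param gain_rate expected family gains per unit branch length.
#' @param loss_rate per-family loss hazard per unit branch length.
#' @param subst_rate per-site substitution probability per unit branch length.
#' @param mean_protein_len mean protein length (residues).
#' @param hgt_fraction fraction of each leaf's genes that are alien
#'   (horizontally acquired) singletons, in `[0, 1)`.
#' @param native_gc GC fraction of the native codon model.
#' @param alien_gc GC fraction of the alien codon model, in (0, 1).
#' @param alien_codon_bias strength (in `[0, 1)`) of the alien table's
#'   preferred-codon (translational) bias; alien genes come from donor
#'   genomes with their own codon preferences on top of the GC offset.
#' @param dup_prob per-family, per-branch duplication probability (paralogs).
#' @param seed integer RNG seed.
#' @return a validated parameter list of class `"sim_params"`.
#' @export
simulation_params <- function(n_genomes = 12, n_core_root = 400,
                              gain_rate = 3, loss_rate = 0.3,
                              subst_rate = 0.01, mean_protein_len = 300,
                              hgt_fraction = 0.10, native_gc = 0.60,
                              alien_gc = 0.45, alien_codon_bias = 0.6,
                              dup_prob = 0.02, seed = 1) {
  if (n_genomes < 2) stop_param("n_genomes must be >= 2")
  if (gain_rate < 0 || loss_rate < 0 || subst_rate < 0) {
    stop_param("rates must be >= 0")
  }
  if (hgt_fraction < 0 || hgt_fraction >= 1) stop_param("hgt_fraction must be in [0, 1)")
  if (alien_gc <= 0 || alien_gc >= 1) stop_param("alien_gc must be in (0, 1)")
  structure(list(n_genomes = as.integer(n_genomes),
                 n_core_root = as.integer(n_core_root),
                 gain_rate = gain_rate, loss_rate = loss_rate,
                 subst_rate = subst_rate,
                 mean_protein_len = as.integer(mean_protein_len),
                 hgt_fraction = hgt_fraction, native_gc = native_gc,
                 alien_gc = alien_gc, alien_codon_bias = alien_codon_bias,
                 dup_prob = dup_prob, seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate a rooted strain tree under a pure-birth (Yule) process
#'
#' Lineages split at rate `birth_rate` each; the process is stopped by a
#' final exponential interval after the n-th lineage arises, so all tips are
#' contemporaneous (the tree is ultrametric).
#'
#' @param n_genomes number of tips (>= 2).
#' @param seed integer RNG seed; identical seeds give identical trees.
#' @param birth_rate per-lineage split rate.
#' @return a rooted, ultrametric ape `phylo` with tip labels `g01..gNN` and
#'   internal node labels `n1..`, all branch lengths strictly positive.
#' @export
simulate_strain_tree <- function(n_genomes, seed = 1, birth_rate = 1) {
  if (n_genomes < 2) stop_param("n_genomes must be >= 2")
  set.seed(seed)
  # lineage bookkeeping: parent index, start time, end time, children
  parent <- c(NA_integer_, 0L, 0L)   # index 1 unused sentinel for root
  start <- c(0, 0, 0)
  end <- c(0, NA_real_, NA_real_)
  active <- c(2L, 3L)
  t <- 0
  while (length(active) < n_genomes) {
    t <- t + stats::rexp(1, rate = birth_rate * length(active))
    i <- active[sample.int(length(active), 1)]
    end[i] <- t
    k <- length(parent)
    parent <- c(parent, i, i)
    start <- c(start, t, t)
    end <- c(end, NA_real_, NA_real_)
    active <- c(setdiff(active, i), k + 1L, k + 2L)
  }
  t_final <- t + stats::rexp(1, rate = birth_rate * length(active))
  end[active] <- t_final
  is_tip <- seq_along(parent) %in% active
  tip_ids <- sort(which(is_tip))
  tip_label <- stats::setNames(sprintf("g%02d", seq_along(tip_ids)), tip_ids)

  newick_of <- function(i) {
    kids <- which(parent == i)
    bl <- sprintf("%.10g", end[i] - start[i])
    if (!length(kids)) return(paste0(tip_label[as.character(i)], ":", bl))
    inner <- paste(vapply(kids, newick_of, character(1)), collapse = ",")
    if (i == 1L) paste0("(", inner, ");") else paste0("(", inner, "):", bl)
  }
  root_kids <- which(parent == 0L)
  inner <- paste(vapply(root_kids, newick_of, character(1)), collapse = ",")
  tr <- ape::read.tree(text = paste0("(", inner, ");"))
  tr$node.label <- sprintf("n%d", seq_len(tr$Nnode))
  tr
}

# name of a node (tip label or internal node label) by ape node number
node_name <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- character(length(node))
  tip <- node <= ntip
  out[tip] <- tree$tip.label[node[tip]]
  out[!tip] <- tree$node.label[node[!tip] - ntip]
  out
}

# inverse lookup
node_number <- function(tree, name) {
  i <- match(name, c(tree$tip.label, tree$node.label))
  if (any(is.na(i))) stop_input("unknown node name '%s'", name[is.na(i)][1])
  i
}

#' Simulate a strain pangenome with full ground truth
#'
#' @param tree rooted strain tree (see [simulate_strain_tree()]); internal
#'   nodes must be labeled (labels are added when missing).
#' @param params a [simulation_params()] object.
#' @return a list with `proteomes` (list of [proteome()] objects) and `truth`
#'   (class `"sim_truth"`): the tree, `family_of_gene`, per-family
#'   `gain_branch` (name of the node the gain branch leads into) and
#'   `loss_branches`, `family_label`, and `hgt_gene_ids`.
#' @export
simulate_pangenome <- function(tree, params) {
  if (!inherits(params, "sim_params")) stop_param("params must come from simulation_params()")
  if (!ape::is.rooted(tree)) stop_param("tree must be rooted")
  if (is.null(tree$node.label)) tree$node.label <- sprintf("n%d", seq_len(tree$Nnode))
  set.seed(params$seed + 1L)
  native_w <- codon_weights(params$native_gc)
  alien_w <- codon_weights(params$alien_gc,
                           codon_bias = params$alien_codon_bias)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  children_of <- split(tree$edge[, 2], tree$edge[, 1])
  edge_len <- stats::setNames(tree$edge.length, tree$edge[, 2])

  counter <- 0L
  gain_branch <- character(0)
  loss_branches <- list()
  family_label <- character(0)

  new_family <- function(node) {
    counter <<- counter + 1L
    id <- sprintf("F%05d", counter)
    gain_branch[id] <<- node_name(tree, node)
    loss_branches[[id]] <<- character(0)
    family_label[id] <<- sample(names(FAMILY_LABEL_POOL), 1,
                                prob = FAMILY_LABEL_POOL)
    len <- max(50L, stats::rpois(1, params$mean_protein_len))
    prot <- random_protein(len, native_w)
    stop_cd <- sample(STOP_CODONS, 1)
    list(id = id, prot = prot,
         dna = paste0(encode_protein(prot, native_w), stop_cd))
  }

  # state: named list family_id -> list(copies = list(prot, dna) ...)
  leaf_states <- vector("list", ntip)

  descend <- function(node, state) {
    if (node <= ntip) {
      leaf_states[[node]] <<- state
      return(invisible(NULL))
    }
    for (child in children_of[[as.character(node)]]) {
      bl <- edge_len[[as.character(child)]]
      st <- state
      # losses
      if (length(st) && params$loss_rate > 0) {
        lost <- stats::runif(length(st)) < 1 - exp(-params$loss_rate * bl)
        if (any(lost)) {
          for (id in names(st)[lost]) {
            loss_branches[[id]] <<- c(loss_branches[[id]], node_name(tree, child))
          }
          st <- st[!lost]
        }
      }
      # substitution + duplication
      p_sub <- 1 - exp(-params$subst_rate * bl)
      for (id in names(st)) {
        st[[id]]$copies <- lapply(st[[id]]$copies, function(cp) {
          core <- substr(cp$dna, 1, nchar(cp$dna) - 3)
          m <- mutate_gene(cp$prot, core, p_sub, native_w)
          list(prot = m$prot,
               dna = paste0(m$dna, substr(cp$dna, nchar(cp$dna) - 2, nchar(cp$dna))))
        })
        if (stats::runif(1) < params$dup_prob) {
          st[[id]]$copies <- c(st[[id]]$copies, st[[id]]$copies[1])
        }
      }
      # gains
      n_gain <- stats::rpois(1, params$gain_rate * bl)
      for (k in seq_len(n_gain)) {
        fam <- new_family(child)
        st[[fam$id]] <- list(copies = list(list(prot = fam$prot, dna = fam$dna)))
      }
      descend(child, st)
    }
  }

  root_state <- list()
  for (k in seq_len(params$n_core_root)) {
    fam <- new_family(root)
    root_state[[fam$id]] <- list(copies = list(list(prot = fam$prot, dna = fam$dna)))
  }
  descend(root, root_state)

  family_of_gene <- character(0)
  hgt_gene_ids <- character(0)
  proteomes <- vector("list", ntip)
  names(proteomes) <- tree$tip.label
  for (i in seq_len(ntip)) {
    gid <- tree$tip.label[i]
    st <- leaf_states[[i]]
    rows <- list()
    idx <- 0L
    for (id in names(st)) {
      for (cp in st[[id]]$copies) {
        idx <- idx + 1L
        rows[[idx]] <- data.frame(gene = sprintf("%s_%04d", gid, idx),
                                  fam = id, prot = cp$prot, dna = cp$dna,
                                  label = unname(family_label[id]),
                                  stringsAsFactors = FALSE)
      }
    }
    n_native <- idx
    n_hgt <- round(params$hgt_fraction / (1 - params$hgt_fraction) * n_native)
    for (k in seq_len(n_hgt)) {
      idx <- idx + 1L
      counter <- counter + 1L
      id <- sprintf("F%05d", counter)
      gain_branch[id] <- gid
      loss_branches[[id]] <- character(0)
      family_label[id] <- "hypothetical"
      len <- max(50L, stats::rpois(1, params$mean_protein_len))
      g <- random_alien_gene(len, alien_w)
      gene_id <- sprintf("%s_%04d", gid, idx)
      rows[[idx]] <- data.frame(gene = gene_id, fam = id, prot = g$prot,
                                dna = paste0(g$dna, sample(STOP_CODONS, 1)),
                                label = "hypothetical", stringsAsFactors = FALSE)
      hgt_gene_ids <- c(hgt_gene_ids, gene_id)
    }
    df <- do.call(rbind, rows)
    ends <- cumsum(nchar(df$dna))
    genes <- gene_table(gene_id = df$gene, genome_id = gid,
                        protein_seq = df$prot, nucleotide_seq = df$dna,
                        start = c(0L, ends[-length(ends)]), end = ends,
                        strand = "+", functional_label = df$label)
    proteomes[[gid]] <- proteome(gid, genes)
    family_of_gene[df$gene] <- df$fam
  }

  truth <- structure(list(tree = tree, family_of_gene = family_of_gene,
                          gain_branch = gain_branch,
                          loss_branches = loss_branches,
                          family_label = family_label,
                          hgt_gene_ids = hgt_gene_ids, params = params),
                     class = "sim_truth")
  list(proteomes = proteomes, truth = truth)
}

#' Simulate a full dataset (tree + pangenome) from parameters
#'
#' @param params a [simulation_params()] object; the tree is simulated from
#'   `params$seed` and the pangenome from `params$seed + 1`.
#' @return see [simulate_pangenome()].
#' @export
simulate_dataset <- function(params = simulation_params()) {
  tree <- simulate_strain_tree(params$n_genomes, seed = params$seed)
  simulate_pangenome(tree, params)
}

#' Verify the Dollo consistency of a simulation's ground truth
#'
#' Asserts, for every family and leaf, that the leaf possesses the family iff
#' the gain node is an ancestor (or the leaf itself) and no loss lies on the
#' gain-to-leaf path.
#'
#' @param sim output of [simulate_pangenome()] / [simulate_dataset()].
#' @return `TRUE` invisibly; errors on any violation.
#' @export
verify_truth <- function(sim) {
  truth <- sim$truth
  tree <- truth$tree
  present <- truth_presence_matrix(truth)
  observed <- present & FALSE
  for (p in sim$proteomes) {
    fams <- unique(unname(truth$family_of_gene[p$genes$gene_id]))
    observed[fams, p$genome_id] <- TRUE
  }
  if (!identical(unname(present), unname(observed))) {
    bad <- which(present != observed, arr.ind = TRUE)[1, ]
    stop_input("Dollo inconsistency: family %s, genome %s",
               rownames(present)[bad[1]], colnames(present)[bad[2]])
  }
  invisible(TRUE)
}

# Expected leaf presence implied by the recorded gain/loss events.
truth_presence_matrix <- function(truth) {
  tree <- truth$tree
  ntip <- length(tree$tip.label)
  fams <- names(truth$gain_branch)
  m <- matrix(FALSE, length(fams), ntip,
              dimnames = list(fams, tree$tip.label))
  # path from each leaf to root as node names
  paths <- lapply(seq_len(ntip), function(i) {
    nodes <- i
    cur <- i
    repeat {
      parent <- tree$edge[tree$edge[, 2] == cur, 1]
      if (!length(parent)) break
      nodes <- c(nodes, parent)
      cur <- parent
    }
    node_name(tree, nodes)
  })
  for (f in fams) {
    gain <- truth$gain_branch[[f]]
    losses <- truth$loss_branches[[f]]
    for (i in seq_len(ntip)) {
      path <- paths[[i]]
      gpos <- match(gain, path)
      if (is.na(gpos)) next
      # nodes on the gain->leaf path are path[1:gpos]
      if (!any(losses %in% path[seq_len(gpos)])) m[f, i] <- TRUE
    }
  }
  m
}

#' Write a simulated dataset to disk
#'
#' Emits, per genome, a protein FASTA (`<genome>.faa`) and a gene nucleotide
#' FASTA (`<genome>.fna`), plus a combined annotation TSV (`annotation.tsv`,
#' columns gene_id and label) and a ground-truth JSON (`truth.json`).
#'
#' @param sim output of [simulate_dataset()].
#' @param out_dir output directory.
#' @param force overwrite a non-empty existing directory.
#' @return `out_dir`, invisibly.
#' @export
emit_dataset <- function(sim, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force) {
    stop_input("output directory '%s' is not empty (use force = TRUE)", out_dir)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (p in sim$proteomes) {
    write_fasta(data.frame(id = p$genes$gene_id, seq = p$genes$protein_seq),
                file.path(out_dir, paste0(p$genome_id, ".faa")))
    write_fasta(data.frame(id = p$genes$gene_id, seq = p$genes$nucleotide_seq),
                file.path(out_dir, paste0(p$genome_id, ".fna")))
  }
  genes <- combined_gene_table(sim$proteomes)
  write_annotation_table(stats::setNames(genes$functional_label, genes$gene_id),
                         file.path(out_dir, "annotation.tsv"))
  truth <- sim$truth
  write_report_json(list(
    tree = write_newick(truth$tree),
    family_of_gene = as.list(truth$family_of_gene),
    gain_branch = as.list(truth$gain_branch),
    loss_branches = truth$loss_branches,
    family_label = as.list(truth$family_label),
    hgt_gene_ids = truth$hgt_gene_ids,
    params = unclass(truth$params)
  ), file.path(out_dir, "truth.json"))
  invisible(out_dir)
}

#' @rdname emit_dataset
#' @param dir a directory written by `emit_dataset`.
#' @export
load_dataset <- function(dir) {
  tj <- read_report_json(file.path(dir, "truth.json"))
  ann <- read_annotation_table(file.path(dir, "annotation.tsv"))
  tree <- parse_newick(tj$tree)
  genomes <- sub("\\.faa$", "", basename(Sys.glob(file.path(dir, "*.faa"))))
  proteomes <- lapply(genomes, function(g) {
    aa <- read_fasta(file.path(dir, paste0(g, ".faa")), "protein")
    nt <- read_fasta(file.path(dir, paste0(g, ".fna")), "dna")
    stopifnot(identical(aa$id, nt$id))
    proteome(g, gene_table(gene_id = aa$id, genome_id = g,
                           protein_seq = aa$seq, nucleotide_seq = nt$seq,
                           functional_label = annotation_label(ann, aa$id)))
  })
  names(proteomes) <- genomes
  params <- do.call(simulation_params, tj$params)
  truth <- structure(list(tree = tree,
                          family_of_gene = unlist(tj$family_of_gene),
                          gain_branch = unlist(tj$gain_branch),
                          loss_branches = lapply(tj$loss_branches, as.character),
                          family_label = unlist(tj$family_label),
                          hgt_gene_ids = as.character(tj$hgt_gene_ids),
                          params = params),
                     class = "sim_truth")
  list(proteomes = proteomes, truth = truth)
}
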