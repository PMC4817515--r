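# Independent oracles and fixture generators. Everything here is written
# from the definitions (dense matrices, plain loops), independently of the
# package's implementation paths it is used to check.

AAS <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
BASES <- c("A", "C", "G", "T")

random_protein_seq <- function(n) paste(sample(AAS, n, TRUE), collapse = "")
random_dna_seq <- function(n) paste(sample(BASES, n, TRUE), collapse = "")

mutate_seq <- function(s, p, alphabet = AAS) {
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < p)
  for (i in hit) v[i] <- sample(setdiff(alphabet, v[i]), 1)
  paste(v, collapse = "")
}

# --- exhaustive Smith-Waterman DP oracle (affine gaps) ----------------------
sw_score_oracle <- function(a, b, gap_open = 10, gap_ext = 1) {
  e <- new.env(); data("BLOSUM62", package = "Biostrings", envir = e)
  S <- get("BLOSUM62", envir = e)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(-Inf, n + 1, m + 1); X <- M; Y <- M
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Y[i, j - 1] - gap_ext)
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
                       S[av[i - 1], bv[j - 1]])
      best <- max(best, M[i, j])
    }
  }
  best
}

# --- dense MCL iteration oracle, straight from the definition ---------------
mcl_oracle <- function(adj, inflation = 1.5, expansion = 2,
                       pruning_epsilon = 1e-6, max_iter = 200,
                       convergence_tol = 1e-8) {
  adj <- as.matrix(adj)
  n <- nrow(adj)
  diag(adj) <- 0
  loop <- apply(adj, 2, max)
  loop[loop == 0] <- 1
  diag(adj) <- loop
  norm <- function(m) sweep(m, 2, pmax(colSums(m), .Machine$double.xmin), "/")
  m <- norm(adj)
  for (it in seq_len(max_iter)) {
    m_new <- m
    for (e in seq_len(expansion - 1)) m_new <- m_new %*% m
    m_new <- m_new^inflation
    m_new <- norm(m_new)
    m_new[m_new < pruning_epsilon] <- 0
    m_new <- norm(m_new)
    if (max(abs(m_new - m)) < convergence_tol) { m <- m_new; break }
    m <- m_new
  }
  # clusters = connected components of the non-zero structure (own BFS)
  support <- (m + t(m)) > 0
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(support[v, ] & is.na(comp)))
    }
  }
  comp
}

# planted-clique similarity graph with sparse noise edges
planted_clique_graph <- function(k_cliques, sizes, intra_w = 10, inter_w = 1,
                                 p_noise = 0.05) {
  n <- sum(sizes)
  truth <- rep(seq_len(k_cliques), sizes)
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (truth[i] == truth[j]) {
        adj[i, j] <- adj[j, i] <- intra_w
      } else if (runif(1) < p_noise) {
        adj[i, j] <- adj[j, i] <- inter_w
      }
    }
  }
  dimnames(adj) <- list(sprintf("x%02d", 1:n), sprintf("x%02d", 1:n))
  list(adj = adj, truth = truth)
}

# --- rooted binary tree shapes (unlabeled), as ape trees --------------------
# all distinct unlabeled rooted binary shapes with n leaves
tree_shapes_newick <- function(n) {
  shapes <- function(k) {
    if (k == 1) return("L")
    out <- character(0)
    for (a in 1:(k %/% 2)) {
      for (sa in shapes(a)) for (sb in shapes(k - a)) {
        pair <- sort(c(sa, sb))
        out <- c(out, paste0("(", pair[1], ",", pair[2], ")"))
      }
    }
    unique(out)
  }
  vapply(shapes(n), function(s) {
    i <- 0L
    while (grepl("L", s, fixed = TRUE)) {
      i <- i + 1L
      s <- sub("L", sprintf("t%d:1", i), s, fixed = TRUE)
    }
    # add unit lengths on internal edges
    s <- gsub(")", "):1", s, fixed = TRUE)
    s <- sub(":1$", ";", s)
    s
  }, character(1), USE.NAMES = FALSE)
}

# exhaustive Dollo oracle: minimum loss count over all single-gain
# assignments (gain node + any loss-edge subset below it)
dollo_min_losses_oracle <- function(tree, pattern_tips) {
  ntip <- length(tree$tip.label)
  n_nodes <- max(tree$edge)
  under <- vector("list", n_nodes)  # tip-index bitmask under each node
  ord <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(ntip)) under[[i]] <- bitwShiftL(1L, i - 1L)
  for (r in seq_len(nrow(ord$edge))) {
    p <- ord$edge[r, 1]; c <- ord$edge[r, 2]
    under[[p]] <- bitwOr(under[[p]] %||% 0L, under[[c]])
  }
  pattern_mask <- Reduce(bitwOr, bitwShiftL(1L, match(pattern_tips, tree$tip.label) - 1L), 0L)
  # edges below a node
  parent_of <- integer(n_nodes)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  best <- Inf
  for (gain in seq_len(n_nodes)) {
    below <- which(vapply(seq_len(n_nodes), function(v) {
      if (v == gain) return(FALSE)
      cur <- v
      while (cur != gain && parent_of[cur] != 0L) cur <- parent_of[cur]
      cur == gain
    }, logical(1)))
    ne <- length(below)
    for (s in 0:(2^ne - 1)) {
      lost <- 0L
      sz <- 0L
      for (bi in seq_len(ne)) {
        if (bitwAnd(s, bitwShiftL(1L, bi - 1L)) != 0L) {
          lost <- bitwOr(lost, under[[below[bi]]])
          sz <- sz + 1L
        }
      }
      if (sz >= best) next
      leaves <- bitwAnd(under[[gain]], bitwNot(lost))
      if (leaves == pattern_mask) best <- min(best, sz)
    }
  }
  best
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# quick full study fixture shared by several tests (computed once per run)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- simulation_params(n_genomes = 6, n_core_root = 60, gain_rate = 2,
                             loss_rate = 0.2, subst_rate = 0.01,
                             mean_protein_len = 150, seed = 77)
      sim <- simulate_dataset(p)
      g <- build_similarity_graph(sim$proteomes)
      cl <- mcl_cluster(g)
      cache <<- list(sim = sim, graph = g, clusters = cl,
                     gfs = gene_family_set(cl, sim$proteomes))
    }
    cache
  }
})
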