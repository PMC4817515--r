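scc_fixture <- function(seqs_by_genome) {
  # one single-copy core family per list slot; seqs_by_genome: genome -> vector
  genomes <- names(seqs_by_genome)
  nf <- length(seqs_by_genome[[1]])
  ps <- lapply(genomes, function(g) {
    proteome(g, gene_table(sprintf("%s_%d", g, 1:nf), g, seqs_by_genome[[g]]))
  })
  membership <- setNames(rep(1:nf, length(genomes)),
                         unlist(lapply(genomes, function(g) sprintf("%s_%d", g, 1:nf))))
  list(gfs = gene_family_set(membership, ps), proteomes = ps)
}

test_that("identical proteomes give zero core-sequence distances", {
  s <- replicate(3, random_protein_seq(90))
  fx <- scc_fixture(list(gA = s, gB = s, gC = s))
  d <- core_sequence_distances(fx$gfs, fx$proteomes)
  expect_true(all(d == 0))
})

test_that("p-distance pooling and Poisson correction match the closed form", {
  set.seed(40)
  a <- random_protein_seq(100)
  b <- a
  pos <- sample(100, 10)
  bv <- strsplit(b, "")[[1]]
  for (i in pos) bv[i] <- sample(setdiff(AAS, bv[i]), 1)
  b <- paste(bv, collapse = "")
  fx <- scc_fixture(list(gA = a, gB = b, gC = a))
  d <- core_sequence_distances(fx$gfs, fx$proteomes)
  expect_equal(d["gA", "gB"], -log(1 - 0.10), tolerance = 1e-12)
  expect_equal(d["gA", "gC"], 0)
})

test_that("core-sequence distances rank-match true path lengths on a fixed tree", {
  # fixed 8-leaf caterpillar with spine positions at Golomb-ruler marks:
  # every pairwise path length is distinct with a gap of at least 0.3, so
  # the rank order is well defined and resolvable from pooled alignments
  spine <- 0.4 * c(0, 1, 4, 9, 15, 22, 32, 34)
  pend <- 0.01 * (1:8)
  nwk <- sprintf("g01:%.4f", pend[1] + spine[2] - spine[1])
  for (k in 2:8) {
    nwk <- sprintf("(%s,g%02d:%.4f)", nwk, k, pend[k])
    if (k < 8) nwk <- sprintf("%s:%.4f", nwk, spine[k + 1] - spine[k])
  }
  tr <- parse_newick(paste0(nwk, ";"))
  tr$node.label <- sprintf("n%d", seq_len(tr$Nnode))
  true_d <- cophenetic(tr)
  expect_gt(min(diff(sort(true_d[lower.tri(true_d)]))), 0.29)

  p <- simulation_params(n_genomes = 8, n_core_root = 1000, gain_rate = 0,
                         loss_rate = 0, subst_rate = 0.04, hgt_fraction = 0,
                         dup_prob = 0, mean_protein_len = 250, seed = 44)
  sim <- simulate_pangenome(tr, p)
  # families from truth: isolates the distance computation from the search
  membership <- setNames(as.integer(factor(sim$truth$family_of_gene)),
                         names(sim$truth$family_of_gene))
  gfs <- gene_family_set(membership, sim$proteomes)
  d <- core_sequence_distances(gfs, sim$proteomes)
  true_d <- true_d[rownames(d), colnames(d)]
  lt <- lower.tri(d)
  expect_equal(cor(d[lt], true_d[lt], method = "spearman"), 1)
})

test_that("gene-content distances equal hand-computed Jaccard values", {
  m <- matrix(FALSE, 8, 5, dimnames = list(sprintf("f%d", 1:8), sprintf("g%d", 1:5)))
  m[1:4, 1] <- TRUE
  m[1:4, 2] <- TRUE                 # identical to g1
  m[5:8, 3] <- TRUE                 # disjoint from g1
  m[c(1, 2, 5, 6), 4] <- TRUE       # overlap 2, union 6 with g1
  m[c(1, 5, 7), 5] <- TRUE          # overlap 1, union 6 with g1
  d <- presence_absence_distances(pa_matrix(m))
  expect_equal(d["g1", "g2"], 0)
  expect_equal(d["g1", "g3"], 1)
  expect_equal(d["g1", "g4"], 1 - 2 / 6)
  expect_equal(d["g1", "g5"], 1 - 1 / 6)
  expect_equal(d["g4", "g5"], 1 - 2 / 5)
})

test_that("three-taxon NJ matches the closed-form branch lengths", {
  dm <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(dm)
  tip_edge <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(tip_edge["A"]), (2 + 3 - 4) / 2)
  expect_equal(unname(tip_edge["B"]), (2 + 4 - 3) / 2)
  expect_equal(unname(tip_edge["C"]), (3 + 4 - 2) / 2)
})

test_that("additive matrices are reconstructed exactly (topology and lengths)", {
  set.seed(57)
  for (k in 1:25) {
    n <- sample(5:20, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- runif(length(tr$edge.length), 0.05, 1)
    dm <- cophenetic(tr)
    nj <- neighbor_joining(dm)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nj)), 0)
    expect_lt(max(abs(cophenetic(nj)[rownames(dm), colnames(dm)] - dm)), 1e-9)
  }
})

test_that("distance constructions are permutation-equivariant", {
  st <- small_study()
  pa <- st$gfs$pa
  d1 <- presence_absence_distances(pa)
  perm <- sample(ncol(pa))
  d2 <- presence_absence_distances(pa_matrix(unclass(pa)[, perm]))
  expect_equal(d2[rownames(d1), colnames(d1)], d1)
})

test_that("rooting works by outgroup and midpoint, and validates labels", {
  dm <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(dm)
  expect_true(ape::is.rooted(root_tree(tr, "C")))
  expect_true(ape::is.rooted(root_tree(tr)))
  expect_error(root_tree(tr, "nope"), class = "pancog_input_error")
})

test_that("a divergent lineage attaches on its own branch, matching truth", {
  # one strain far from a tight cluster (rumen-strain analogue)
  tr <- simulate_strain_tree(8, seed = 3)
  out_tip <- tr$tip.label[1]
  tr$edge.length[tr$edge[, 2] == 1] <- max(tr$edge.length) * 8
  p <- simulation_params(n_genomes = 8, n_core_root = 30, gain_rate = 0,
                         loss_rate = 0, subst_rate = 0.01, hgt_fraction = 0,
                         dup_prob = 0, mean_protein_len = 150, seed = 10)
  sim <- simulate_pangenome(tr, p)
  g <- build_similarity_graph(sim$proteomes)
  gfs <- gene_family_set(mcl_cluster(g), sim$proteomes)
  d <- core_sequence_distances(gfs, sim$proteomes)
  nj <- neighbor_joining(d)
  # the divergent tip must carry the longest terminal branch by far
  term <- setNames(nj$edge.length[match(seq_along(nj$tip.label), nj$edge[, 2])],
                   nj$tip.label)
  expect_equal(names(which.max(term)), out_tip)
  expect_gt(max(term), 3 * max(term[names(term) != out_tip]))
  # and NJ recovers the generating topology
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nj)), 0)
})
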