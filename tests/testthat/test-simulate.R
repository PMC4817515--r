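test_that("strain trees are rooted, binary, seeded and positive-length", {
  tr <- simulate_strain_tree(2, seed = 4)
  expect_equal(length(tr$tip.label), 2)
  expect_true(all(tr$edge.length > 0))

  t1 <- simulate_strain_tree(10, seed = 5)
  t2 <- simulate_strain_tree(10, seed = 5)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_true(ape::is.rooted(t1))
  expect_true(ape::is.binary(t1))
  expect_error(simulate_strain_tree(1), class = "pancog_parameter_error")
})

test_that("mean root-to-tip depth matches an independent pure-birth simulation", {
  # package trees
  depths <- vapply(1:300, function(k) {
    tr <- simulate_strain_tree(8, seed = 2000 + k)
    max(ape::node.depth.edgelength(tr))
  }, numeric(1))
  # independent oracle: sum of exponential inter-birth waits, 2..n lineages,
  # plus the final stop interval (all tips contemporaneous, so depth = total)
  set.seed(999)
  oracle <- vapply(1:3000, function(k) sum(rexp(7, rate = 2:8)), numeric(1))
  se <- sqrt(var(depths) / length(depths) + var(oracle) / length(oracle))
  expect_lt(abs(mean(depths) - mean(oracle)), 4 * se)
})

test_that("degenerate simulator regimes behave as the model dictates", {
  # no gain, no loss: every genome carries exactly the root families
  p0 <- simulation_params(n_genomes = 5, n_core_root = 25, gain_rate = 0,
                          loss_rate = 0, subst_rate = 0.02, hgt_fraction = 0,
                          dup_prob = 0, mean_protein_len = 80, seed = 3)
  sim0 <- simulate_dataset(p0)
  fams_per_genome <- vapply(sim0$proteomes, function(pr) {
    length(unique(sim0$truth$family_of_gene[pr$genes$gene_id]))
  }, numeric(1))
  expect_true(all(fams_per_genome == 25))
  expect_equal(length(unique(sim0$truth$family_of_gene)), 25)

  # zero-length branches: all genomes identical, zero divergence
  tr <- simulate_strain_tree(4, seed = 8)
  tr$edge.length[] <- 0
  simz <- simulate_pangenome(tr, p0)
  seqs <- lapply(simz$proteomes, function(pr) unname(sort(pr$genes$protein_seq)))
  for (k in 2:4) expect_identical(seqs[[1]], seqs[[k]])
})

test_that("simulated truth is Dollo-consistent and seed-deterministic", {
  p <- simulation_params(n_genomes = 7, n_core_root = 40, gain_rate = 2,
                         loss_rate = 0.3, mean_protein_len = 100, seed = 21)
  sim <- simulate_dataset(p)
  expect_true(verify_truth(sim))
  sim2 <- simulate_dataset(p)
  expect_identical(sim$truth$family_of_gene, sim2$truth$family_of_gene)
  expect_identical(sim$proteomes[[3]]$genes$nucleotide_seq,
                   sim2$proteomes[[3]]$genes$nucleotide_seq)
})

test_that("mean accessory families per leaf matches the branch-sum expectation", {
  # fixed tree; families at a leaf = root families surviving + gains that
  # survive from their gain branch: E computed by independent enumeration
  tr <- simulate_strain_tree(10, seed = 31)
  g <- 5; l <- 0.2
  # oracle: for each leaf, E[n_families] = sum over path-prefix structure
  ntip <- length(tr$tip.label)
  parent_of <- integer(max(tr$edge)); parent_of[tr$edge[, 2]] <- tr$edge[, 1]
  elen <- numeric(max(tr$edge)); elen[tr$edge[, 2]] <- tr$edge.length
  expected_leaf <- vapply(seq_len(ntip), function(tip) {
    # nodes on root->tip path (excluding root), in root-to-tip order
    path <- tip; cur <- tip
    while (parent_of[cur] != 0) { cur <- parent_of[cur]; path <- c(cur, path) }
    path <- path[-1]
    surv_below <- function(idx) exp(-l * sum(elen[path[idx:length(path)]]))
    tot <- 60 * surv_below(1)  # root families survive the whole path
    for (k in seq_along(path)) {
      b <- elen[path[k]]
      # gains arrive at the end of their branch and face loss only on the
      # remaining path
      gains <- g * b
      after <- if (k < length(path)) exp(-l * sum(elen[path[(k + 1):length(path)]])) else 1
      tot <- tot + gains * after
    }
    tot
  }, numeric(1))
  p <- simulation_params(n_genomes = 10, n_core_root = 60, gain_rate = g,
                         loss_rate = l, subst_rate = 0, hgt_fraction = 0,
                         dup_prob = 0, mean_protein_len = 60, seed = 1)
  reps <- 60
  got <- matrix(0, reps, ntip)
  for (r in seq_len(reps)) {
    pr <- p; pr$seed <- 5000 + r
    sim <- simulate_pangenome(tr, pr)
    got[r, ] <- vapply(tr$tip.label, function(gid) {
      length(unique(sim$truth$family_of_gene[sim$proteomes[[gid]]$genes$gene_id]))
    }, numeric(1))
  }
  # compare per-leaf Monte-Carlo means against the analytic expectation
  se <- apply(got, 2, sd) / sqrt(reps)
  expect_true(all(abs(colMeans(got) - expected_leaf) < 4 * pmax(se, 0.5)))
})

test_that("expected pan-genome size increases with the gain rate", {
  tr <- simulate_strain_tree(6, seed = 13)
  mean_pan <- function(g) {
    vals <- vapply(1:15, function(r) {
      p <- simulation_params(n_genomes = 6, n_core_root = 30, gain_rate = g,
                             loss_rate = 0.2, subst_rate = 0, hgt_fraction = 0,
                             dup_prob = 0, mean_protein_len = 60,
                             seed = 900 + r)
      sim <- simulate_pangenome(tr, p)
      length(unique(sim$truth$family_of_gene))
    }, numeric(1))
    mean(vals)
  }
  pans <- vapply(c(0, 2, 6), mean_pan, numeric(1))
  expect_true(all(diff(pans) > 0))
})

test_that("datasets emit to disk and reload identically", {
  p <- simulation_params(n_genomes = 3, n_core_root = 15, gain_rate = 1,
                         mean_protein_len = 80, seed = 6)
  sim <- simulate_dataset(p)
  dir <- withr::local_tempdir()
  out <- file.path(dir, "ds")
  emit_dataset(sim, out)
  expect_length(Sys.glob(file.path(out, "*.faa")), 3)
  expect_length(Sys.glob(file.path(out, "*.fna")), 3)
  expect_true(file.exists(file.path(out, "annotation.tsv")))
  expect_true(file.exists(file.path(out, "truth.json")))
  expect_error(emit_dataset(sim, out), class = "pancog_input_error")

  back <- load_dataset(out)
  for (gid in names(sim$proteomes)) {
    expect_identical(back$proteomes[[gid]]$genes$gene_id,
                     sim$proteomes[[gid]]$genes$gene_id)
    expect_identical(back$proteomes[[gid]]$genes$protein_seq,
                     sim$proteomes[[gid]]$genes$protein_seq)
    expect_identical(back$proteomes[[gid]]$genes$nucleotide_seq,
                     sim$proteomes[[gid]]$genes$nucleotide_seq)
  }
  expect_identical(back$truth$family_of_gene[names(sim$truth$family_of_gene)],
                   sim$truth$family_of_gene)
  # truth family sizes equal FASTA-derived counts
  sizes_truth <- table(back$truth$family_of_gene)
  genes <- unlist(lapply(back$proteomes, function(x) x$genes$gene_id))
  sizes_files <- table(back$truth$family_of_gene[genes])
  expect_equal(as.vector(sizes_truth[names(sizes_files)]),
               as.vector(sizes_files))
})
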