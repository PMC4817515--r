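one_gene_proteome <- function(nt, id = "g1", genome = "G") {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
  aa <- sub("\\*$", "", aa)
  proteome(genome, gene_table(id, genome, aa, nucleotide_seq = nt))
}

test_that("codon usage profiles count codons and normalize per amino acid", {
  p <- one_gene_proteome("ATGAAAAAATAA")
  prof <- codon_usage_profile(p)
  expect_equal(unname(prof$freqs["AAA"]), 1)     # Lys usage 100% AAA
  expect_equal(unname(prof$freqs["AAG"]), 0)
  expect_true(prof$low_confidence)
  # frequencies sum to 1 within every amino acid, over random fixtures
  set.seed(8)
  for (k in 1:50) {
    nt <- paste(c("ATG", sample(pancog:::SENSE_CODONS, 50, TRUE), "TGA"),
                collapse = "")
    pr <- codon_usage_profile(one_gene_proteome(nt))
    sums <- tapply(pr$freqs, pancog:::CODON_AA[names(pr$freqs)], sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("profile counts equal an independent codon-counting script", {
  p <- simulation_params(n_genomes = 2, n_core_root = 100, gain_rate = 0,
                         loss_rate = 0, hgt_fraction = 0, dup_prob = 0,
                         mean_protein_len = 120, seed = 14)
  sim <- simulate_dataset(p)
  pr <- codon_usage_profile(sim$proteomes[[1]])
  # oracle: substring loop over all genes
  cnt <- integer(0)
  for (s in sim$proteomes[[1]]$genes$nucleotide_seq) {
    for (i in seq(1, nchar(s), by = 3)) {
      cd <- substr(s, i, i + 2)
      cnt[cd] <- (if (is.na(cnt[cd])) 0L else cnt[cd]) + 1L
    }
  }
  cnt <- cnt[!names(cnt) %in% c("TAA", "TAG", "TGA")]
  expect_equal(as.integer(pr$counts[names(cnt)]), unname(cnt))
  expect_equal(sum(pr$counts), sum(cnt))
})

test_that("stop codons and ambiguous codons are excluded", {
  p <- proteome("G", gene_table("g1", "G", "MK",
                                nucleotide_seq = "ATGAANTAA", partial = TRUE))
  prof <- codon_usage_profile(p)
  expect_equal(sum(prof$counts), 1L)  # only ATG usable
  bad <- proteome("G", gene_table("g1", "G", "MK", nucleotide_seq = "ATGAAAT",
                                  partial = TRUE))
  expect_error(codon_usage_profile(bad), class = "pancog_input_error")
})

test_that("native-composition genes stay under the false-positive budget", {
  set.seed(61)
  # a genome drawn from a biased codon model
  w <- pancog:::codon_weights(0.60)
  nt <- replicate(80, paste(c(sample(names(w), 250, TRUE, prob = as.numeric(w)), "TAA"),
                            collapse = ""))
  aa <- vapply(nt, function(s) sub("\\*$", "", as.character(
    Biostrings::translate(Biostrings::DNAString(s)))), "")
  p <- proteome("G", gene_table(sprintf("g%03d", 1:80), "G", unname(aa),
                                nucleotide_seq = unname(nt)))
  prof <- codon_usage_profile(p)
  thr <- calibrate_flag_threshold(prof, n_sim = 500, fpr = 0.05,
                                  gene_len = 250, seed = 2)
  # 500 fresh self-composed genes: at most ~5% may exceed the threshold
  nulls <- replicate(500, {
    cds <- sample(names(w), 250, TRUE, prob = as.numeric(w))
    pancog:::gene_atypicality(table(factor(cds, names(w))), prof)
  })
  expect_lte(mean(nulls > thr), 0.08)
  # and the full flag rule (with the GC3 co-criterion) is stricter
  sc <- score_genes(p, prof, thr)
  expect_lte(mean(sc$calls$flagged), 0.05)
})

test_that("a maximally alien gene is flagged", {
  set.seed(62)
  w <- pancog:::codon_weights(0.62)
  nt <- replicate(60, paste(c(sample(names(w), 300, TRUE, prob = as.numeric(w)), "TAA"),
                            collapse = ""))
  alien_w <- pancog:::codon_weights(0.25, codon_bias = 0.9)
  nt[60] <- paste(c(sample(names(alien_w), 300, TRUE, prob = as.numeric(alien_w)), "TAA"),
                  collapse = "")
  aa <- vapply(nt, function(s) sub("\\*$", "", as.character(
    Biostrings::translate(Biostrings::DNAString(s)))), "")
  p <- proteome("G", gene_table(sprintf("g%03d", 1:60), "G", unname(aa),
                                nucleotide_seq = unname(nt)))
  sc <- hgt_screen_genome(p, seed = 4)
  expect_true(sc$calls$flagged[60])
})

test_that("the flagged fraction rises with the alien GC offset", {
  frac_at <- function(alien_gc) {
    p <- simulation_params(n_genomes = 2, n_core_root = 120, gain_rate = 0,
                           loss_rate = 0, subst_rate = 0, hgt_fraction = 0.1,
                           dup_prob = 0, alien_gc = alien_gc, seed = 33)
    sim <- simulate_dataset(p)
    sc <- hgt_screen_genome(sim$proteomes[[1]], seed = 7)
    sc$mobilome_fraction
  }
  fr <- vapply(c(0.60, 0.50, 0.40), frac_at, numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_gt(fr[3], fr[1])
})

test_that("the mobilome fraction is invariant to gene order", {
  p <- simulation_params(n_genomes = 2, n_core_root = 60, gain_rate = 0,
                         loss_rate = 0, hgt_fraction = 0.1, dup_prob = 0,
                         seed = 44)
  sim <- simulate_dataset(p)
  pr <- sim$proteomes[[1]]
  sc1 <- hgt_screen_genome(pr, seed = 3)
  perm <- sample(nrow(pr$genes))
  pr2 <- proteome(pr$genome_id, pr$genes[perm, ])
  sc2 <- hgt_screen_genome(pr2, seed = 3)
  expect_equal(sc1$mobilome_fraction, sc2$mobilome_fraction)
})

test_that("TUG overlap handles empty, partial and complete intersections", {
  st <- small_study()
  screens <- lapply(st$sim$proteomes, hgt_screen_genome, seed = 21)
  ov <- overlap_with_tugs(screens, st$gfs)
  expect_setequal(ov$genome_id, names(st$sim$proteomes))
  expect_true(all(ov$pct_tug_flagged >= 0 & ov$pct_tug_flagged <= 100,
                  na.rm = TRUE))
  # no flagged genes -> 0% wherever TUGs exist
  none <- lapply(screens, function(s) {
    s$calls$flagged[] <- FALSE
    s
  })
  ov0 <- overlap_with_tugs(none, st$gfs)
  expect_true(all(ov0$pct_tug_flagged[ov0$n_tug > 0] == 0))
  # flag everything -> 100%
  all_on <- lapply(screens, function(s) {
    s$calls$flagged[] <- TRUE
    s
  })
  ov1 <- overlap_with_tugs(all_on, st$gfs)
  expect_true(all(ov1$pct_tug_flagged[ov1$n_tug > 0] == 100))
})
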