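# Simplified compositional screen for horizontally transferred genes.
#
# Each gene is scored by the mean per-codon log-likelihood ratio of its own
# synonymous codon usage against the genome-wide usage (a per-gene KL
# divergence estimate), with the gene's GC3 deviation from the genome as a
# co-criterion. The flag threshold is calibrated on a null simulation of
# native-composition genes to a configured false-positive rate. This is a
# deliberately transparent screen exercising the flag -> fraction -> TUG
# overlap procedure; it is not an HMM segmentation method.

codon_counts <- function(nt_seqs) {
  cod <- unlist(lapply(nt_seqs, function(s) {
    L <- nchar(s)
    if (L %% 3 != 0) stop_input("nucleotide sequence length not divisible by 3")
    substring(s, seq(1, L - 2, by = 3), seq(3, L, by = 3))
  }), use.names = FALSE)
  cod <- cod[!grepl("N", cod, fixed = TRUE)]
  cod <- cod[!cod %in% STOP_CODONS]
  table(factor(cod, SENSE_CODONS))
}

gc3_fraction <- function(counts) {
  third <- substr(names(counts), 3, 3)
  sum(counts[third %in% c("G", "C")]) / sum(counts)
}

# synonymous relative frequencies with per-amino-acid pseudocounts;
# amino acids with no observed codons get the uniform distribution over
# their synonymous set, so per-amino-acid frequencies always sum to 1
synonymous_freqs <- function(counts, pseudo = 0) {
  x <- as.numeric(counts) + pseudo
  names(x) <- names(counts)
  for (aa in unique(CODON_AA)) {
    syn <- SENSE_CODONS[CODON_AA == aa]
    tot <- sum(x[syn])
    x[syn] <- if (tot > 0) x[syn] / tot else 1 / length(syn)
  }
  x
}

#' Genome-wide synonymous codon usage profile
#'
#' @param p a [proteome()] with nucleotide sequences (lengths divisible by 3;
#'   stop codons and codons containing N are excluded).
#' @return a list of class `"codon_usage_profile"`: `freqs` (relative
#'   synonymous codon frequencies, summing to 1 within each amino acid),
#'   `counts`, `gc3` (genome GC3), `n_codons`, `low_confidence` (fewer than
#'   10,000 usable codons).
#' @export
codon_usage_profile <- function(p) {
  nt <- p$genes$nucleotide_seq
  nt <- nt[!is.na(nt)]
  if (!length(nt)) stop_input("proteome '%s' has no nucleotide sequences", p$genome_id)
  counts <- codon_counts(nt)
  if (sum(counts) == 0) stop_input("no usable codons in proteome '%s'", p$genome_id)
  structure(list(freqs = synonymous_freqs(counts),
                 counts = counts,
                 gc3 = gc3_fraction(counts),
                 n_codons = sum(counts),
                 low_confidence = sum(counts) < 10000),
            class = "codon_usage_profile")
}

# mean per-codon log-likelihood ratio of gene-local vs genome-wide synonymous
# usage; smoothing keeps both distributions strictly positive
gene_atypicality <- function(counts, profile, pseudo = 0.5) {
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  f_gene <- synonymous_freqs(counts, pseudo = pseudo)
  f_genome <- synonymous_freqs(profile$counts, pseudo = pseudo)
  use <- as.numeric(counts) > 0
  sum(as.numeric(counts)[use] * log(f_gene[use] / f_genome[use])) / n
}

#' Score genes for compositional atypicality and flag HGT candidates
#'
#' A gene is flagged when its atypicality exceeds `flag_threshold`, its GC3
#' deviates from the genome by at least `gc3_min`, and it is at least
#' `min_len` nucleotides long.
#'
#' @param p a [proteome()] with nucleotide sequences.
#' @param profile the genome's [codon_usage_profile()].
#' @param flag_threshold atypicality flag threshold; see
#'   [calibrate_flag_threshold()].
#' @param min_len minimum gene length (nt) for flagging.
#' @param gc3_min minimum absolute GC3 deviation for flagging.
#' @return a list of class `"hgt_screen"`: `calls` (data frame gene_id,
#'   atypicality, gc3_deviation, flagged) and `mobilome_fraction` (% of ORFs
#'   flagged).
#' @export
score_genes <- function(p, profile, flag_threshold, min_len = 300L,
                        gc3_min = 0.05) {
  genes <- p$genes
  res <- lapply(genes$nucleotide_seq, function(s) {
    cnt <- codon_counts(s)
    c(atyp = gene_atypicality(cnt, profile),
      gc3 = gc3_fraction(cnt))
  })
  res <- do.call(rbind, res)
  calls <- data.frame(gene_id = genes$gene_id,
                      atypicality = res[, "atyp"],
                      gc3_deviation = abs(res[, "gc3"] - profile$gc3),
                      stringsAsFactors = FALSE)
  calls$flagged <- calls$atypicality > flag_threshold &
    calls$gc3_deviation >= gc3_min &
    nchar(genes$nucleotide_seq) >= min_len
  structure(list(calls = calls,
                 mobilome_fraction = 100 * mean(calls$flagged),
                 genome_id = p$genome_id,
                 flag_threshold = flag_threshold),
            class = "hgt_screen")
}

#' Calibrate the atypicality flag threshold on a null simulation
#'
#' Simulates genes of native composition (amino acids from the genome's
#' amino-acid usage, codons from its synonymous usage) and returns the
#' `1 - fpr` quantile of their atypicality scores, so that scoring a genome
#' against its own profile flags about `fpr` of genes at most.
#'
#' The null atypicality of a native gene scales inversely with its length, so
#' the null lengths must match the scored genes: pass the genome's own gene
#' lengths via `lengths` (codons are drawn from them with replacement), or a
#' single fixed `gene_len`.
#'
#' @param profile a [codon_usage_profile()].
#' @param n_sim number of null genes.
#' @param fpr target false-positive rate.
#' @param gene_len fixed null gene length in codons (ignored when `lengths`
#'   is given).
#' @param lengths pool of gene lengths in codons to resample null lengths
#'   from (typically the scored genome's own).
#' @param seed RNG seed (recorded in reports for reproducibility).
#' @return the calibrated threshold (a single number).
#' @export
calibrate_flag_threshold <- function(profile, n_sim = 500L, fpr = 0.05,
                                     gene_len = 300L, lengths = NULL,
                                     seed = 1L) {
  set.seed(seed)
  marg <- as.numeric(profile$counts) / sum(profile$counts)
  lens <- if (is.null(lengths)) rep(gene_len, n_sim) else
    sample(lengths, n_sim, replace = TRUE)
  scores <- vapply(lens, function(L) {
    codons <- sample(SENSE_CODONS, L, replace = TRUE, prob = marg)
    gene_atypicality(table(factor(codons, SENSE_CODONS)), profile)
  }, numeric(1))
  unname(stats::quantile(scores, 1 - fpr, type = 7))
}

#' Run the full compositional HGT screen on one genome
#'
#' Builds the genome's codon usage profile, calibrates the flag threshold on
#' a null simulation at the genome's own gene-length distribution, and scores
#' every gene.
#'
#' @param p a [proteome()] with nucleotide sequences.
#' @param fpr target false-positive rate for the calibration.
#' @param n_sim null-simulation size.
#' @param min_len,gc3_min see [score_genes()].
#' @param seed RNG seed for the null simulation.
#' @return a [score_genes()] result (class `"hgt_screen"`), with the
#'   calibrated threshold in `$flag_threshold`.
#' @export
hgt_screen_genome <- function(p, fpr = 0.05, n_sim = 500L, min_len = 300L,
                              gc3_min = 0.05, seed = 1L) {
  profile <- codon_usage_profile(p)
  lens <- nchar(p$genes$nucleotide_seq) %/% 3L - 1L
  thr <- calibrate_flag_threshold(profile, n_sim = n_sim, fpr = fpr,
                                  lengths = lens, seed = seed)
  score_genes(p, profile, thr, min_len = min_len, gc3_min = gc3_min)
}

#' Overlap between HGT candidates and truly unique genes (TUGs)
#'
#' @param screens a list of [score_genes()] results (one per genome), or one
#'   such result.
#' @param gfs a [gene_family_set()] over the same dataset.
#' @return data frame per genome: `n_tug`, `n_tug_flagged`,
#'   `pct_tug_flagged` (`NA` where a genome has no TUGs).
#' @export
overlap_with_tugs <- function(screens, gfs) {
  if (inherits(screens, "hgt_screen")) screens <- list(screens)
  uniq <- names(gfs$classification)[gfs$classification == "unique"]
  tug_members <- gfs$members[gfs$members$family_id %in% uniq, ]
  out <- lapply(screens, function(sc) {
    tugs <- tug_members$gene_id[tug_members$genome_id == sc$genome_id]
    flagged <- sc$calls$gene_id[sc$calls$flagged]
    n_tug <- length(tugs)
    n_hit <- length(intersect(tugs, flagged))
    data.frame(genome_id = sc$genome_id, n_tug = n_tug,
               n_tug_flagged = n_hit,
               pct_tug_flagged = if (n_tug) 100 * n_hit / n_tug else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
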