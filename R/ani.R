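# Fragment-based average nucleotide identity (ANI).
#
# The classical fragment formulation: the query genome is cut into
# consecutive 1020-nt pieces; each piece is aligned to the subject genome
# (both strands) and kept if it reaches 30% identity over at least 70% of its
# length; ANI is the mean identity of kept fragments, averaged over the two
# directions. Fragment placement uses exact k-mer seeding with a diagonal
# vote, followed by an end-gap-free alignment against the seeded window.

#' ANI parameters
#'
#' @param fragment_len fragment length in nucleotides (>= 100).
#' @param frag_pid_min identity floor for a fragment to be counted.
#' @param frag_cov_min fraction of the fragment that must be aligned.
#' @param seed_k k-mer size used to place fragments on the subject.
#' @param window_pad extra subject bases kept on each side of the seeded
#'   window before alignment.
#' @return a list of class `"ani_params"`.
#' @export
ani_params <- function(fragment_len = 1020L, frag_pid_min = 0.30,
                       frag_cov_min = 0.70, seed_k = 14L, window_pad = 60L) {
  if (fragment_len < 100) stop_param("fragment_len must be >= 100")
  structure(list(fragment_len = as.integer(fragment_len),
                 frag_pid_min = frag_pid_min, frag_cov_min = frag_cov_min,
                 seed_k = as.integer(seed_k), window_pad = as.integer(window_pad)),
            class = "ani_params")
}

chop_fragments <- function(seqs, len) {
  out <- character(0)
  for (s in seqs) {
    L <- nchar(s)
    n <- L %/% len
    if (n == 0) next
    starts <- (seq_len(n) - 1L) * len + 1L
    out <- c(out, substring(s, starts, starts + len - 1L))
  }
  out
}

# k-mer position index of a set of subject sequences (forward strand),
# as a data.table kmer -> (sequence, position).
subject_kmer_index <- function(seqs, k) {
  dt <- data.table::rbindlist(lapply(seq_along(seqs), function(si) {
    L <- nchar(seqs[si])
    if (L < k) return(NULL)
    data.table::data.table(kmer = substring(seqs[si], 1:(L - k + 1L), k:L),
                           si = si, pos = 1:(L - k + 1L))
  }))
  data.table::setkey(dt, kmer)
  dt
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# Place fragments on the subject by diagonal voting; returns for each
# fragment the chosen subject sequence, strand and window coordinates
# (NA when no seed matched).
seed_fragments <- function(frags, index, k, stride = 17L) {
  n <- length(frags)
  qk <- data.table::rbindlist(lapply(seq_len(n), function(qi) {
    L <- nchar(frags[qi])
    starts <- unique(c(seq(1L, L - k + 1L, by = stride), L - k + 1L))
    fwd <- data.table::data.table(kmer = substring(frags[qi], starts, starts + k - 1L),
                                  qi = qi, qpos = starts, strand = "+")
    rc <- revcomp(frags[qi])
    rev <- data.table::data.table(kmer = substring(rc, starts, starts + k - 1L),
                                  qi = qi, qpos = starts, strand = "-")
    rbind(fwd, rev)
  }))
  hits <- index[qk, nomatch = NULL, on = "kmer", allow.cartesian = TRUE]
  if (!nrow(hits)) {
    return(data.frame(si = rep(NA_integer_, n), strand = NA_character_,
                      diag = NA_integer_))
  }
  hits$diag <- hits$pos - hits$qpos
  hits$bucket <- hits$diag %/% 32L
  votes <- hits[, .N, by = .(qi, si, strand, bucket)]
  data.table::setorder(votes, qi, -N, si, strand, bucket)
  best <- votes[, .SD[1], by = qi]
  # representative exact diagonal within the winning bucket
  data.table::setkey(hits, qi, si, strand, bucket)
  diag_of <- hits[best, on = c("qi", "si", "strand", "bucket"),
                  mult = "first"]
  out <- data.frame(si = rep(NA_integer_, n), strand = NA_character_,
                    diag = NA_integer_)
  out$si[diag_of$qi] <- diag_of$si
  out$strand[diag_of$qi] <- diag_of$strand
  out$diag[diag_of$qi] <- diag_of$diag
  out
}

ani_one_direction <- function(a_seqs, b_index, b_seqs, params) {
  frags <- chop_fragments(a_seqs, params$fragment_len)
  if (!length(frags)) return(list(identities = numeric(0), n_total = 0L))
  placed <- seed_fragments(frags, b_index, params$seed_k)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  identities <- numeric(0)
  for (qi in seq_along(frags)) {
    if (is.na(placed$si[qi])) next
    frag <- if (placed$strand[qi] == "-") revcomp(frags[qi]) else frags[qi]
    subj <- b_seqs[placed$si[qi]]
    lo <- max(1L, placed$diag[qi] + 1L - params$window_pad)
    hi <- min(nchar(subj),
              placed$diag[qi] + nchar(frag) + params$window_pad)
    window <- substr(subj, lo, hi)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(frag), Biostrings::DNAString(window),
      type = "overlap", substitutionMatrix = mat,
      gapOpening = 4, gapExtension = 2)
    alen <- Biostrings::nchar(aln)
    if (alen == 0) next
    ident <- Biostrings::nmatch(aln) / alen
    cov <- alen / nchar(frag)
    if (ident >= params$frag_pid_min && cov >= params$frag_cov_min) {
      identities <- c(identities, ident)
    }
  }
  list(identities = identities, n_total = length(frags))
}

#' Average nucleotide identity between two genomes
#'
#' @param genome_a,genome_b DNA sequences of the two assemblies: character
#'   vectors, or [proteome()] objects (their assembly, falling back to the
#'   concatenated coding sequences).
#' @param params an [ani_params()].
#' @return a list with `ani` (percentage, bidirectional mean), `ani_ab` /
#'   `ani_ba` (directional values), and `n_fragments_used`. Errors with class
#'   `pancog_ani_undefined` when no fragment passes the filters.
#' @export
compute_ani <- function(genome_a, genome_b, params = ani_params()) {
  a <- if (inherits(genome_a, "proteome")) assembly_of(genome_a) else genome_a
  b <- if (inherits(genome_b, "proteome")) assembly_of(genome_b) else genome_b
  a <- toupper(a); b <- toupper(b)
  if (!length(a) || !sum(nchar(a)) || !length(b) || !sum(nchar(b))) {
    stop_param("both assemblies must be non-empty")
  }
  idx_b <- subject_kmer_index(b, params$seed_k)
  idx_a <- subject_kmer_index(a, params$seed_k)
  ab <- ani_one_direction(a, idx_b, b, params)
  ba <- ani_one_direction(b, idx_a, a, params)
  n_used <- length(ab$identities) + length(ba$identities)
  if (n_used == 0) {
    stop(errorCondition("no fragment passed the identity/coverage filters; ANI is undefined",
                        class = c("pancog_ani_undefined", "pancog_error")))
  }
  dir_means <- c(mean(ab$identities) * 100, mean(ba$identities) * 100)
  list(ani = mean(dir_means, na.rm = TRUE),
       ani_ab = dir_means[1], ani_ba = dir_means[2],
       n_fragments_used = n_used)
}
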