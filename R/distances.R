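# Genome-genome distance constructions: Poisson-corrected core-sequence
# distances (concatenation-equivalent pooling over single-copy core
# families) and gene-content (Jaccard) distances from the presence/absence
# matrix.

validate_dm <- function(d) {
  if (!isSymmetric(unname(d), tol = 1e-12)) stop_input("distance matrix must be symmetric")
  if (any(!is.finite(d))) stop_input("distance matrix has non-finite entries")
  if (any(diag(d) != 0)) stop_input("distance matrix diagonal must be zero")
  d
}

#' Poisson-corrected core-sequence distances
#'
#' For every genome pair, the members of each single-copy core family are
#' globally aligned (end-gap free, same scoring scheme as the similarity
#' search); mismatches and aligned columns are pooled over all families —
#' equivalent to a p-distance on the concatenated core alignment — and
#' corrected for multiple substitutions as `d = -ln(1 - p)`.
#'
#' @param gfs a [gene_family_set()].
#' @param proteomes the proteome list the families were built from.
#' @param families family ids to use; defaults to [single_copy_core()].
#' @param scoring a [scoring_scheme()].
#' @return a symmetric distance matrix over genomes.
#' @export
core_sequence_distances <- function(gfs, proteomes,
                                    families = single_copy_core(gfs),
                                    scoring = scoring_scheme()) {
  genome_ids <- colnames(gfs$pa)
  if (length(genome_ids) < 3) stop_param("need at least 3 genomes")
  if (!length(families)) stop_param("no single-copy core families available")
  genes <- combined_gene_table(proteomes)
  seq_of <- stats::setNames(genes$protein_seq, genes$gene_id)
  genome_of <- stats::setNames(genes$genome_id, genes$gene_id)
  # member of family f in genome g (single copy by construction)
  member <- matrix(NA_character_, length(families), length(genome_ids),
                   dimnames = list(families, genome_ids))
  for (f in families) {
    gid <- gfs$families[[f]]
    member[f, genome_of[gid]] <- gid
  }
  G <- length(genome_ids)
  d <- matrix(0, G, G, dimnames = list(genome_ids, genome_ids))
  for (i in seq_len(G - 1)) {
    for (j in (i + 1):G) {
      pat <- Biostrings::AAStringSet(unname(seq_of[member[, i]]))
      sub <- Biostrings::AAStringSet(unname(seq_of[member[, j]]))
      aln <- Biostrings::pairwiseAlignment(
        pat, sub, type = "overlap",
        substitutionMatrix = scoring$matrix,
        gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
      matches <- sum(Biostrings::nmatch(aln))
      mismatches <- sum(Biostrings::nmismatch(aln))
      p <- mismatches / (matches + mismatches)
      if (p >= 1) {
        stop_input("p-distance >= 1 between %s and %s; Poisson correction undefined",
                   genome_ids[i], genome_ids[j])
      }
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  validate_dm(d)
}

#' Gene-content (Jaccard) distances from a presence/absence matrix
#'
#' `d(i, j) = 1 - |F_i intersect F_j| / |F_i union F_j|` over family sets.
#'
#' @param pa a [pa_matrix()].
#' @return a symmetric distance matrix over genomes.
#' @export
presence_absence_distances <- function(pa) {
  if (ncol(pa) < 3) stop_param("need at least 3 genomes")
  if (any(colSums(pa) == 0)) {
    stop_input("genome '%s' has an empty family set",
               colnames(pa)[colSums(pa) == 0][1])
  }
  d <- as.matrix(vegan::vegdist(t(unclass(pa)), method = "jaccard",
                                binary = TRUE))
  diag(d) <- 0
  validate_dm(d)
}
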