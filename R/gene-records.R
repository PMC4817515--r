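# Core domain containers: gene records, proteomes and the gene-family
# presence/absence matrix.
#
# A gene table is a plain data frame (one row per predicted protein-coding
# gene); a proteome wraps the gene table of one genome together with optional
# assembly sequences. Coordinates, when present, are 0-based half-open.

#' Build and validate a gene table
#'
#' @param gene_id,genome_id character vectors (recycled `genome_id` allowed).
#' @param protein_seq amino-acid sequences (uppercase, 20 standard letters + X).
#' @param nucleotide_seq optional DNA sequences (A/C/G/T/N); unless a record is
#'   flagged `partial`, the length must equal `3 * nchar(protein_seq) + 3`
#'   (coding sequence including the stop codon).
#' @param start,end optional 0-based half-open coordinates (`end > start`).
#' @param strand optional `"+"`/`"-"`.
#' @param functional_label optional functional tag (for example `"GH13"`, an
#'   eggNOG category letter, or `"hypothetical"`).
#' @param partial logical; `TRUE` marks records whose coding sequence is
#'   incomplete, relaxing the nucleotide-length invariant.
#' @return a validated data frame with one row per gene.
#' @export
gene_table <- function(gene_id, genome_id, protein_seq,
                       nucleotide_seq = NA_character_,
                       start = NA_integer_, end = NA_integer_,
                       strand = NA_character_,
                       functional_label = NA_character_,
                       partial = FALSE) {
  df <- data.frame(gene_id = as.character(gene_id),
                   genome_id = as.character(genome_id),
                   protein_seq = as.character(protein_seq),
                   nucleotide_seq = as.character(nucleotide_seq),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   functional_label = as.character(functional_label),
                   partial = as.logical(partial),
                   stringsAsFactors = FALSE)
  validate_gene_table(df)
}

validate_gene_table <- function(df) {
  if (anyDuplicated(df$gene_id)) {
    stop_input("duplicate gene_id '%s'", df$gene_id[duplicated(df$gene_id)][1])
  }
  bad <- grepl(sprintf("[^%s]", paste(PROTEIN_ALPHABET, collapse = "")),
               df$protein_seq)
  if (any(bad)) {
    stop_input("illegal protein residue in gene '%s'", df$gene_id[bad][1])
  }
  has_nt <- !is.na(df$nucleotide_seq)
  if (any(has_nt)) {
    exp_len <- 3L * nchar(df$protein_seq[has_nt]) + 3L
    ok <- nchar(df$nucleotide_seq[has_nt]) == exp_len | df$partial[has_nt]
    if (!all(ok)) {
      stop_input("nucleotide length of gene '%s' is not 3*protein+3 and the record is not flagged partial",
                 df$gene_id[has_nt][!ok][1])
    }
  }
  has_coord <- !is.na(df$start) & !is.na(df$end)
  if (any(has_coord & df$end <= df$start)) {
    stop_input("end <= start for gene '%s'",
               df$gene_id[has_coord & df$end <= df$start][1])
  }
  df
}

#' Construct a proteome (one genome's gene complement)
#'
#' @param genome_id genome identifier.
#' @param genes a gene table (see [gene_table()]); every row must carry this
#'   `genome_id` and there must be at least one gene.
#' @param assembly_seqs optional named character vector of assembly (contig)
#'   DNA sequences. When absent, [assembly_of()] falls back to concatenating
#'   the genes' nucleotide sequences.
#' @return an object of class `"proteome"`.
#' @export
proteome <- function(genome_id, genes, assembly_seqs = NULL) {
  genes <- validate_gene_table(genes)
  if (nrow(genes) < 1) stop_input("proteome '%s' has no genes", genome_id)
  if (!all(genes$genome_id == genome_id)) {
    stop_input("gene table of '%s' contains foreign genome_ids", genome_id)
  }
  structure(list(genome_id = genome_id, genes = genes,
                 assembly_seqs = assembly_seqs),
            class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("<proteome> %s: %d genes%s\n", x$genome_id, nrow(x$genes),
              if (is.null(x$assembly_seqs)) "" else
                sprintf(", %d assembly seq(s)", length(x$assembly_seqs))))
  invisible(x)
}

# Assembly DNA of a proteome: stored contigs, or the concatenated CDS set.
assembly_of <- function(p) {
  if (!is.null(p$assembly_seqs)) return(p$assembly_seqs)
  nt <- p$genes$nucleotide_seq
  if (all(is.na(nt))) stop_input("proteome '%s' has no nucleotide sequences", p$genome_id)
  stats::setNames(paste(nt[!is.na(nt)], collapse = ""), p$genome_id)
}

# Bind the gene tables of a list of proteomes, rejecting cross-genome
# duplicate gene IDs.
combined_gene_table <- function(proteomes) {
  df <- do.call(rbind, lapply(proteomes, function(p) p$genes))
  rownames(df) <- NULL
  if (anyDuplicated(df$gene_id)) {
    stop_input("duplicate gene_id across proteomes: '%s'",
               df$gene_id[duplicated(df$gene_id)][1])
  }
  df
}

#' Construct a presence/absence matrix of gene families over genomes
#'
#' @param cells logical matrix, families in rows (rownames = family ids),
#'   genomes in columns (colnames = genome ids). Every family must be present
#'   in at least one genome.
#' @param copy_counts optional integer matrix of the same shape; must be
#'   positive exactly where `cells` is `TRUE`.
#' @return the validated matrix, of class `"pa_matrix"`, with `copy_counts`
#'   kept as an attribute.
#' @export
pa_matrix <- function(cells, copy_counts = NULL) {
  if (!is.logical(cells)) storage.mode(cells) <- "logical"
  if (is.null(rownames(cells)) || is.null(colnames(cells))) {
    stop_input("presence/absence matrix needs family rownames and genome colnames")
  }
  if (any(rowSums(cells) == 0)) {
    stop_input("family '%s' is absent from every genome",
               rownames(cells)[rowSums(cells) == 0][1])
  }
  if (!is.null(copy_counts)) {
    if (!identical(dim(copy_counts), dim(cells))) {
      stop_input("copy_counts shape differs from cells")
    }
    if (any((copy_counts > 0) != cells)) {
      stop_input("copy_counts must be positive exactly where a family is present")
    }
    attr(cells, "copy_counts") <- copy_counts
  }
  class(cells) <- c("pa_matrix", class(cells))
  cells
}

#' Write / read a presence-absence matrix as TSV (families x genomes, 0/1)
#'
#' @param pa a [pa_matrix()].
#' @param path file path.
#' @return `path` (write) or a `pa_matrix` (read).
#' @export
write_pa_matrix <- function(pa, path) {
  m <- matrix(as.integer(pa), nrow(pa), dimnames = dimnames(pa))
  utils::write.table(data.frame(family_id = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pa_matrix
#' @export
read_pa_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"family_id" %in% names(df)) stop_format("missing required column 'family_id' in %s", path)
  m <- as.matrix(df[, setdiff(names(df), "family_id"), drop = FALSE]) > 0
  rownames(m) <- df$family_id
  pa_matrix(m)
}
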