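# FASTA input/output.
#
# Parsing is delegated to Biostrings; this layer adds alphabet validation
# with positional error reporting, duplicate-ID rejection and the ID /
# description split (ID = first whitespace-delimited token of the header).

PROTEIN_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")
DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a FASTA file into a data frame of sequence records
#'
#' @param path path to a FASTA file (headers start with `>`).
#' @param alphabet `"dna"` (A/C/G/T/N) or `"protein"` (20 amino acids + X).
#'   Sequences are uppercased before validation.
#' @return a data frame with columns `id` (token before the first whitespace
#'   in the header), `desc` (full header) and `seq`, in file order.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop_input("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_format("malformed FASTA '%s': %s",
                                                  path, conditionMessage(e)))
  if (length(set) == 0) stop_format("empty FASTA file: %s", path)
  desc <- names(set)
  id <- sub("\\s.*$", "", desc)
  if (anyDuplicated(id)) {
    stop_format("duplicate FASTA id '%s' in %s", id[duplicated(id)][1], path)
  }
  seq <- toupper(as.character(set))
  allowed <- if (alphabet == "dna") DNA_ALPHABET else PROTEIN_ALPHABET
  bad <- regexpr(sprintf("[^%s]", paste(allowed, collapse = "")), seq)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop_format("illegal %s residue '%s' in record '%s' at position %d",
                alphabet, substr(seq[i], bad[i], bad[i]), id[i], bad[i])
  }
  data.frame(id = id, desc = desc, seq = unname(seq), stringsAsFactors = FALSE)
}

#' Write sequence records to a FASTA file
#'
#' @param records data frame with columns `id` and `seq` (optionally `desc`,
#'   used as the full header when present), or a named character vector.
#' @param path output file path.
#' @param width line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), desc = names(records),
                          seq = unname(records), stringsAsFactors = FALSE)
  }
  if (is.null(records$desc)) records$desc <- records$id
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$desc
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
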