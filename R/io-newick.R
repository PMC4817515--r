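# Newick serialization. Trees are ape "phylo" objects throughout; this layer
# adds a parenthesis pre-check with character offsets (ape's parser aborts
# without position information) and round-trip-stable writing.

#' Serialize a tree to a Newick string
#'
#' @param tree an ape `phylo` object.
#' @param path optional file path; when given the string is also written there.
#' @param digits significant digits for branch lengths (>= 6 preserves
#'   round-trip identity at the precision used in this package).
#' @return the Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  if (!inherits(tree, "phylo")) stop_param("tree must be a 'phylo' object")
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Parse a Newick string (or file) into a tree
#'
#' @param text a Newick string; alternatively use `path`.
#' @param path file containing a Newick tree.
#' @return an ape `phylo` object.
#' @export
parse_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop_param("give either text or path")
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  check_parens(text)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop_format("malformed Newick string")
  tr
}

# Balanced-parenthesis scan reporting the first offending character offset.
check_parens <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop_format("unbalanced ')' at character offset %d", i)
      }
    }
  }
  if (depth != 0L) {
    stop_format("unclosed '(' remaining at end of string (offset %d)",
                length(chars))
  }
  invisible(TRUE)
}
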