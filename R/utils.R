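# Shared small utilities and typed error conditions.

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("pancog_format_error", "pancog_error")))
}

stop_param <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("pancog_parameter_error", "pancog_error")))
}

stop_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("pancog_input_error", "pancog_error")))
}

#' Adjusted Rand index between two partitions
#'
#' Measures agreement between two clusterings of the same items, corrected
#' for chance; 1 means identical partitions (up to label names), 0 is the
#' expectation under independent random labellings.
#'
#' @param a,b vectors of cluster labels over the same items (same length,
#'   same order). Names are ignored; only the grouping matters.
#' @return a single number in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_param("partitions must cover the same items")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_i * sum_j / n2
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# deterministic %in%-style best pick: highest score, lowest evalue, then
# lexicographically smallest id
pick_best <- function(score, evalue, id) {
  ord <- order(-score, evalue, id)
  ord[1]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
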