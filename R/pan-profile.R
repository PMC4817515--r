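# Pan- and core-genome accumulation profiles and the Heaps-law power fit.

# all permutations of 1..n as a matrix (n! rows); used when exhaustive
# enumeration of genome orderings is feasible
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- (r + 1L):(r + nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

#' Pan/core accumulation profiles over genome addition orders
#'
#' For each genome ordering, genomes are added one at a time; the pan size is
#' the cumulative union of families, the core size the cumulative
#' intersection, and the new-family count the increment of the pan. Means and
#' SDs are taken over orderings: all `G!` orderings when feasible
#' (`factorial(G) <= n_orderings`, always when `G <= 8` at the default), else
#' `n_orderings` seeded random permutations.
#'
#' @param pa a [pa_matrix()] (families x genomes).
#' @param n_orderings number of random orderings when enumeration is
#'   infeasible (>= 1).
#' @param seed RNG seed for the sampled orderings.
#' @return a data frame of class `"pan_profile"` with columns `n`,
#'   `pan_mean`, `pan_sd`, `core_mean`, `core_sd`, `new_mean`, `new_sd`;
#'   attributes `n_orderings` (used), `exhaustive`, `seed`.
#' @export
accumulation_profiles <- function(pa, n_orderings = 1000L, seed = 1L) {
  G <- ncol(pa)
  if (G < 2) stop_param("need at least 2 genomes")
  if (n_orderings < 1) stop_param("n_orderings must be >= 1")
  exhaustive <- factorial(G) <= n_orderings
  if (exhaustive) {
    perms <- all_permutations(G)
  } else {
    set.seed(seed)
    perms <- t(replicate(n_orderings, sample.int(G)))
  }
  m <- unclass(pa)
  pan <- core <- new <- matrix(0L, nrow(perms), G)
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    in_pan <- m[, p[1]]
    in_core <- m[, p[1]]
    pan[r, 1] <- sum(in_pan)
    core[r, 1] <- sum(in_core)
    new[r, 1] <- sum(in_pan)
    for (s in 2:G) {
      col <- m[, p[s]]
      added <- sum(col & !in_pan)
      in_pan <- in_pan | col
      in_core <- in_core & col
      pan[r, s] <- pan[r, s - 1] + added
      core[r, s] <- sum(in_core)
      new[r, s] <- added
    }
    if (any(diff(pan[r, ]) < 0) || any(diff(core[r, ]) > 0)) {
      stop_input("accumulation monotonicity violated (internal error)")
    }
  }
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  prof <- data.frame(n = seq_len(G),
                     pan_mean = colMeans(pan), pan_sd = apply(pan, 2, sd0),
                     core_mean = colMeans(core), core_sd = apply(core, 2, sd0),
                     new_mean = colMeans(new), new_sd = apply(new, 2, sd0))
  attr(prof, "n_orderings") <- nrow(perms)
  attr(prof, "exhaustive") <- exhaustive
  attr(prof, "seed") <- seed
  class(prof) <- c("pan_profile", class(prof))
  prof
}

#' Power-trend fit of a pan-genome profile and the open/closed verdict
#'
#' Fits `P(n) = kappa * n^gamma` to the mean pan size by least squares on the
#' log-log scale, and the Heaps-law decay `N(n) = k * n^-alpha` to the mean
#' new-family counts (n >= 2). The pan-genome is called open when the pan
#' exponent has not flattened (`gamma >= gamma_open`) or the new-gene decay
#' is sub-harmonic (`alpha <= 1`); both thresholds are exposed because the
#' openness verdict is conventionally qualitative.
#'
#' @param profile a [accumulation_profiles()] result, or any data frame with
#'   columns `n` and `pan_mean` (and optionally `new_mean`).
#' @param gamma_open openness threshold on the pan exponent.
#' @return a list of class `"power_law_fit"`: `kappa`, `gamma`, `r_squared`,
#'   `alpha`, `alpha_r_squared`, `verdict` (`"open"` / `"closed"`).
#' @export
fit_power_law <- function(profile, gamma_open = 0.05) {
  if (nrow(profile) < 4) stop_param("need a profile over at least 4 genomes")
  if (any(profile$pan_mean <= 0)) stop_input("non-positive pan size; cannot fit power law")
  fit <- stats::lm(log(pan_mean) ~ log(n), data = profile)
  gamma <- unname(stats::coef(fit)[2])
  kappa <- exp(unname(stats::coef(fit)[1]))
  # noiseless profiles fit exactly; summary.lm warns about that, harmlessly
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (is.nan(r2)) r2 <- 1  # zero-variance response: constant profile, exact fit
  alpha <- NA_real_
  alpha_r2 <- NA_real_
  if (!is.null(profile$new_mean)) {
    nd <- profile[profile$n >= 2, ]
    if (all(nd$new_mean <= 0)) {
      alpha <- Inf
    } else {
      if (any(nd$new_mean <= 0)) {
        warning("dropping n with zero new families from the Heaps fit")
        nd <- nd[nd$new_mean > 0, ]
      }
      if (nrow(nd) >= 2) {
        nfit <- stats::lm(log(new_mean) ~ log(n), data = nd)
        alpha <- -unname(stats::coef(nfit)[2])
        alpha_r2 <- suppressWarnings(summary(nfit)$r.squared)
      }
    }
  }
  verdict <- if (gamma >= gamma_open || (!is.na(alpha) && alpha <= 1)) "open" else "closed"
  structure(list(kappa = kappa, gamma = gamma, r_squared = r2,
                 alpha = alpha, alpha_r_squared = alpha_r2,
                 gamma_open = gamma_open, verdict = verdict),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> P(n) = %.4g * n^%.4g (R2 %.4f); new-gene alpha %.4g; %s pan-genome\n",
              x$kappa, x$gamma, x$r_squared, x$alpha, x$verdict))
  invisible(x)
}
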