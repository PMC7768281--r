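#' Spearman rank correlation with listwise deletion
#'
#' Pearson correlation of average-ranked values. Pairs with a missing
#' value in either vector are removed first; ties receive average ranks.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Spearman's rho, or `NA_real_` when fewer than 3 complete pairs
#'   remain or either vector has zero rank variance.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) return(NA_real_)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

# draw a bootstrap resample index matrix (n_resamples x n), seeded
resample_idx_ <- function(n, n_resamples, seed) {
  with_seed_(seed,
             matrix(sample.int(n, n * n_resamples, replace = TRUE),
                    nrow = n_resamples))
}

# canonical pair order so bootstrap output does not depend on how the
# caller happened to order the observations
canonical_order_ <- function(...) do.call(order, list(...))

#' Bootstrap confidence interval for a Spearman correlation
#'
#' Resamples (x, y) pairs with replacement, recomputes rho per resample,
#' and reports the percentile interval. Resamples in which either variable
#' collapses to zero rank variance are skipped (their count is reported).
#' An empirical two-sided p value against rho = 0 is also computed from
#' the resample distribution, as `2 * min(share <= 0, share >= 0)`,
#' clipped to `[2/(n_resamples + 1), 1]`. Observation pairs are put in a
#' canonical order after listwise deletion, so the result does not depend
#' on how the caller ordered them.
#'
#' @param x,y Numeric vectors; missing pairs are removed listwise.
#' @param n_resamples Number of bootstrap resamples (default 5000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; same seed, same interval.
#' @return An object of class `correlation_result`: `rho`, `ci_low`,
#'   `ci_high`, `p`, `n`, `n_resamples`, `level`, `n_skipped`.
#' @export
bootstrap_ci <- function(x, y, n_resamples = 5000, level = 0.95,
                         seed = NULL) {
  stopifnot(length(x) == length(y), n_resamples >= 1,
            level > 0, level < 1)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  o <- canonical_order_(x, y)
  x <- x[o]; y <- y[o]
  n <- length(x)
  rho <- spearman_cor(x, y)
  if (n < 3 || is.na(rho)) {
    return(correlation_result_(NA_real_, NA_real_, NA_real_, NA_real_,
                               n, n_resamples, level, 0L))
  }
  idx <- resample_idx_(n, n_resamples, seed)
  rhos <- apply(idx, 1, function(i) spearman_cor(x[i], y[i]))
  skipped <- sum(is.na(rhos))
  rhos <- rhos[!is.na(rhos)]
  qs <- stats::quantile(rhos, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  p <- empirical_p_(rhos, length(rhos))
  correlation_result_(rho, qs[1], qs[2], p, n, n_resamples, level,
                      as.integer(skipped))
}

correlation_result_ <- function(rho, lo, hi, p, n, n_resamples, level,
                                n_skipped) {
  structure(list(rho = rho, ci_low = lo, ci_high = hi, p = p, n = n,
                 n_resamples = n_resamples, level = level,
                 n_skipped = n_skipped),
            class = "correlation_result")
}

empirical_p_ <- function(draws, n_resamples) {
  p <- 2 * min(mean(draws <= 0), mean(draws >= 0))
  min(max(p, 2 / (n_resamples + 1)), 1)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, %g%% CI [%.3f, %.3f], p = %.4g, n = %d\n",
              x$rho, 100 * x$level, x$ci_low, x$ci_high, x$p, x$n))
  invisible(x)
}

#' Bootstrap test for a difference of correlations
#'
#' Tests whether rho(x, y1) differs from rho(x, y2) by computing the
#' difference of Spearman correlations on paired bootstrap resamples of
#' (x, y1, y2) triples, giving a distribution of bootstrapped differences.
#' With `use_absolute = TRUE` the absolute values of the two correlations
#' are taken before differencing, comparing magnitudes while ignoring
#' direction. The empirical two-sided p value asks whether the measured
#' difference is significantly different from zero:
#' `2 * min(share of differences <= 0, >= 0)`, clipped to
#' `[2/(n_resamples + 1), 1]`.
#'
#' @param x Shared variable.
#' @param y1,y2 Variables whose correlations with `x` are compared.
#' @param use_absolute Compare correlation magnitudes rather than signed
#'   values.
#' @param n_resamples,level,seed As in [bootstrap_ci()].
#' @return An object of class `diff_corr_result`: `delta_rho` (observed
#'   difference), `ci_low`, `ci_high`, `p`, `n`, `use_absolute`,
#'   `n_resamples`, `n_skipped`.
#' @export
bootstrap_diff_corr <- function(x, y1, y2, use_absolute = FALSE,
                                n_resamples = 5000, level = 0.95,
                                seed = NULL) {
  stopifnot(length(x) == length(y1), length(x) == length(y2))
  ok <- stats::complete.cases(x, y1, y2)
  x <- x[ok]; y1 <- y1[ok]; y2 <- y2[ok]
  o <- canonical_order_(x, y1, y2)
  x <- x[o]; y1 <- y1[o]; y2 <- y2[o]
  n <- length(x)
  tr <- if (use_absolute) abs else identity
  delta <- tr(spearman_cor(x, y1)) - tr(spearman_cor(x, y2))
  if (n < 3 || is.na(delta)) {
    return(structure(list(delta_rho = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p = NA_real_, n = n,
                          use_absolute = use_absolute,
                          n_resamples = n_resamples, n_skipped = 0L),
                     class = "diff_corr_result"))
  }
  idx <- resample_idx_(n, n_resamples, seed)
  deltas <- apply(idx, 1, function(i) {
    tr(spearman_cor(x[i], y1[i])) - tr(spearman_cor(x[i], y2[i]))
  })
  skipped <- sum(is.na(deltas))
  deltas <- deltas[!is.na(deltas)]
  qs <- stats::quantile(deltas, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(list(delta_rho = delta, ci_low = qs[1], ci_high = qs[2],
                 p = empirical_p_(deltas, length(deltas)), n = n,
                 use_absolute = use_absolute, n_resamples = n_resamples,
                 n_skipped = as.integer(skipped)),
            class = "diff_corr_result")
}

#' @export
print.diff_corr_result <- function(x, ...) {
  cat(sprintf(
    "Difference of %scorrelations: delta rho = %.3f, CI [%.3f, %.3f], p = %.4g, n = %d\n",
    if (x$use_absolute) "absolute " else "", x$delta_rho, x$ci_low,
    x$ci_high, x$p, x$n))
  invisible(x)
}

#' Consecutive block differences
#'
#' For each subject's ordered block values, computes the value of each
#' block minus the value of the prior block — an estimate of how measured
#' values vary across time. Differences are typically pooled across
#' subjects for correlation with other measures' differences.
#'
#' @param values Matrix (subjects x blocks) or a single subject's vector,
#'   with at least 2 blocks.
#' @return Matrix (subjects x blocks-1) of consecutive differences.
#' @export
block_differences <- function(values) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  if (ncol(values) < 2) stop("need at least 2 blocks to difference")
  values[, -1, drop = FALSE] - values[, -ncol(values), drop = FALSE]
}
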