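#' Measure band ratios and spectral parameters across a cohort
#'
#' Runs the measurement pipeline over every (subject, channel, block) cell
#' of a synthetic cohort: band-ratio measures from the raw spectrum, and —
#' optionally — a full spectral parameterization, from which fitted
#' aperiodic parameters, band-assigned peak parameters, and parameterized
#' ratios are derived. This is the bridge between the generator and the
#' statistics: the returned table carries one row per cell and is the
#' input to [subject_measures()] and the correlation suites.
#'
#' @param cohort A `cohort_result` from [generate_cohort()].
#' @param fit Logical: parameterize each spectrum (default TRUE). With
#'   FALSE only the ratio columns are filled and all fitted-parameter
#'   columns are `NA`, which is much faster when only raw ratios are
#'   needed.
#' @param settings [fit_settings()] used when fitting.
#' @param bands,pairs Band definitions and ratio pairs.
#' @return Data frame of class `cohort_measures`, one row per cell:
#'   `subject`, `channel`, `block`, `age`; raw ratios `tbr`, `tar`, `abr`
#'   and their log10 forms; fitted `fit_offset`, `fit_exponent`,
#'   `fit_r_squared`; per-band fitted peak columns `<band>_cf`,
#'   `<band>_pw`, `<band>_bw` (NA when no peak was assigned);
#'   parameterized ratios `tbr_param`, `tar_param`, `abr_param` (NA when
#'   either peak is absent).
#' @export
cohort_measures <- function(cohort, fit = TRUE,
                            settings = fit_settings(),
                            bands = canonical_bands(),
                            pairs = default_ratio_pairs()) {
  stopifnot(inherits(cohort, "cohort_result"))
  n <- nrow(cohort$truth)
  out <- cohort$truth[, c("subject", "channel", "block", "age")]
  freqs <- cohort$freqs

  # raw band ratios, vectorized over cells
  lin <- 10^cohort$spectra
  band_mean <- function(b) {
    sel <- freqs >= b$low & freqs <= b$high
    rowMeans(lin[, sel, drop = FALSE])
  }
  bp <- lapply(bands, band_mean)
  for (nm in names(pairs)) {
    val <- bp[[pairs[[nm]][1]]] / bp[[pairs[[nm]][2]]]
    out[[nm]] <- val
    out[[paste0("log_", nm)]] <- log10(val)
  }

  fit_cols <- c("fit_offset", "fit_exponent", "fit_r_squared",
                as.vector(outer(names(bands), c("_cf", "_pw", "_bw"),
                                paste0)),
                paste0(names(pairs), "_param"))
  for (cl in fit_cols) out[[cl]] <- NA_real_
  if (fit) {
    for (i in seq_len(n)) {
      ps <- power_spectrum(freqs, cohort$spectra[i, ])
      ft <- fit_spectrum(ps, settings)
      out$fit_offset[i] <- ft$offset
      out$fit_exponent[i] <- ft$exponent
      out$fit_r_squared[i] <- ft$r_squared
      tab <- assign_band_peaks(ft, bands)
      for (bn in tab$band) {
        r <- tab[tab$band == bn, ]
        out[[paste0(bn, "_cf")]][i] <- r$cf
        out[[paste0(bn, "_pw")]][i] <- r$pw
        out[[paste0(bn, "_bw")]][i] <- r$bw
      }
      for (nm in names(pairs)) {
        out[[paste0(nm, "_param")]][i] <-
          parameterized_ratio(tab, pairs[[nm]][1], pairs[[nm]][2])
      }
    }
  }
  class(out) <- c("cohort_measures", "data.frame")
  out
}

#' Aggregate cohort measures to one row per subject
#'
#' Averages each measure across channels (and, if several are kept, across
#' blocks) within subject. Peak parameters of a band are averaged over the
#' cells where that band's peak was detected; a subject's parameterized
#' ratio is kept `NA` unless at least one cell produced it. Alternatively
#' `mode = "pool"` returns the channel-level rows unaggregated (one row
#' per subject x channel), for analyses that pool channels as
#' observations.
#'
#' @param measures A `cohort_measures` table.
#' @param blocks Which blocks to keep before aggregating (default 1, the
#'   first block).
#' @param mode `"average"` (default; one row per subject) or `"pool"`
#'   (one row per subject x channel).
#' @return Data frame with the same measure columns, aggregated.
#' @export
subject_measures <- function(measures, blocks = 1,
                             mode = c("average", "pool")) {
  mode <- match.arg(mode)
  stopifnot(inherits(measures, "data.frame"))
  m <- measures[measures$block %in% blocks, , drop = FALSE]
  if (nrow(m) == 0) stop("no rows left after block selection")
  keys <- if (mode == "average") "subject" else c("subject", "channel")
  num_cols <- setdiff(names(m)[vapply(m, is.numeric, logical(1))],
                      c("subject", "channel", "block"))
  agg <- stats::aggregate(m[num_cols], by = m[keys],
                          FUN = function(v) {
                            v <- v[!is.na(v)]
                            if (length(v) == 0) NA_real_ else mean(v)
                          })
  agg[order(agg$subject), , drop = FALSE]
}

#' Correlations between ratio measures and spectral parameters
#'
#' Spearman correlation with bootstrap CI for each band-ratio measure
#' against each fitted spectral parameter (per-band center frequency,
#' power, and bandwidth, plus the aperiodic exponent). The aperiodic
#' offset is excluded by default since offset shifts by themselves do not
#' affect ratio measures. Missing values (e.g. parameters of undetected
#' peaks) are handled listwise per pair.
#'
#' @param subject_table Output of [subject_measures()] (or any data frame
#'   holding the measure and parameter columns).
#' @param ratios Ratio column names (default raw `tbr`, `tar`, `abr`).
#' @param params Parameter column names; default all `<band>_cf/pw/bw`
#'   present plus `fit_exponent`.
#' @param n_resamples,level,seed Bootstrap settings per cell.
#' @return Tidy data frame: `measure`, `parameter`, `rho`, `ci_low`,
#'   `ci_high`, `p`, `n`. Cells with fewer than 3 complete pairs carry
#'   `NA`s.
#' @export
ratio_param_correlation_table <- function(subject_table,
                                          ratios = c("tbr", "tar", "abr"),
                                          params = NULL,
                                          n_resamples = 5000,
                                          level = 0.95, seed = NULL) {
  if (is.null(params)) {
    cand <- c(as.vector(outer(c("theta", "alpha", "beta"),
                              c("_cf", "_pw", "_bw"), paste0)),
              "fit_exponent")
    params <- intersect(cand, names(subject_table))
  }
  seeds <- derive_seeds_(seed, length(ratios) * length(params))
  rows <- list()
  k <- 0
  for (r in ratios) {
    for (p in params) {
      k <- k + 1
      ci <- bootstrap_ci(subject_table[[r]], subject_table[[p]],
                         n_resamples = n_resamples, level = level,
                         seed = seeds[[k]])
      rows[[k]] <- data.frame(measure = r, parameter = p, rho = ci$rho,
                              ci_low = ci$ci_low, ci_high = ci$ci_high,
                              p = ci$p, n = ci$n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spatial (topography) correlation between two measures
#'
#' Group-averages each measure per channel first, then rank-correlates
#' the two channel profiles — the spatial-similarity comparison of two
#' topographies.
#'
#' @param measures A `cohort_measures` table (any blocks).
#' @param measure_x,measure_y Column names to compare.
#' @param n_resamples,level,seed Bootstrap settings.
#' @return A `correlation_result` across channels.
#' @export
topography_correlation <- function(measures, measure_x, measure_y,
                                   n_resamples = 5000, level = 0.95,
                                   seed = NULL) {
  ch_mean <- function(col) {
    a <- stats::aggregate(measures[[col]],
                          by = list(channel = measures$channel),
                          FUN = function(v) mean(v, na.rm = TRUE))
    a$x[order(a$channel)]
  }
  x <- ch_mean(measure_x)
  y <- ch_mean(measure_y)
  if (length(x) < 3) stop("need at least 3 channels for a topography")
  bootstrap_ci(x, y, n_resamples = n_resamples, level = level, seed = seed)
}

#' Age correlations for ratio measures and spectral parameters
#'
#' Spearman + bootstrap CI of each raw ratio, each parameterized ratio,
#' and the fitted aperiodic exponent against subject age. Parameterized
#' ratios use only the subjects where both band peaks were detected
#' (listwise per measure).
#'
#' @param subject_table Output of [subject_measures()] including an `age`
#'   column.
#' @param measures Columns to correlate with age; default the raw ratios,
#'   the parameterized ratios, and `fit_exponent` (those present).
#' @param n_resamples,level,seed Bootstrap settings.
#' @return Tidy data frame: `measure`, `rho`, `ci_low`, `ci_high`, `p`,
#'   `n`.
#' @export
age_correlation_suite <- function(subject_table, measures = NULL,
                                  n_resamples = 5000, level = 0.95,
                                  seed = NULL) {
  if (is.null(measures)) {
    cand <- c("tbr", "tar", "abr", "tbr_param", "tar_param", "abr_param",
              "fit_exponent")
    measures <- intersect(cand, names(subject_table))
  }
  seeds <- derive_seeds_(seed, length(measures))
  rows <- lapply(seq_along(measures), function(i) {
    ci <- bootstrap_ci(subject_table[[measures[i]]], subject_table$age,
                       n_resamples = n_resamples, level = level,
                       seed = seeds[[i]])
    data.frame(measure = measures[i], rho = ci$rho, ci_low = ci$ci_low,
               ci_high = ci$ci_high, p = ci$p, n = ci$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
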