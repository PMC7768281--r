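#' Frequency band definition
#'
#' @param label Band name (e.g. `"theta"`).
#' @param low,high Band edges in Hz, `0 < low < high`. Edges are treated as
#'   inclusive by all band-power computations in this package.
#' @return An object of class `band`.
#' @export
band <- function(label, low, high) {
  stopifnot(is.character(label), length(label) == 1, low > 0, high > low)
  structure(list(label = label, low = low, high = high), class = "band")
}

#' @export
print.band <- function(x, ...) {
  cat(sprintf("band %s: %g-%g Hz\n", x$label, x$low, x$high))
  invisible(x)
}

#' Canonical EEG frequency bands
#'
#' The band definitions used throughout: theta 4-8 Hz, alpha 8-13 Hz,
#' beta 13-30 Hz. Note that the printed canonical definitions overlap at
#' 8 Hz; with inclusive edges the shared 8 Hz bin belongs to both theta and
#' alpha. Supply custom bands where half-open conventions are wanted.
#'
#' @return Named list of [band()] objects.
#' @export
canonical_bands <- function() {
  list(theta = band("theta", 4, 8),
       alpha = band("alpha", 8, 13),
       beta  = band("beta", 13, 30))
}

#' Mean band power of a spectrum
#'
#' Averages *linear* power (`10^log10power`) over all frequency bins with
#' `low <= f <= high`, endpoints inclusive. Averaging is done on the linear
#' scale, matching the convention of absolute band-power measures.
#'
#' @param spectrum A [power_spectrum()].
#' @param bnd A [band()].
#' @return Mean linear power (au) across the band's bins.
#' @examples
#' ps <- sim_spectrum(spectral_params(0, 1, noise_sd = 0))
#' band_power(ps, band("theta", 4, 8)) # mean of 1/f over 4..8 Hz
#' @export
band_power <- function(spectrum, bnd) {
  stopifnot(inherits(spectrum, "power_spectrum"), inherits(bnd, "band"))
  sel <- spectrum$freqs >= bnd$low & spectrum$freqs <= bnd$high
  if (!any(sel)) {
    stop(sprintf(
      "band %s (%g-%g Hz) has no bins on the spectrum's axis (%g-%g Hz)",
      bnd$label, bnd$low, bnd$high,
      min(spectrum$freqs), max(spectrum$freqs)))
  }
  mean(10^spectrum$power[sel])
}

#' Band ratio measure
#'
#' Mean linear power across the low band divided by mean linear power
#' across the high band (e.g. the theta/beta ratio). The raw value is
#' strictly positive; it is invariant to any constant shift of log10 power
#' (aperiodic offset) and to any positive rescaling of linear power.
#'
#' @param spectrum A [power_spectrum()].
#' @param low_band,high_band [band()] objects.
#' @return An object of class `ratio_measure` with fields `value`,
#'   `low_band`, `high_band`, `log_flag` (FALSE: raw scale).
#' @examples
#' ps <- sim_spectrum(spectral_params(0, 1, noise_sd = 0))
#' compute_ratio(ps, band("theta", 4, 8), band("beta", 13, 30))
#' @export
compute_ratio <- function(spectrum, low_band, high_band) {
  val <- band_power(spectrum, low_band) / band_power(spectrum, high_band)
  structure(list(value = val, low_band = low_band, high_band = high_band,
                 log_flag = FALSE),
            class = "ratio_measure")
}

#' Log-transform a ratio measure
#'
#' Ratio measures typically display skewed distributions and are often
#' log10-transformed before analysis or plotting.
#'
#' @param ratio A `ratio_measure` on the raw scale.
#' @return The measure with `value = log10(value)` and `log_flag = TRUE`.
#' @export
log_ratio <- function(ratio) {
  stopifnot(inherits(ratio, "ratio_measure"))
  if (isTRUE(ratio$log_flag)) stop("ratio is already log-transformed")
  if (!is.finite(ratio$value) || ratio$value <= 0) {
    stop("ratio value must be a positive finite number")
  }
  ratio$value <- log10(ratio$value)
  ratio$log_flag <- TRUE
  ratio
}

#' @export
print.ratio_measure <- function(x, ...) {
  cat(sprintf("%s/%s ratio: %g%s\n", x$low_band$label, x$high_band$label,
              x$value, if (isTRUE(x$log_flag)) " (log10)" else ""))
  invisible(x)
}

#' Table of band-ratio measures for one spectrum
#'
#' Convenience wrapper computing the default ratio set (theta/beta,
#' theta/alpha, alpha/beta) on the canonical bands.
#'
#' @param spectrum A [power_spectrum()].
#' @param bands Named list of [band()] objects (default
#'   [canonical_bands()]).
#' @param pairs List of character pairs `c(low, high)` naming entries of
#'   `bands`.
#' @return Data frame with columns `measure`, `low_band`, `high_band`,
#'   `value`, `log_value`.
#' @export
ratio_table <- function(spectrum, bands = canonical_bands(),
                        pairs = default_ratio_pairs()) {
  rows <- lapply(pairs, function(p) {
    r <- compute_ratio(spectrum, bands[[p[1]]], bands[[p[2]]])
    data.frame(measure = paste0(p[1], "/", p[2]),
               low_band = p[1], high_band = p[2],
               value = r$value, log_value = log10(r$value))
  })
  do.call(rbind, rows)
}

#' Default band-ratio pairs
#'
#' @return List of `c(low, high)` band-name pairs: theta/beta, theta/alpha,
#'   alpha/beta.
#' @export
default_ratio_pairs <- function() {
  list(tbr = c("theta", "beta"),
       tar = c("theta", "alpha"),
       abr = c("alpha", "beta"))
}
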