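#' Frequency axis for simulated power spectra
#'
#' Generates a linearly spaced frequency axis. The default axis spans
#' 1-35 Hz at 0.5 Hz resolution (69 points, both endpoints included), the
#' range over which all simulation experiments in this package operate.
#' Values are generated by count rather than repeated addition so the grid
#' is free of floating-point drift.
#'
#' @param f_min Lowest frequency, Hz. Must be > 0 (log-frequency must be
#'   defined everywhere on the axis).
#' @param f_max Highest frequency, Hz.
#' @param df Frequency resolution, Hz.
#' @return Numeric vector of strictly increasing frequencies in Hz.
#' @examples
#' f <- freq_axis()
#' length(f) # 69
#' @export
freq_axis <- function(f_min = 1, f_max = 35, df = 0.5) {
  stopifnot(f_min > 0, f_max > f_min, df > 0)
  n <- floor((f_max - f_min) / df + 1e-9) + 1
  f_min + df * (0:(n - 1))
}

check_freqs <- function(freqs) {
  if (!is.numeric(freqs) || length(freqs) < 1 || anyNA(freqs)) {
    stop("frequency axis must be a numeric vector without missing values")
  }
  if (any(freqs <= 0)) {
    stop("all frequencies must be > 0 (log-frequency undefined otherwise)")
  }
  if (is.unsorted(freqs, strictly = TRUE)) {
    stop("frequency axis must be strictly increasing")
  }
  invisible(freqs)
}

#' Generative description of one power spectrum
#'
#' Bundles the aperiodic parameters (offset and exponent of the 1/f-like
#' component), a set of Gaussian periodic peaks, and the level of
#' log10-power measurement noise into a single object describing how one
#' spectrum is generated.
#'
#' Peaks are given as a data frame (or coercible matrix/vector) with columns
#' `cf` (center frequency, Hz), `pw` (power above the aperiodic component,
#' au in log10 spacing), and `bw` (bandwidth: the Gaussian width parameter
#' w, Hz).
#'
#' @param offset Aperiodic offset b, log10-power au.
#' @param exponent Aperiodic exponent chi (steepness of the 1/f).
#' @param peaks `NULL` for a pure-aperiodic spectrum, otherwise a
#'   data frame / matrix with columns `cf`, `pw`, `bw`, or a length-3
#'   numeric vector `c(cf, pw, bw)` for a single peak.
#' @param noise_sd Standard deviation of normally distributed noise added
#'   per frequency, in log10-power au. Default 0.005.
#' @return An object of class `spectral_params`.
#' @examples
#' spectral_params(0, 1, peaks = rbind(c(6, 0.5, 1.5), c(10, 0.5, 1.5)))
#' @export
spectral_params <- function(offset = 0, exponent = 1, peaks = NULL,
                            noise_sd = 0.005) {
  stopifnot(is.finite(offset), is.finite(exponent), noise_sd >= 0)
  peaks <- as_peaks(peaks)
  structure(
    list(offset = offset, exponent = exponent, peaks = peaks,
         noise_sd = noise_sd),
    class = "spectral_params"
  )
}

as_peaks <- function(peaks) {
  if (is.null(peaks) || (is.data.frame(peaks) && nrow(peaks) == 0)) {
    return(data.frame(cf = numeric(0), pw = numeric(0), bw = numeric(0)))
  }
  if (is.numeric(peaks) && is.null(dim(peaks))) {
    stopifnot(length(peaks) == 3)
    peaks <- matrix(peaks, nrow = 1)
  }
  peaks <- as.data.frame(peaks)
  if (ncol(peaks) != 3) stop("peaks need three columns: cf, pw, bw")
  names(peaks) <- c("cf", "pw", "bw")
  if (any(peaks$bw <= 0)) stop("peak bandwidth must be > 0")
  if (any(peaks$pw < 0)) stop("peak power must be >= 0")
  if (any(peaks$cf <= 0)) stop("peak center frequency must be > 0")
  peaks
}

#' @export
print.spectral_params <- function(x, ...) {
  cat("Spectral parameters\n")
  cat(sprintf("  aperiodic: offset = %g, exponent = %g\n",
              x$offset, x$exponent))
  if (nrow(x$peaks) == 0) {
    cat("  peaks: none\n")
  } else {
    cat(sprintf("  peaks (%d):\n", nrow(x$peaks)))
    for (i in seq_len(nrow(x$peaks))) {
      cat(sprintf("    cf = %g Hz, pw = %g au, bw = %g Hz\n",
                  x$peaks$cf[i], x$peaks$pw[i], x$peaks$bw[i]))
    }
  }
  cat(sprintf("  noise sd: %g au\n", x$noise_sd))
  invisible(x)
}

#' Power spectrum container
#'
#' The common currency of every stage in the package: a frequency axis plus
#' power values. Power is stored in log10 spacing (au) by default, matching
#' the generative model; linear power is obtained with
#' [spectrum_power_linear()] only where an operation demands it (band
#' averaging, time-series synthesis).
#'
#' @param freqs Strictly increasing positive frequencies, Hz.
#' @param power Power values, same length as `freqs`.
#' @param scale `"log10"` (default) or `"linear"`, describing `power`.
#' @return An object of class `power_spectrum` with power on the log10
#'   scale (linear input is converted; linear power must then be > 0).
#' @export
power_spectrum <- function(freqs, power, scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  check_freqs(freqs)
  if (length(power) != length(freqs)) {
    stop("power and freqs must have the same length")
  }
  if (scale == "linear") {
    if (any(power <= 0)) stop("linear power must be strictly positive")
    power <- log10(power)
  }
  structure(list(freqs = as.numeric(freqs), power = as.numeric(power)),
            class = "power_spectrum")
}

#' Linear-scale power of a spectrum
#'
#' @param spectrum A [power_spectrum()].
#' @return Numeric vector of linear power values, `10^power`.
#' @export
spectrum_power_linear <- function(spectrum) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  10^spectrum$power
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    "Power spectrum: %d bins, %g-%g Hz (log10 power, range %.3g to %.3g au)\n",
    length(x$freqs), min(x$freqs), max(x$freqs),
    min(x$power), max(x$power)))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, log_freq = FALSE, ...) {
  plot(x$freqs, x$power, type = "l",
       log = if (log_freq) "x" else "",
       xlab = "Frequency (Hz)", ylab = "log10 power (au)", ...)
  invisible(x)
}

#' Aperiodic (1/f-like) component of a power spectrum
#'
#' Evaluates the aperiodic component in log10-power spacing:
#' `L(f) = b - chi * log10(f)`, where `b` is the offset and `chi` the
#' exponent. In linear power this is the familiar `1/f^chi` form. At
#' f = 1 Hz the value equals the offset exactly, for any exponent.
#'
#' @param freqs Frequencies, Hz; all must be > 0.
#' @param offset Offset b, log10-power au.
#' @param exponent Exponent chi.
#' @return log10-power values, one per frequency.
#' @examples
#' aperiodic_component(10, offset = 0, exponent = 1) # -1
#' @export
aperiodic_component <- function(freqs, offset, exponent) {
  check_freqs(freqs)
  offset - exponent * log10(freqs)
}

#' Periodic (Gaussian peak) component of a power spectrum
#'
#' Sums the Gaussian contributions of all peaks:
#' `G(f) = sum_n a_n * exp(-(f - c_n)^2 / (2 w_n^2))` in log10-power au,
#' where `c` is the center frequency, `a` the peak power over the aperiodic
#' component, and `w` the bandwidth (Gaussian width). An empty peak set
#' contributes zero everywhere.
#'
#' @param freqs Frequencies, Hz.
#' @param peaks Peaks in any form accepted by [spectral_params()].
#' @return log10-power values, one per frequency.
#' @export
peak_component <- function(freqs, peaks) {
  check_freqs(freqs)
  peaks <- as_peaks(peaks)
  out <- numeric(length(freqs))
  for (i in seq_len(nrow(peaks))) {
    out <- out + peaks$pw[i] *
      exp(-(freqs - peaks$cf[i])^2 / (2 * peaks$bw[i]^2))
  }
  out
}

#' Simulate a neural power spectrum
#'
#' Builds a spectrum as aperiodic component + Gaussian peaks + normally
#' distributed noise, all in log10-power spacing:
#' `P(f) = L(f) + sum_n G_n(f) + e(f)`, `e ~ N(0, noise_sd)` drawn
#' independently per frequency bin. With `noise_sd = 0` the output equals
#' the deterministic model exactly; with a seed the output is reproducible
#' bit for bit.
#'
#' @param params A [spectral_params()] object.
#' @param freqs Frequency axis; defaults to [freq_axis()] (1-35 Hz, 0.5 Hz
#'   steps).
#' @param seed Optional integer seed for the noise draw. The caller's RNG
#'   state is left untouched.
#' @return A [power_spectrum()] (log10 scale).
#' @examples
#' ps <- sim_spectrum(spectral_params(0, 1, noise_sd = 0), seed = 1)
#' @export
sim_spectrum <- function(params, freqs = freq_axis(), seed = NULL) {
  stopifnot(inherits(params, "spectral_params"))
  check_freqs(freqs)
  pow <- aperiodic_component(freqs, params$offset, params$exponent) +
    peak_component(freqs, params$peaks)
  if (params$noise_sd > 0) {
    pow <- pow + with_seed_(seed, stats::rnorm(length(freqs),
                                               sd = params$noise_sd))
  }
  power_spectrum(freqs, pow)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram of a time series, using Hann-windowed
#' segments. Defaults follow the package's resting-state analysis settings:
#' 2-s windows with 25% overlap, giving 0.5 Hz frequency resolution, with
#' the output restricted to 1-35 Hz before downstream use. Segmentation and
#' windowing are delegated to [signal::specgram()]; segments are combined by
#' mean averaging and scaled as a one-sided spectral density
#' (power per Hz), returned in log10 spacing.
#'
#' @param x Numeric time series (voltages, au).
#' @param fs Sampling rate, Hz.
#' @param window_seconds Segment length in seconds (default 2).
#' @param overlap_fraction Fractional overlap between segments (default
#'   0.25).
#' @param f_range Length-2 vector restricting the returned frequencies
#'   (inclusive); `NULL` keeps all positive-frequency bins. Default
#'   `c(1, 35)`.
#' @return A [power_spectrum()] (log10 scale).
#' @export
welch_psd <- function(x, fs, window_seconds = 2, overlap_fraction = 0.25,
                      f_range = c(1, 35)) {
  stopifnot(is.numeric(x), fs > 0,
            window_seconds > 0, overlap_fraction >= 0, overlap_fraction < 1)
  nwin <- round(window_seconds * fs)
  if (length(x) < nwin) {
    stop(sprintf("signal (%d samples) shorter than one %g-s window (%d samples)",
                 length(x), window_seconds, nwin))
  }
  noverlap <- round(overlap_fraction * nwin)
  win <- signal::hanning(nwin)
  sg <- signal::specgram(x, n = nwin, Fs = fs, window = win,
                         overlap = noverlap)
  # one-sided density scaling: 2 |X|^2 / (fs * sum(win^2)); DC and Nyquist
  # bins are not doubled
  pxx <- rowMeans(Mod(sg$S)^2) / (fs * sum(win^2))
  freqs <- as.numeric(sg$f)
  one_sided <- rep(2, length(freqs))
  one_sided[freqs == 0] <- 1
  one_sided[abs(freqs - fs / 2) < 1e-9] <- 1
  pxx <- pxx * one_sided
  keep <- freqs > 0
  if (!is.null(f_range)) {
    keep <- keep & freqs >= f_range[1] & freqs <= f_range[2]
  }
  if (!any(keep)) stop("no frequency bins left after restricting the range")
  power_spectrum(freqs[keep], pxx[keep], scale = "linear")
}

# Evaluate an expression with a temporary RNG state. NULL seed means use
# (and advance) the caller's RNG as-is.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
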