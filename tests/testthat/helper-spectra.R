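# Shared fixture builders for the test suite. Everything is generated in
# code at test time; no stored data.

# Randomized generative parameters for the fit-recovery suite: 0-3 peaks
# with widths inside the default fit bounds, centers away from the axis
# edges, and pairwise separation of at least twice the summed widths so
# peaks are well separated relative to their spread.
random_recovery_params <- function(n_peaks = NULL) {
  if (is.null(n_peaks)) n_peaks <- sample(0:3, 1)
  cfs <- numeric(0); bws <- numeric(0); tries <- 0
  while (length(cfs) < n_peaks && tries < 1000) {
    tries <- tries + 1
    cf <- stats::runif(1, 4, 28)
    bw <- stats::runif(1, 1, 2)
    if (all(abs(cf - cfs) > 2 * (bw + bws))) {
      cfs <- c(cfs, cf); bws <- c(bws, bw)
    }
  }
  peaks <- if (length(cfs) > 0) {
    cbind(cfs, stats::runif(length(cfs), 0.3, 1), bws)
  } else NULL
  spectral_params(offset = stats::runif(1, -1, 1),
                  exponent = stats::runif(1, 0.5, 2.5),
                  peaks = peaks, noise_sd = 0)
}

# Largest center-frequency recovery error of a fit against the generating
# peaks (0 when there were no peaks; Inf when all were missed).
max_cf_error <- function(fit, params) {
  true_cf <- params$peaks$cf
  if (length(true_cf) == 0) return(0)
  if (nrow(fit$peaks) == 0) return(Inf)
  max(vapply(true_cf,
             function(cf) min(abs(fit$peaks$cf - cf)), numeric(1)))
}

# Flat spectrum with constant linear power p over the default axis
flat_spectrum <- function(p = 1, freqs = freq_axis()) {
  power_spectrum(freqs, rep(log10(p), length(freqs)))
}

# Cohort config scaled down for unit tests: few subjects/channels, one
# block, deterministic spectra
tiny_cohort_config <- function(...) {
  cohort_config(n_subjects = 8, n_channels = 3, n_blocks = 2,
                noise_sd = 0, ...)
}

tbr_of <- function(sweep) sweep$ratio[sweep$measure == "theta/beta"]
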