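#' Configuration for a synthetic resting-state EEG cohort
#'
#' Describes a hierarchical generative model for a cohort of subjects x
#' channels x blocks of eyes-closed resting power spectra, with ground
#' truth stored alongside every simulated spectrum. The default shape
#' mirrors a developmental resting-state EEG study: 111 subjects (ages
#' drawn from a truncated normal, mean 15.79, SD 8.03, range 6-44 years),
#' 111 channels, 5 resting blocks, spectra over 1-35 Hz built from an
#' aperiodic component plus theta/alpha/beta peaks, a negative
#' exponent-age association, and dominant, variable alpha power.
#'
#' The hierarchy: each subject draws an age, an aperiodic offset and
#' exponent (the exponent includes an age slope), and per-band peak
#' presence (Bernoulli per `*_prevalence`) and parameters. Channel
#' structure is a smooth cosine gradient over the ordered channel index
#' that multiplicatively modulates the exponent and alpha power. Blocks
#' add within-subject jitter to each parameter. All SDs are in the
#' parameter's own units (Hz for cf/bw, log10-power au otherwise).
#'
#' @param n_subjects,n_channels,n_blocks Cohort dimensions.
#' @param age_mean,age_sd,age_range Truncated-normal age model (years).
#' @param exponent_mean Population mean exponent at the mean age.
#' @param exponent_age_slope Change in exponent per year of age (negative:
#'   the spectrum flattens with age).
#' @param exponent_sd Between-subject exponent SD around the age trend.
#' @param offset_mean,offset_sd Between-subject aperiodic offset model.
#' @param theta,alpha,beta Per-band peak models: lists with
#'   `prevalence` and `cf_mean`, `cf_sd`, `cf_range`, `pw_mean`, `pw_sd`,
#'   `pw_min`, `bw_mean`, `bw_sd`, `bw_range`.
#' @param channel_gradient_exponent,channel_gradient_alpha_pw Relative
#'   amplitude of the cosine channel gradient applied multiplicatively to
#'   the exponent and to alpha peak power.
#' @param block_jitter_sd Named list of within-subject, between-block SDs:
#'   `exponent`, `offset`, `cf`, `pw`, `bw`.
#' @param noise_sd Per-frequency log10-power noise in each simulated
#'   spectrum.
#' @param freqs Frequency axis for the simulated spectra.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 111, n_channels = 111, n_blocks = 5,
                          age_mean = 15.79, age_sd = 8.03,
                          age_range = c(6, 44),
                          exponent_mean = 1.5,
                          exponent_age_slope = -0.02,
                          exponent_sd = 0.15,
                          offset_mean = 0, offset_sd = 0.3,
                          theta = peak_model(prevalence = 0.6,
                                             cf_mean = 6, cf_sd = 0.75,
                                             cf_range = c(4, 8),
                                             pw_mean = 0.4, pw_sd = 0.15,
                                             pw_min = 0.15,
                                             bw_mean = 1.5, bw_sd = 0.25,
                                             bw_range = c(1, 3)),
                          alpha = peak_model(prevalence = 1.0,
                                             cf_mean = 10, cf_sd = 1,
                                             cf_range = c(8, 13),
                                             pw_mean = 0.8, pw_sd = 0.25,
                                             pw_min = 0.2,
                                             bw_mean = 2, bw_sd = 0.4,
                                             bw_range = c(1, 4)),
                          beta = peak_model(prevalence = 0.6,
                                            cf_mean = 21.5, cf_sd = 3,
                                            cf_range = c(13, 30),
                                            pw_mean = 0.35, pw_sd = 0.12,
                                            pw_min = 0.15,
                                            bw_mean = 2, bw_sd = 0.5,
                                            bw_range = c(1, 4)),
                          channel_gradient_exponent = 0.1,
                          channel_gradient_alpha_pw = 0.2,
                          block_jitter_sd = list(exponent = 0.05,
                                                 offset = 0.05,
                                                 cf = 0.2, pw = 0.05,
                                                 bw = 0.1),
                          noise_sd = 0.005,
                          freqs = freq_axis()) {
  if (n_subjects < 1 || n_channels < 1 || n_blocks < 1) {
    stop("cohort needs at least one subject, channel, and block")
  }
  for (pm in list(theta, alpha, beta)) {
    stopifnot(pm$prevalence >= 0, pm$prevalence <= 1)
  }
  stopifnot(exponent_sd >= 0, offset_sd >= 0, noise_sd >= 0,
            age_range[1] < age_range[2])
  structure(
    list(n_subjects = n_subjects, n_channels = n_channels,
         n_blocks = n_blocks,
         age_mean = age_mean, age_sd = age_sd, age_range = age_range,
         exponent_mean = exponent_mean,
         exponent_age_slope = exponent_age_slope,
         exponent_sd = exponent_sd,
         offset_mean = offset_mean, offset_sd = offset_sd,
         bands = list(theta = theta, alpha = alpha, beta = beta),
         channel_gradient_exponent = channel_gradient_exponent,
         channel_gradient_alpha_pw = channel_gradient_alpha_pw,
         block_jitter_sd = block_jitter_sd,
         noise_sd = noise_sd, freqs = freqs),
    class = "cohort_config")
}

#' Per-band peak model for the cohort generator
#'
#' @param prevalence Probability that a subject expresses a peak in this
#'   band.
#' @param cf_mean,cf_sd,cf_range Center-frequency distribution (normal,
#'   clamped to `cf_range`), Hz.
#' @param pw_mean,pw_sd,pw_min Peak-power distribution (normal, floored at
#'   `pw_min`), log10-power au.
#' @param bw_mean,bw_sd,bw_range Bandwidth distribution (normal, clamped),
#'   Hz.
#' @return A plain list with the model's fields.
#' @export
peak_model <- function(prevalence, cf_mean, cf_sd, cf_range,
                       pw_mean, pw_sd, pw_min, bw_mean, bw_sd, bw_range) {
  list(prevalence = prevalence, cf_mean = cf_mean, cf_sd = cf_sd,
       cf_range = cf_range, pw_mean = pw_mean, pw_sd = pw_sd,
       pw_min = pw_min, bw_mean = bw_mean, bw_sd = bw_sd,
       bw_range = bw_range)
}

# Moments of a normal truncated to [a, b]
truncnorm_moments_ <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  z <- stats::pnorm(be) - stats::pnorm(al)
  d <- (stats::dnorm(al) - stats::dnorm(be)) / z
  m <- mu + sigma * d
  v <- sigma^2 *
    (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / z - d^2)
  c(mean = m, sd = sqrt(v))
}

# Underlying (mu, sigma) such that the [a, b]-truncated normal has the
# requested mean and SD. The config states the observed moments of the
# bounded age distribution, not the latent parameters.
truncnorm_params_ <- function(mean, sd, a, b) {
  obj <- function(p) {
    mo <- truncnorm_moments_(p[1], exp(p[2]), a, b)
    (mo[1] - mean)^2 + (mo[2] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

rtruncnorm_ <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

clamp_ <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic EEG cohort
#'
#' Draws a full cohort from a [cohort_config()]: subject ages and
#' subject-level spectral parameters, channel-gradient modulation, block
#' jitter, and one simulated power spectrum per (subject, channel, block)
#' cell. The ground-truth generating parameters of every cell are stored
#' losslessly alongside the spectra.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the same seed reproduces the cohort bit for
#'   bit.
#' @return An object of class `cohort_result`: `ages` (per subject,
#'   years), `truth` (data frame, one row per cell: `subject`, `channel`,
#'   `block`, `age`, `offset`, `exponent`, and `cf`/`pw`/`bw` per band,
#'   `NA` where the subject lacks that peak), `spectra` (matrix, one row
#'   per `truth` row, columns = frequency bins, log10 power), `freqs`,
#'   `config`, `seed`.
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed_(seed, generate_cohort_(config, seed))
}

generate_cohort_ <- function(config, seed) {
  ns <- config$n_subjects; nc <- config$n_channels; nb <- config$n_blocks
  freqs <- config$freqs
  age_par <- truncnorm_params_(config$age_mean, config$age_sd,
                               config$age_range[1], config$age_range[2])
  ages <- rtruncnorm_(ns, age_par[1], age_par[2],
                      config$age_range[1], config$age_range[2])

  # subject-level aperiodic parameters; exponent carries the age slope
  exp_subj <- config$exponent_mean +
    config$exponent_age_slope * (ages - config$age_mean) +
    stats::rnorm(ns, sd = config$exponent_sd)
  exp_subj <- pmax(exp_subj, 0.1)
  off_subj <- stats::rnorm(ns, config$offset_mean, config$offset_sd)

  # subject-level peaks
  band_names <- names(config$bands)
  subj_peaks <- lapply(band_names, function(bn) {
    bm <- config$bands[[bn]]
    present <- stats::runif(ns) < bm$prevalence
    data.frame(
      present = present,
      cf = clamp_(stats::rnorm(ns, bm$cf_mean, bm$cf_sd),
                  bm$cf_range[1], bm$cf_range[2]),
      pw = pmax(stats::rnorm(ns, bm$pw_mean, bm$pw_sd), bm$pw_min),
      bw = clamp_(stats::rnorm(ns, bm$bw_mean, bm$bw_sd),
                  bm$bw_range[1], bm$bw_range[2]))
  })
  names(subj_peaks) <- band_names

  # smooth cosine gradient across the ordered channel index, scaled to a
  # multiplicative factor 1 +/- amplitude
  grad <- if (nc == 1) 0 else cos(pi * (seq_len(nc) - 1) / (nc - 1))
  fac_exp <- 1 + config$channel_gradient_exponent * grad
  fac_apw <- 1 + config$channel_gradient_alpha_pw * grad

  jit <- config$block_jitter_sd
  n_cells <- ns * nc * nb
  truth <- data.frame(
    subject = rep(seq_len(ns), each = nc * nb),
    channel = rep(rep(seq_len(nc), each = nb), times = ns),
    block = rep(seq_len(nb), times = ns * nc))
  truth$age <- ages[truth$subject]
  truth$offset <- off_subj[truth$subject] +
    stats::rnorm(n_cells, sd = jit$offset)
  truth$exponent <- pmax(
    exp_subj[truth$subject] * fac_exp[truth$channel] +
      stats::rnorm(n_cells, sd = jit$exponent), 0.05)

  for (bn in band_names) {
    sp <- subj_peaks[[bn]]
    bm <- config$bands[[bn]]
    present <- sp$present[truth$subject]
    cf <- clamp_(sp$cf[truth$subject] + stats::rnorm(n_cells, sd = jit$cf),
                 bm$cf_range[1], bm$cf_range[2])
    pw <- sp$pw[truth$subject]
    if (bn == "alpha") pw <- pw * fac_apw[truth$channel]
    pw <- pmax(pw + stats::rnorm(n_cells, sd = jit$pw), bm$pw_min / 2)
    bw <- clamp_(sp$bw[truth$subject] + stats::rnorm(n_cells, sd = jit$bw),
                 bm$bw_range[1], bm$bw_range[2])
    truth[[paste0(bn, "_cf")]] <- ifelse(present, cf, NA_real_)
    truth[[paste0(bn, "_pw")]] <- ifelse(present, pw, NA_real_)
    truth[[paste0(bn, "_bw")]] <- ifelse(present, bw, NA_real_)
  }

  # simulate spectra: deterministic model per cell + per-bin noise
  lf <- log10(freqs)
  spectra <- outer(truth$offset, rep(1, length(freqs))) -
    outer(truth$exponent, lf)
  for (bn in band_names) {
    cf <- truth[[paste0(bn, "_cf")]]
    pw <- truth[[paste0(bn, "_pw")]]
    bw <- truth[[paste0(bn, "_bw")]]
    has <- !is.na(cf)
    if (any(has)) {
      g <- pw[has] * exp(-outer(cf[has], freqs, function(c, f)
        (f - c)^2) / (2 * bw[has]^2))
      spectra[has, ] <- spectra[has, ] + g
    }
  }
  if (config$noise_sd > 0) {
    spectra <- spectra + matrix(stats::rnorm(length(spectra),
                                             sd = config$noise_sd),
                                nrow = n_cells)
  }

  structure(list(ages = ages, truth = truth, spectra = spectra,
                 freqs = freqs, config = config, seed = seed),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf(
    "Synthetic EEG cohort: %d subjects x %d channels x %d blocks (%d spectra)\n",
    x$config$n_subjects, x$config$n_channels, x$config$n_blocks,
    nrow(x$spectra)))
  cat(sprintf("  ages %.1f-%.1f years (mean %.2f)\n",
              min(x$ages), max(x$ages), mean(x$ages)))
  invisible(x)
}

#' Extract one cell's spectrum from a cohort
#'
#' @param cohort A `cohort_result`.
#' @param subject,channel,block Cell indices.
#' @return A [power_spectrum()].
#' @export
cohort_spectrum <- function(cohort, subject, channel = 1, block = 1) {
  i <- which(cohort$truth$subject == subject &
               cohort$truth$channel == channel &
               cohort$truth$block == block)
  if (length(i) != 1) stop("no such cohort cell")
  power_spectrum(cohort$freqs, cohort$spectra[i, ])
}

#' Synthesize a time series with a target power spectrum
#'
#' Random-phase inverse-spectral synthesis: the target model (aperiodic
#' plus peaks, or an explicit spectrum) is evaluated as a linear power
#' spectral density at every positive Fourier frequency of the output
#' signal; each Fourier component receives amplitude
#' `sqrt(2 * PSD(f) * df)` and an independent uniform random phase, and
#' the signal is the inverse transform. The Welch PSD of the result
#' matches the target (in log10 au) up to estimator noise, so the
#' time-series path of the pipeline can be tested end to end.
#'
#' @param params A [spectral_params()] describing the target (its
#'   `noise_sd` is ignored: estimator noise arises naturally), or a
#'   [power_spectrum()] to be interpolated onto the Fourier frequencies
#'   (model evaluation outside an explicit spectrum's range uses its edge
#'   values).
#' @param fs Sampling rate, Hz; must be at least 70 so that activity up to
#'   35 Hz is representable. Default 500.
#' @param duration Signal length in seconds, default 30 (one resting-state
#'   block's usable segment).
#' @param seed Integer seed for the phase draws.
#' @return Numeric time series of `fs * duration` samples (au).
#' @export
synth_time_series <- function(params, fs = 500, duration = 30,
                              seed = NULL) {
  if (fs < 70) stop("fs must be at least 70 Hz to represent 35 Hz activity")
  n <- round(fs * duration)
  if (n < 2 * fs) stop("duration must cover at least one 2-s Welch window")
  df <- fs / n
  f_pos <- df * seq_len(floor((n - 1) / 2))
  if (inherits(params, "power_spectrum")) {
    lin <- stats::approx(params$freqs, 10^params$power, xout = f_pos,
                         rule = 2)$y
  } else if (inherits(params, "spectral_params")) {
    lin <- 10^(aperiodic_component(f_pos, params$offset, params$exponent) +
                 peak_component(f_pos, params$peaks))
  } else {
    stop("params must be spectral_params or a power_spectrum")
  }
  amp <- sqrt(2 * lin * df)
  phase <- with_seed_(seed, stats::runif(length(f_pos), 0, 2 * pi))
  z <- complex(modulus = amp * n / 2, argument = phase)
  spec <- complex(real = numeric(n))
  spec[1 + seq_along(f_pos)] <- z
  spec[n + 1 - seq_along(f_pos)] <- Conj(z)
  Re(stats::fft(spec, inverse = TRUE)) / n
}
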