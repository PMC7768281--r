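#' Default simulation parameters for sweep experiments
#'
#' The baseline spectrum for all parameter sweeps: offset 0, exponent 1,
#' and one peak per canonical band — theta at 6 Hz, alpha at 10 Hz, beta at
#' 21.5 Hz — each with power 0.5 au and bandwidth 0.1 Hz.
#'
#' @param noise_sd Noise level for the baseline (default 0, so sweep
#'   results are deterministic; pass 0.005 for the noisy variant).
#' @return A [spectral_params()] object.
#' @export
default_sim_params <- function(noise_sd = 0) {
  spectral_params(
    offset = 0, exponent = 1,
    peaks = rbind(theta = c(6, 0.5, 0.1),
                  alpha = c(10, 0.5, 0.1),
                  beta  = c(21.5, 0.5, 0.1)),
    noise_sd = noise_sd)
}

#' Sweep grid definitions for every spectral parameter
#'
#' One row per sweepable parameter: center frequency, power, and bandwidth
#' of the theta, alpha, and beta peaks, plus the aperiodic offset and
#' exponent. Each has a default (used when the parameter is held fixed), a
#' range, and an increment defining its sweep grid; grids include both
#' endpoints. Note the bandwidth rows carry a default (0.1 Hz) that lies
#' outside their own sweep range (0.2-0.4 Hz); the values are used as
#' given.
#'
#' @return Data frame with columns `param`, `band`, `field`, `default`,
#'   `start`, `stop`, `step`.
#' @export
sweep_param_table <- function() {
  data.frame(
    param = c("theta_cf", "theta_pw", "theta_bw",
              "alpha_cf", "alpha_pw", "alpha_bw",
              "beta_cf", "beta_pw", "beta_bw",
              "offset", "exponent"),
    band = c(rep("theta", 3), rep("alpha", 3), rep("beta", 3), NA, NA),
    field = c(rep(c("cf", "pw", "bw"), 3), "offset", "exponent"),
    default = c(6, 0.5, 0.1, 10, 0.5, 0.1, 21.5, 0.5, 0.1, 0, 1),
    start = c(4, 0, 0.2, 8, 0, 0.2, 13, 0, 0.2, 0, 0),
    stop = c(8, 1, 0.4, 13, 1, 0.4, 30, 1, 0.4, 2.5, 3),
    step = c(0.25, 0.1, 0.2, 0.25, 0.1, 0.2, 1, 0.1, 0.2, 0.25, 0.2),
    stringsAsFactors = FALSE)
}

#' Grid of values for one parameter's sweep
#'
#' @param param A parameter id from [sweep_param_table()].
#' @return Numeric vector `start, start + step, ..., stop` (endpoints
#'   included; generated by count to avoid float drift).
#' @export
sweep_grid <- function(param) {
  tab <- sweep_param_table()
  row <- tab[tab$param == param, ]
  if (nrow(row) != 1) {
    stop(sprintf("unknown sweep parameter '%s'; see sweep_param_table()",
                 param))
  }
  n <- floor((row$stop - row$start) / row$step + 1e-9) + 1
  row$start + row$step * (0:(n - 1))
}

# Return base params with one named parameter replaced. Peak rows in the
# default baseline are named after their bands.
set_sweep_param_ <- function(base, param, value) {
  tab <- sweep_param_table()
  row <- tab[tab$param == param, ]
  if (nrow(row) != 1) stop(sprintf("unknown sweep parameter '%s'", param))
  if (row$field %in% c("offset", "exponent")) {
    base[[row$field]] <- value
  } else {
    i <- match(row$band, rownames(base$peaks))
    if (is.na(i)) {
      stop(sprintf("base parameters have no '%s' peak to vary", row$band))
    }
    base$peaks[i, row$field] <- value
  }
  base
}

#' Single-parameter simulation sweep
#'
#' Simulates one spectrum per grid value, varying a single spectral
#' parameter while all others stay at their defaults, and computes the
#' band-ratio measures at each grid point. With `noise_sd = 0` the sweep is
#' fully deterministic.
#'
#' @param param Parameter id from [sweep_param_table()].
#' @param values Grid values; defaults to [sweep_grid()] for `param`.
#' @param base Baseline [spectral_params()]; defaults to
#'   [default_sim_params()].
#' @param bands,pairs Band definitions and ratio pairs (see
#'   [ratio_table()]).
#' @param noise_sd Noise SD overriding the baseline's (default 0).
#' @param seed Seed for the noise draws (one independent draw per grid
#'   point); ignored when `noise_sd = 0`.
#' @param freqs Frequency axis.
#' @return Data frame of class `sweep_result`, long format: `param`,
#'   `value`, `measure`, `ratio`, `log_ratio`.
#' @examples
#' sw <- single_param_sweep("exponent")
#' subset(sw, measure == "theta/beta")
#' @export
single_param_sweep <- function(param, values = NULL,
                               base = default_sim_params(),
                               bands = canonical_bands(),
                               pairs = default_ratio_pairs(),
                               noise_sd = 0, seed = NULL,
                               freqs = freq_axis()) {
  if (is.null(values)) values <- sweep_grid(param)
  if (length(values) == 0) stop("empty sweep grid")
  base$noise_sd <- noise_sd
  seeds <- derive_seeds_(seed, length(values))
  rows <- lapply(seq_along(values), function(i) {
    p <- set_sweep_param_(base, param, values[i])
    ps <- sim_spectrum(p, freqs = freqs, seed = seeds[[i]])
    rt <- ratio_table(ps, bands = bands, pairs = pairs)
    data.frame(param = param, value = values[i],
               measure = rt$measure, ratio = rt$value,
               log_ratio = rt$log_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- seed
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Paired-parameter simulation sweep
#'
#' Varies two spectral parameters simultaneously over the full Cartesian
#' product of their grids, computing band-ratio measures at every cell.
#' Ratio values are reported both raw and log10-transformed; the log10
#' form is the conventional one for visualizing these skewed surfaces.
#'
#' @param param1,param2 Distinct parameter ids from
#'   [sweep_param_table()].
#' @param values1,values2 Grid values (default: each parameter's
#'   [sweep_grid()]).
#' @inheritParams single_param_sweep
#' @return Data frame of class `grid_result`, long format: `param1`,
#'   `value1`, `param2`, `value2`, `measure`, `ratio`, `log_ratio`.
#' @export
paired_param_sweep <- function(param1, param2,
                               values1 = NULL, values2 = NULL,
                               base = default_sim_params(),
                               bands = canonical_bands(),
                               pairs = default_ratio_pairs(),
                               noise_sd = 0, seed = NULL,
                               freqs = freq_axis()) {
  if (identical(param1, param2)) {
    stop("paired sweep requires two distinct parameters")
  }
  if (is.null(values1)) values1 <- sweep_grid(param1)
  if (is.null(values2)) values2 <- sweep_grid(param2)
  base$noise_sd <- noise_sd
  cells <- expand.grid(value1 = values1, value2 = values2,
                       KEEP.OUT.ATTRS = FALSE)
  seeds <- derive_seeds_(seed, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    p <- set_sweep_param_(base, param1, cells$value1[i])
    p <- set_sweep_param_(p, param2, cells$value2[i])
    ps <- sim_spectrum(p, freqs = freqs, seed = seeds[[i]])
    rt <- ratio_table(ps, bands = bands, pairs = pairs)
    data.frame(param1 = param1, value1 = cells$value1[i],
               param2 = param2, value2 = cells$value2[i],
               measure = rt$measure, ratio = rt$value,
               log_ratio = rt$log_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- seed
  class(out) <- c("grid_result", "data.frame")
  out
}

#' Census of parameters that alter a band ratio
#'
#' Sweeps each parameter in `params` over its grid (noise disabled) and
#' asks whether the ratio measure changes: a parameter "alters" the ratio
#' when the range of ratio values across its sweep, relative to the
#' baseline ratio, exceeds `tolerance`. The default parameter set is the
#' ten-parameter enumeration used for the theta/beta census: center
#' frequency, power, and bandwidth of the theta and beta peaks, alpha
#' center frequency and alpha power, aperiodic offset, and aperiodic
#' exponent. Alpha bandwidth, whose influence is real but bookkept
#' separately, can be added explicitly.
#'
#' @param params Character vector of parameter ids.
#' @param base Baseline [spectral_params()].
#' @param pair Length-2 character vector naming the low and high band of
#'   the ratio (default theta/beta).
#' @param bands Band definitions.
#' @param tolerance Relative-change threshold for "alters" (default 1e-6:
#'   far above float error, below any genuine effect at the default
#'   parameter values).
#' @param freqs Frequency axis.
#' @return List with `count` (number of altering parameters), `verdicts`
#'   (data frame `param`, `rel_range`, `affected`), and `unaffected`
#'   (character vector).
#' @export
count_affected_params <- function(params = census_params(),
                                  base = default_sim_params(),
                                  pair = c("theta", "beta"),
                                  bands = canonical_bands(),
                                  tolerance = 1e-6,
                                  freqs = freq_axis()) {
  base$noise_sd <- 0
  base_spec <- sim_spectrum(base, freqs = freqs)
  baseline <- compute_ratio(base_spec, bands[[pair[1]]],
                            bands[[pair[2]]])$value
  measure <- paste0(pair[1], "/", pair[2])
  verdicts <- lapply(params, function(p) {
    sw <- single_param_sweep(p, base = base, bands = bands,
                             pairs = list(pair), noise_sd = 0,
                             freqs = freqs)
    vals <- sw$ratio[sw$measure == measure]
    rel <- (max(vals) - min(vals)) / baseline
    data.frame(param = p, rel_range = rel, affected = rel > tolerance)
  })
  verdicts <- do.call(rbind, verdicts)
  list(count = sum(verdicts$affected),
       verdicts = verdicts,
       unaffected = verdicts$param[!verdicts$affected])
}

#' The ten-parameter census set
#'
#' @return Character vector of the ten parameter ids counted in the
#'   theta/beta parameter-effect census: theta and beta center frequency,
#'   power, and bandwidth; alpha center frequency and power; aperiodic
#'   offset and exponent.
#' @export
census_params <- function() {
  c("theta_cf", "theta_pw", "theta_bw",
    "beta_cf", "beta_pw", "beta_bw",
    "alpha_cf", "alpha_pw",
    "offset", "exponent")
}

# Derive per-draw seeds from one master seed (NULL stays NULL throughout).
derive_seeds_ <- function(seed, n) {
  if (is.null(seed)) return(vector("list", n))
  as.list(with_seed_(seed, sample.int(.Machine$integer.max, n)))
}
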