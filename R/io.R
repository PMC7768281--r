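#' Write a power spectrum to delimited text
#'
#' Two-column CSV with header `frequency_hz, log10_power`; values are
#' written with 6 significant digits.
#'
#' @param spectrum A [power_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  df <- data.frame(frequency_hz = signif(spectrum$freqs, 6),
                   log10_power = signif(spectrum$power, 6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a power spectrum from delimited text
#'
#' Expects the format written by [write_spectrum()]: a header line and two
#' numeric columns (frequency in Hz, log10 power). Frequencies must be
#' strictly increasing and positive; violations are reported with the
#' offending line number.
#'
#' @param path Input file path.
#' @return A [power_spectrum()].
#' @export
read_spectrum <- function(path) {
  df <- tryCatch(utils::read.csv(path, header = TRUE),
                 error = function(e) stop(sprintf(
                   "cannot parse '%s': %s", path, conditionMessage(e))))
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop(sprintf("'%s' has no spectrum rows (need two columns and a header)",
                 path))
  }
  f <- suppressWarnings(as.numeric(df[[1]]))
  p <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(f) || anyNA(p)) {
    bad <- which(is.na(f) | is.na(p))[1]
    stop(sprintf("non-numeric value in '%s' at data line %d", path, bad))
  }
  if (any(f <= 0)) {
    stop(sprintf("non-positive frequency in '%s' at data line %d",
                 path, which(f <= 0)[1]))
  }
  if (is.unsorted(f, strictly = TRUE)) {
    bad <- which(diff(f) <= 0)[1] + 1
    stop(sprintf(
      "frequencies not strictly increasing in '%s' at data line %d",
      path, bad))
  }
  power_spectrum(f, p)
}

#' Run a configured analysis pipeline
#'
#' Executes the package's stages from a single structured configuration
#' and writes each stage's results plus a JSON run manifest to an output
#' directory. Supported stages (run in the order given): `"simulate"`
#' (one spectrum from `$simulate` parameters), `"sweep"` (single- or
#' paired-parameter sweeps per `$sweep`), `"fit"` (parameterize a
#' spectrum file per `$fit`), `"cohort"` (generate a cohort and its
#' measures per `$cohort`), `"analyze"` (correlation tables on the cohort
#' measures per `$analyze`). One global seed spawns per-stage sub-seeds
#' deterministically, so stages are individually reproducible; every
#' result file is traceable through the manifest, which records the
#' configuration, seeds, and package version.
#'
#' @param config A named list, or a path to a JSON or YAML file holding
#'   one. Recognized top-level fields: `stages` (character vector),
#'   `seed` (integer), plus one list per stage as described above.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config_(config)
  }
  if (!is.list(config)) stop("config must be a list or a path to one")
  stages <- config$stages
  if (is.null(stages) || length(stages) == 0) {
    stop("config field 'stages' is missing or empty")
  }
  bad <- setdiff(stages, c("simulate", "sweep", "fit", "cohort", "analyze"))
  if (length(bad) > 0) {
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  stage_seeds <- derive_seeds_(seed, length(stages))
  names(stage_seeds) <- stages
  outputs <- character(0)
  state <- new.env(parent = emptyenv())

  for (i in seq_along(stages)) {
    st <- stages[i]
    ss <- stage_seeds[[i]]
    outputs <- c(outputs, switch(
      st,
      simulate = stage_simulate_(config$simulate, ss, out_dir),
      sweep = stage_sweep_(config$sweep, ss, out_dir),
      fit = stage_fit_(config$fit, out_dir),
      cohort = stage_cohort_(config$cohort, ss, out_dir, state),
      analyze = stage_analyze_(config$analyze, ss, out_dir, state)))
  }

  manifest <- list(
    package = "bandratios",
    version = as.character(utils::packageVersion("bandratios")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    stage_seeds = stage_seeds,
    stages = stages,
    config = config,
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(manifest)
}

read_config_ <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

params_from_config_ <- function(cfg) {
  peaks <- cfg$peaks
  if (!is.null(peaks) && is.list(peaks) && !is.data.frame(peaks)) {
    peaks <- do.call(rbind, lapply(peaks, unlist))
  }
  spectral_params(offset = cfg$offset %||% 0,
                  exponent = cfg$exponent %||% 1,
                  peaks = peaks,
                  noise_sd = cfg$noise_sd %||% 0.005)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_simulate_ <- function(cfg, seed, out_dir) {
  cfg <- cfg %||% list()
  ps <- sim_spectrum(params_from_config_(cfg), seed = seed)
  path <- file.path(out_dir, "spectrum.csv")
  write_spectrum(ps, path)
  path
}

stage_sweep_ <- function(cfg, seed, out_dir) {
  cfg <- cfg %||% list()
  noise <- cfg$noise_sd %||% 0
  if (!is.null(cfg$param2)) {
    res <- paired_param_sweep(cfg$param, cfg$param2,
                              values1 = cfg$values, values2 = cfg$values2,
                              noise_sd = noise, seed = seed)
    path <- file.path(out_dir,
                      sprintf("sweep_%s_x_%s.csv", cfg$param, cfg$param2))
  } else {
    param <- cfg$param %||% "exponent"
    res <- single_param_sweep(param, values = cfg$values,
                              noise_sd = noise, seed = seed)
    path <- file.path(out_dir, sprintf("sweep_%s.csv", param))
  }
  utils::write.csv(res, path, row.names = FALSE)
  path
}

stage_fit_ <- function(cfg, out_dir) {
  if (is.null(cfg$spectrum)) stop("fit stage needs config field 'spectrum'")
  ps <- read_spectrum(cfg$spectrum)
  settings <- do.call(fit_settings, cfg$settings %||% list())
  ft <- fit_spectrum(ps, settings)
  row <- data.frame(offset = ft$offset, exponent = ft$exponent,
                    n_peaks = nrow(ft$peaks),
                    r_squared = ft$r_squared, fit_error = ft$fit_error)
  for (i in seq_len(nrow(ft$peaks))) {
    row[[paste0("peak", i, "_cf")]] <- ft$peaks$cf[i]
    row[[paste0("peak", i, "_pw")]] <- ft$peaks$pw[i]
    row[[paste0("peak", i, "_bw")]] <- ft$peaks$bw[i]
  }
  path <- file.path(out_dir, "fit.csv")
  utils::write.csv(row, path, row.names = FALSE)
  jsonlite::write_json(unclass(settings),
                       file.path(out_dir, "fit_settings.json"),
                       auto_unbox = TRUE, digits = NA)
  c(path, file.path(out_dir, "fit_settings.json"))
}

stage_cohort_ <- function(cfg, seed, out_dir, state) {
  cfg <- cfg %||% list()
  cc <- do.call(cohort_config, cfg[setdiff(names(cfg), "fit")] %||% list())
  cohort <- generate_cohort(cc, seed = seed)
  measures <- cohort_measures(cohort, fit = isTRUE(cfg$fit %||% TRUE))
  state$cohort <- cohort
  state$measures <- measures
  truth_path <- file.path(out_dir, "cohort_truth.csv")
  meas_path <- file.path(out_dir, "cohort_measures.csv")
  utils::write.csv(cohort$truth, truth_path, row.names = FALSE)
  utils::write.csv(measures, meas_path, row.names = FALSE)
  c(truth_path, meas_path)
}

stage_analyze_ <- function(cfg, seed, out_dir, state) {
  cfg <- cfg %||% list()
  if (is.null(state$measures)) {
    if (is.null(cfg$measures)) {
      stop("analyze stage needs a prior cohort stage or config field 'measures'")
    }
    state$measures <- utils::read.csv(cfg$measures)
  }
  n_res <- cfg$n_resamples %||% 5000
  subj <- subject_measures(state$measures, blocks = cfg$blocks %||% 1,
                           mode = cfg$mode %||% "average")
  seeds <- derive_seeds_(seed, 2)
  corr <- ratio_param_correlation_table(subj, n_resamples = n_res,
                                        seed = seeds[[1]])
  ages <- age_correlation_suite(subj, n_resamples = n_res,
                                seed = seeds[[2]])
  corr_path <- file.path(out_dir, "ratio_param_correlations.csv")
  age_path <- file.path(out_dir, "age_correlations.csv")
  utils::write.csv(corr, corr_path, row.names = FALSE)
  utils::write.csv(ages, age_path, row.names = FALSE)
  c(corr_path, age_path)
}
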