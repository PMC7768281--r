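test_that("cohorts are seed-reproducible and correctly shaped", {
  cfg <- tiny_cohort_config()
  a <- generate_cohort(cfg, seed = 1)
  b <- generate_cohort(cfg, seed = 1)
  expect_identical(a$spectra, b$spectra)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(cfg, seed = 2)
  expect_false(identical(a$spectra, c$spectra))
  expect_equal(nrow(a$truth), 8 * 3 * 2)
  expect_equal(dim(a$spectra), c(8 * 3 * 2, 69))
  expect_error(cohort_config(n_subjects = 0), "at least one")
})

test_that("degenerate config with zero variability yields identical spectra", {
  cfg <- cohort_config(
    n_subjects = 4, n_channels = 2, n_blocks = 2,
    age_sd = 1e-6,
    exponent_sd = 0, exponent_age_slope = 0, offset_sd = 0,
    theta = peak_model(1, 6, 0, c(4, 8), 0.4, 0, 0.1, 1.5, 0, c(1, 3)),
    alpha = peak_model(1, 10, 0, c(8, 13), 0.8, 0, 0.1, 2, 0, c(1, 4)),
    beta = peak_model(1, 21.5, 0, c(13, 30), 0.35, 0, 0.1, 2, 0, c(1, 4)),
    channel_gradient_exponent = 0, channel_gradient_alpha_pw = 0,
    block_jitter_sd = list(exponent = 0, offset = 0, cf = 0, pw = 0,
                           bw = 0),
    noise_sd = 0)
  co <- generate_cohort(cfg, seed = 3)
  expect_equal(max(apply(co$spectra, 2, function(col) diff(range(col)))), 0)
})

test_that("exponent-only cohorts give perfect rank coupling with theta/beta", {
  cfg <- cohort_config(
    n_subjects = 20, n_channels = 1, n_blocks = 1,
    exponent_sd = 0.4, exponent_age_slope = 0, offset_sd = 0.2,
    theta = peak_model(0, 6, 0, c(4, 8), 0.4, 0, 0.1, 1.5, 0, c(1, 3)),
    alpha = peak_model(0, 10, 0, c(8, 13), 0.8, 0, 0.1, 2, 0, c(1, 4)),
    beta = peak_model(0, 21.5, 0, c(13, 30), 0.35, 0, 0.1, 2, 0, c(1, 4)),
    channel_gradient_exponent = 0, channel_gradient_alpha_pw = 0,
    block_jitter_sd = list(exponent = 0, offset = 0, cf = 0, pw = 0,
                           bw = 0),
    noise_sd = 0)
  co <- generate_cohort(cfg, seed = 4)
  m <- cohort_measures(co, fit = FALSE)
  expect_equal(spearman_cor(m$tbr, co$truth$exponent), 1)
})

test_that("cohort marginals track the configured population moments", {
  cfg <- cohort_config(n_subjects = 400, n_channels = 1, n_blocks = 1)
  co <- generate_cohort(cfg, seed = 5)
  se_mean <- cfg$age_sd / sqrt(400)
  expect_lt(abs(mean(co$ages) - cfg$age_mean), 3 * se_mean)
  expect_lt(abs(sd(co$ages) - cfg$age_sd), 3 * se_mean)
  expect_true(all(co$ages >= 6 & co$ages <= 44))
  # negative exponent-age association by construction
  expect_lt(spearman_cor(co$truth$exponent, co$truth$age), 0)
  # alpha present everywhere; theta/beta at their configured prevalence
  expect_true(all(!is.na(co$truth$alpha_pw)))
  expect_equal(mean(!is.na(co$truth$theta_pw)), 0.6, tolerance = 0.1)
})

test_that("block jitter produces consecutive differences centered on zero", {
  cfg <- cohort_config(n_subjects = 60, n_channels = 1, n_blocks = 5,
                       noise_sd = 0)
  co <- generate_cohort(cfg, seed = 6)
  expmat <- matrix(co$truth$exponent, ncol = 5, byrow = TRUE)
  d <- block_differences(expmat)
  expect_equal(dim(d), c(60, 4))
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 3 * se)
})

test_that("time-series synthesis is seeded and validates its inputs", {
  p <- spectral_params(0, 1, noise_sd = 0)
  x1 <- synth_time_series(p, fs = 500, duration = 5, seed = 9)
  x2 <- synth_time_series(p, fs = 500, duration = 5, seed = 9)
  expect_identical(x1, x2)
  expect_length(x1, 2500)
  expect_error(synth_time_series(p, fs = 60), "70")
  expect_error(synth_time_series(p, fs = 500, duration = 1), "window")
  expect_error(synth_time_series(list(), fs = 500), "spectral_params")
})

test_that("synthesized series reproduce their target spectrum through Welch", {
  p <- spectral_params(0, 1, noise_sd = 0)
  x <- synth_time_series(p, fs = 500, duration = 30, seed = 10)
  w <- welch_psd(x, 500)
  target <- aperiodic_component(w$freqs, 0, 1)
  expect_lt(sqrt(mean((w$power - target)^2)), 0.1)
  ft <- fit_spectrum(w)
  expect_equal(ft$exponent, 1, tolerance = 0.1)

  # a peaked target leaves its oscillation at the right location
  pk <- spectral_params(0, 1, peaks = c(10, 0.8, 1.5), noise_sd = 0)
  xp <- synth_time_series(pk, fs = 500, duration = 30, seed = 11)
  wp <- welch_psd(xp, 500)
  bump <- wp$power - aperiodic_component(wp$freqs, 0, 1)
  expect_equal(wp$freqs[which.max(bump)], 10, tolerance = 0.5)
})
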