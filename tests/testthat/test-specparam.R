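test_that("noiseless pure-aperiodic spectra are recovered essentially exactly", {
  ps <- sim_spectrum(spectral_params(0, 1, noise_sd = 0))
  ft <- fit_spectrum(ps)
  expect_equal(ft$offset, 0, tolerance = 1e-6)
  expect_equal(ft$exponent, 1, tolerance = 1e-6)
  expect_equal(nrow(ft$peaks), 0)
  expect_gte(ft$r_squared, 0.999)
  expect_lt(ft$fit_error, 1e-6)
})

test_that("noiseless three-peak spectra are recovered within tolerance", {
  true_peaks <- rbind(c(6, 0.5, 1.5), c(10, 0.5, 1.5), c(21.5, 0.5, 1.5))
  ps <- sim_spectrum(spectral_params(0, 1, peaks = true_peaks,
                                     noise_sd = 0))
  ft <- fit_spectrum(ps)
  expect_equal(nrow(ft$peaks), 3)
  expect_equal(ft$peaks$cf, true_peaks[, 1], tolerance = 0.25)
  expect_equal(ft$peaks$pw, true_peaks[, 2], tolerance = 0.05)
  expect_equal(ft$exponent, 1, tolerance = 0.05)
  expect_gte(ft$r_squared, 0.999)
})

test_that("randomized noiseless recovery suite meets tolerances", {
  set.seed(77)
  for (i in 1:50) {
    p <- random_recovery_params()
    ft <- fit_spectrum(sim_spectrum(p))
    expect_lt(abs(ft$exponent - p$exponent), 0.05)
    expect_lt(abs(ft$offset - p$offset), 0.05)
    expect_lte(max_cf_error(ft, p), 0.25)
    expect_gte(ft$r_squared, 0.999)
  }
})

test_that("recovery degrades gracefully under measurement noise", {
  set.seed(88)
  fails <- 0
  for (i in 1:200) {
    p <- random_recovery_params()
    p$noise_sd <- 0.005
    ft <- fit_spectrum(sim_spectrum(p, seed = 5000 + i))
    ok <- abs(ft$exponent - p$exponent) <= 0.1 &&
      max_cf_error(ft, p) <= 0.5
    fails <- fails + !ok
  }
  expect_lt(fails / 200, 0.05)
})

test_that("fit respects peak count and width constraints", {
  set.seed(99)
  stg <- fit_settings(max_peaks = 2)
  for (i in 1:20) {
    p <- random_recovery_params(n_peaks = 3)
    p$noise_sd <- 0.01
    ft <- fit_spectrum(sim_spectrum(p, seed = 600 + i), stg)
    expect_lte(nrow(ft$peaks), 2)
    if (nrow(ft$peaks) > 0) {
      expect_true(all(ft$peaks$bw >= stg$peak_width_bounds[1]))
      expect_true(all(ft$peaks$bw <= stg$peak_width_bounds[2]))
    }
  }
})

test_that("fit -> regenerate -> re-fit is approximately idempotent", {
  set.seed(123)
  for (i in 1:10) {
    p <- random_recovery_params()
    ft1 <- fit_spectrum(sim_spectrum(p))
    regen <- sim_spectrum(spectral_params(ft1$offset, ft1$exponent,
                                          peaks = ft1$peaks, noise_sd = 0))
    ft2 <- fit_spectrum(regen)
    expect_equal(ft2$exponent, ft1$exponent, tolerance = 0.05)
    expect_equal(ft2$offset, ft1$offset, tolerance = 0.05)
    expect_equal(nrow(ft2$peaks), nrow(ft1$peaks))
    if (nrow(ft1$peaks) > 0) {
      expect_equal(sort(ft2$peaks$cf), sort(ft1$peaks$cf),
                   tolerance = 0.25)
    }
  }
})

test_that("goodness of fit matches hand-computed Pearson r^2 and MAE", {
  mk_fit <- function(model, freqs) {
    structure(list(model = model, freqs = freqs), class = "spectral_fit")
  }
  f <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  data <- power_spectrum(f[1:3] + 0, c(0, 1, 2))
  # small worked case: r = cov/sqrt(varx*vary) -> r^2 = 0.75
  g <- goodness_of_fit(mk_fit(c(0, 1, 1), data$freqs), data)
  expect_equal(g$r_squared, 0.75)

  ps <- sim_spectrum(spectral_params(0, 1, noise_sd = 0))
  ident <- goodness_of_fit(mk_fit(ps$power, ps$freqs), ps)
  expect_equal(ident$r_squared, 1)
  expect_equal(ident$fit_error, 0)
  shifted <- goodness_of_fit(mk_fit(ps$power + 0.3, ps$freqs), ps)
  expect_equal(shifted$r_squared, 1)
  expect_equal(shifted$fit_error, 0.3)

  flat <- flat_spectrum(1)
  g0 <- goodness_of_fit(mk_fit(rep(0.5, 69), flat$freqs), flat)
  expect_true(is.na(g0$r_squared))
})

test_that("band peak assignment follows containment and power tie-breaks", {
  mk <- function(peaks) {
    structure(list(peaks = as.data.frame(peaks)), class = "spectral_fit")
  }
  tab <- assign_band_peaks(mk(data.frame(cf = c(6, 21.5),
                                         pw = c(0.5, 0.4),
                                         bw = c(1.5, 2))))
  expect_equal(tab$cf[tab$band == "theta"], 6)
  expect_equal(tab$cf[tab$band == "beta"], 21.5)
  expect_true(is.na(tab$cf[tab$band == "alpha"]))

  # two alpha-range candidates: higher power wins
  tab2 <- assign_band_peaks(mk(data.frame(cf = c(9, 11),
                                          pw = c(0.3, 0.6),
                                          bw = c(2, 2))))
  expect_equal(tab2$cf[tab2$band == "alpha"], 11)
  # exact power tie: lower center frequency wins
  tab3 <- assign_band_peaks(mk(data.frame(cf = c(9, 11),
                                          pw = c(0.4, 0.4),
                                          bw = c(2, 2))))
  expect_equal(tab3$cf[tab3$band == "alpha"], 9)

  empty <- assign_band_peaks(mk(data.frame(cf = numeric(0),
                                           pw = numeric(0),
                                           bw = numeric(0))))
  expect_true(all(is.na(empty$cf)))
})

test_that("parameterized ratios divide peak powers and propagate absence", {
  tab <- data.frame(band = c("theta", "alpha", "beta"),
                    cf = c(6, 10, NA), pw = c(0.8, 0.4, NA),
                    bw = c(1.5, 2, NA))
  expect_equal(parameterized_ratio(tab, "theta", "alpha"), 2)
  tab$pw[1] <- 0.5; tab$pw[2] <- 0.5
  expect_equal(parameterized_ratio(tab, "theta", "alpha"), 1)
  expect_true(is.na(parameterized_ratio(tab, "theta", "beta")))
  expect_error(parameterized_ratio(tab, "theta", "gamma"), "not found")
})

test_that("fit settings validate their invariants", {
  expect_error(fit_settings(peak_width_bounds = c(2, 1)))
  expect_error(fit_settings(max_peaks = -1))
  expect_error(fit_settings(aperiodic_mode = "knee"))
})
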