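test_that("aperiodic component follows b - chi*log10(f)", {
  expect_equal(aperiodic_component(10, offset = 0, exponent = 1), -1)
  expect_equal(aperiodic_component(c(2, 7, 20), offset = 2.5, exponent = 0),
               rep(2.5, 3))
  expect_equal(aperiodic_component(10, offset = 1, exponent = 2), -1)
  # offset is the value at 1 Hz for any exponent
  for (chi in c(0, 0.5, 1, 2, 3)) {
    expect_equal(aperiodic_component(1, offset = 0.7, exponent = chi), 0.7)
  }
  expect_error(aperiodic_component(c(0, 1), 0, 1), "frequencies")
  expect_error(aperiodic_component(-3, 0, 1), "frequencies")
})

test_that("peak component evaluates Gaussians and sums them", {
  f <- freq_axis()
  pk <- c(10, 0.5, 2)
  g <- peak_component(f, pk)
  expect_equal(g[f == 10], 0.5)                       # maximum at cf
  expect_equal(g[f == 12], 0.5 * exp(-1 / 2))         # at cf + w
  expect_equal(g[f == 8], g[f == 12])                 # symmetry
  expect_equal(peak_component(f, NULL), rep(0, length(f)))
  two <- peak_component(f, rbind(c(6, 0.5, 1), c(20, 0.3, 1)))
  expect_equal(two, peak_component(f, c(6, 0.5, 1)) +
                 peak_component(f, c(20, 0.3, 1)))
  expect_error(peak_component(f, c(10, 0.5, -1)), "bandwidth")
})

test_that("simulated spectra equal the deterministic model when noiseless", {
  f <- freq_axis()
  expect_length(f, 69)
  flat <- sim_spectrum(spectral_params(0, 0, noise_sd = 0))
  expect_equal(flat$power, rep(0, 69))

  p <- spectral_params(0, 1,
                       peaks = rbind(c(6, 0.5, 0.1), c(10, 0.5, 0.1),
                                     c(21.5, 0.5, 0.1)),
                       noise_sd = 0)
  ps <- sim_spectrum(p)
  expect_equal(ps$power[f == 10], -1 + 0.5, tolerance = 1e-9)
  expect_equal(ps$power,
               aperiodic_component(f, 0, 1) + peak_component(f, p$peaks))

  # no peaks + positive exponent: strictly decreasing log power
  mono <- sim_spectrum(spectral_params(-0.3, 1.3, noise_sd = 0))
  expect_true(all(diff(mono$power) < 0))
})

test_that("simulation noise is seed-reproducible and scaled correctly", {
  p <- spectral_params(0, 1, noise_sd = 0.005)
  a <- sim_spectrum(p, seed = 11)
  b <- sim_spectrum(p, seed = 11)
  expect_identical(a$power, b$power)
  c <- sim_spectrum(p, seed = 12)
  expect_false(identical(a$power, c$power))
  # noise SD close to nominal when pooled over many draws
  base <- sim_spectrum(spectral_params(0, 1, noise_sd = 0))$power
  devs <- unlist(lapply(1:100, function(s)
    sim_spectrum(p, seed = s)$power - base))
  expect_equal(sd(devs), 0.005, tolerance = 0.05)
})

test_that("power spectrum container validates input and round-trips scale", {
  f <- freq_axis()
  expect_error(power_spectrum(c(1, 1, 2), c(0, 0, 0)), "increasing")
  expect_error(power_spectrum(c(0.5, 0, 1), c(0, 0, 0)), "> 0")
  expect_error(power_spectrum(f, numeric(3)), "length")
  expect_error(power_spectrum(1:3, c(1, -1, 2), scale = "linear"),
               "positive")
  ps <- sim_spectrum(spectral_params(0.3, 1.2, noise_sd = 0))
  back <- power_spectrum(ps$freqs, spectrum_power_linear(ps),
                         scale = "linear")
  expect_equal(back$power, ps$power, tolerance = 1e-12)
})

test_that("Welch PSD locates spectral peaks and conserves variance", {
  fs <- 500
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  w <- welch_psd(x, fs)
  expect_equal(w$freqs[which.max(w$power)], 10)
  expect_equal(diff(w$freqs)[1], 0.5)            # 2-s windows -> 0.5 Hz
  expect_true(min(w$freqs) >= 1 && max(w$freqs) <= 35)

  set.seed(201)
  xn <- rnorm(fs * 20)
  wn <- welch_psd(xn, fs, f_range = NULL)
  # Parseval-style check under density normalization
  expect_equal(sum(10^wn$power) * 0.5, var(xn), tolerance = 0.05)
  # white noise: flat within sampling error
  expect_lt(sd(wn$power), 0.15)

  expect_error(welch_psd(rnorm(100), fs), "shorter")
})
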