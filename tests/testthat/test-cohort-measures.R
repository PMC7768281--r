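# Cohort-level measurement and correlation suites. Fits run on small
# cohorts so the whole file stays fast.

exponent_only_cfg <- function(n_subjects = 24, n_channels = 1) {
  cohort_config(
    n_subjects = n_subjects, n_channels = n_channels, n_blocks = 1,
    exponent_sd = 0.4, exponent_age_slope = 0, offset_sd = 0.2,
    theta = peak_model(0, 6, 0, c(4, 8), 0.4, 0, 0.1, 1.5, 0, c(1, 3)),
    alpha = peak_model(0, 10, 0, c(8, 13), 0.8, 0, 0.1, 2, 0, c(1, 4)),
    beta = peak_model(0, 21.5, 0, c(13, 30), 0.35, 0, 0.1, 2, 0, c(1, 4)),
    channel_gradient_exponent = 0, channel_gradient_alpha_pw = 0,
    block_jitter_sd = list(exponent = 0, offset = 0, cf = 0, pw = 0,
                           bw = 0),
    noise_sd = 0)
}

test_that("measure tables carry ratios, fits, and parameterized ratios", {
  cfg <- tiny_cohort_config()
  co <- generate_cohort(cfg, seed = 21)
  m <- cohort_measures(co)
  expect_equal(nrow(m), nrow(co$truth))
  expect_true(all(m$tbr > 0))
  expect_equal(m$log_tbr, log10(m$tbr))
  # fitted exponents track the generating exponents closely
  expect_gt(spearman_cor(m$fit_exponent, co$truth$exponent), 0.95)
  # alpha peaks (prevalence 1) are found nearly everywhere
  expect_gt(mean(!is.na(m$alpha_pw)), 0.9)
  # parameterized ratio equals assigned theta/beta peak power quotient
  has <- which(!is.na(m$tbr_param))
  expect_equal(m$tbr_param[has], m$theta_pw[has] / m$beta_pw[has])
})

test_that("subject aggregation averages channels and respects block choice", {
  cfg <- tiny_cohort_config()
  co <- generate_cohort(cfg, seed = 22)
  m <- cohort_measures(co, fit = FALSE)
  s1 <- subject_measures(m, blocks = 1)
  expect_equal(nrow(s1), 8)
  first <- m[m$subject == 1 & m$block == 1, ]
  expect_equal(s1$tbr[1], mean(first$tbr))
  pool <- subject_measures(m, blocks = 1, mode = "pool")
  expect_equal(nrow(pool), 8 * 3)
  expect_error(subject_measures(m, blocks = 99), "no rows")
})

test_that("exponent-only cohorts isolate the exponent cell of the table", {
  co <- generate_cohort(exponent_only_cfg(), seed = 23)
  m <- cohort_measures(co)
  s <- subject_measures(m)
  tab <- ratio_param_correlation_table(s, ratios = "tbr",
                                       n_resamples = 100, seed = 1)
  exp_cell <- tab[tab$parameter == "fit_exponent", ]
  expect_gt(exp_cell$rho, 0.99)
  # no periodic peaks anywhere: all peak-parameter cells are absent
  pk_cells <- tab[tab$parameter != "fit_exponent", ]
  expect_true(all(is.na(pk_cells$rho) | pk_cells$n < 3))
})

test_that("zero-variance measures produce absent correlation cells", {
  df <- data.frame(subject = 1:10, age = rep(30, 10),
                   tbr = rep(2, 10), fit_exponent = rnorm(10))
  tab <- ratio_param_correlation_table(df, ratios = "tbr",
                                       params = "fit_exponent",
                                       n_resamples = 50, seed = 2)
  expect_true(is.na(tab$rho))
  ages <- age_correlation_suite(df, measures = "tbr", n_resamples = 50,
                                seed = 3)
  expect_true(is.na(ages$rho))
})

test_that("topography correlations recover shared channel gradients", {
  cfg <- cohort_config(
    n_subjects = 12, n_channels = 20, n_blocks = 1,
    exponent_sd = 0.1, exponent_age_slope = 0,
    theta = peak_model(0, 6, 0, c(4, 8), 0.4, 0, 0.1, 1.5, 0, c(1, 3)),
    alpha = peak_model(0, 10, 0, c(8, 13), 0.8, 0, 0.1, 2, 0, c(1, 4)),
    beta = peak_model(0, 21.5, 0, c(13, 30), 0.35, 0, 0.1, 2, 0, c(1, 4)),
    channel_gradient_exponent = 0.15,
    block_jitter_sd = list(exponent = 0.01, offset = 0.01, cf = 0,
                           pw = 0, bw = 0),
    noise_sd = 0)
  co <- generate_cohort(cfg, seed = 24)
  m <- cohort_measures(co, fit = FALSE)
  m$truth_exponent <- co$truth$exponent
  # identical and negated measures are perfectly (anti)correlated
  self <- topography_correlation(m, "tbr", "tbr", n_resamples = 50,
                                 seed = 4)
  expect_equal(self$rho, 1)
  m$neg_tbr <- -m$tbr
  anti <- topography_correlation(m, "tbr", "neg_tbr", n_resamples = 50,
                                 seed = 5)
  expect_equal(anti$rho, -1)
  # shared exponent gradient drives a strong spatial correlation
  topo <- topography_correlation(m, "tbr", "truth_exponent",
                                 n_resamples = 100, seed = 6)
  expect_gt(topo$rho, 0.9)
})

test_that("age suites separate real trends from shuffled nulls", {
  co <- generate_cohort(
    cohort_config(n_subjects = 40, n_channels = 1, n_blocks = 1,
                  exponent_sd = 0.05, exponent_age_slope = -0.03,
                  noise_sd = 0),
    seed = 25)
  m <- cohort_measures(co, fit = FALSE)
  s <- subject_measures(m)
  real <- age_correlation_suite(s, measures = "tbr", n_resamples = 200,
                                seed = 7)
  expect_lt(real$ci_high, 0)       # raw ratio tracks age via the exponent

  # shuffled ages: small correlations, CIs spanning zero in most seeds
  hits <- 0
  for (i in 1:20) {
    s$age <- withr::with_seed(1000 + i, sample(s$age))
    null <- age_correlation_suite(s, measures = "tbr", n_resamples = 200,
                                  seed = i)
    hits <- hits + (null$ci_low <= 0 && null$ci_high >= 0)
  }
  expect_gte(hits, 19)
})
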