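test_that("the default monitoring grid has 37 points over 24 h", {
  g <- measurement_grid()
  expect_length(g, 37)
  expect_equal(g[1], 0)
  expect_equal(g[37], 24)
  expect_true(all(diff(g) > 0))
  # 15-min spacing for 2 h, 30-min for 6 h, hourly thereafter
  expect_equal(g[g <= 2], seq(0, 2, 0.25))
  expect_equal(diff(g[g >= 8]), rep(1, 16))
  expect_equal(measurement_grid(intervals = 1, durations = 2), c(0, 1, 2))
  expect_error(measurement_grid(intervals = 3, durations = 2), "interval")
  expect_error(measurement_grid(intervals = c(1, 1), durations = 2), "length")
})

test_that("series are the group polynomial plus controlled noise", {
  # noiseless limit: the series equals the polynomial on the grid
  cfg <- cohort_config(channels = list(SBP = channel_spec(
    shapes = list(c(140, -1, 0.02)), probs = 1, sigma = 1e-9)),
    grid = seq(0, 24, 4), outcomes = NULL)
  coh <- simulate_bp_cohort(n = 3, seed = 41, config = cfg)
  expect_equal(coh$bp$value_mmhg,
               rep(trajectory_value(c(140, -1, 0.02), seq(0, 24, 4)), 3),
               tolerance = 1e-6)
  # CLT: mean over many replicates approaches the polynomial value
  cfg2 <- cohort_config(channels = list(SBP = channel_spec(
    shapes = list(c(130, -0.5)), probs = 1, sigma = 8)),
    grid = c(0, 12, 24), outcomes = NULL)
  coh2 <- simulate_bp_cohort(n = 10000, seed = 42, config = cfg2)
  at12 <- coh2$bp$value_mmhg[coh2$bp$time_h == 12]
  expect_lt(abs(mean(at12) - trajectory_value(c(130, -0.5), 12)),
            3 * 8 / sqrt(10000))
})

test_that("AR(1) noise has the requested lag-1 autocorrelation", {
  cfg <- cohort_config(channels = list(SBP = channel_spec(
    shapes = list(c(130, 0)), probs = 1, sigma = 8)),
    grid = seq(0, 24, 1), noise = "ar1", rho = 0.6, outcomes = NULL)
  coh <- simulate_bp_cohort(n = 10000, seed = 43, config = cfg)
  e <- matrix(coh$bp$value_mmhg - 130, nrow = 25)  # time x patient
  r <- cor(as.vector(e[-25, ]), as.vector(e[-1, ]))
  expect_lt(abs(r - 0.6), 0.03)
  expect_lt(abs(sd(e) - 8), 0.2)  # marginal SD preserved
})

test_that("intercept calibration hits the target marginal prevalence", {
  # all unit ORs: alpha is the logit of the target
  expect_equal(calibrate_intercept(rep(1, 3), c(0.2, 0.5, 0.3), 0.19),
               qlogis(0.19), tolerance = 1e-8)
  # symmetric two-group case has the closed-form root -1/2
  expect_equal(calibrate_intercept(c(1, exp(1)), c(0.5, 0.5), 0.5), -0.5,
               tolerance = 1e-8)
  # Monte-Carlo marginal matches the target within half a point
  coh <- simulate_bp_cohort(n = 200000, seed = 44, series = FALSE)
  expect_lt(abs(mean(coh$outcomes$end_24h) - 0.190), 0.005)
  expect_lt(abs(mean(coh$outcomes$eni_24h) - 0.371), 0.005)
  expect_lt(abs(mean(coh$outcomes$mrs_unfavorable) - 0.314), 0.005)
})

test_that("outcome generation recovers the configured effects", {
  # glucose effect: per-unit OR recovered by logistic refit
  cfg <- cohort_config(outcomes = list(
    end = outcome_spec("SBP", c(0.263, 1.140, 1, 1.507, 2.852), 0.190,
                       glucose_or = 1.193),
    eni = outcome_spec("SBP", c(0.841, 1.152, 1, 0.379, 0.288), 0.371),
    mrs = outcome_spec("SBP", c(0.963, 1.251, 1, 2.228, 2.883), 0.314)))
  coh <- simulate_bp_cohort(n = 100000, seed = 45, config = cfg, series = FALSE)
  fit <- glm(coh$outcomes$end_24h ~ coh$covariates$glucose +
               factor(coh$truth$labels$SBP), family = binomial())
  or_glu <- exp(coef(fit)[2])
  expect_lt(abs(or_glu / 1.193 - 1), 0.05)
  # seeded rerun is bit-identical
  coh2 <- simulate_bp_cohort(n = 1000, seed = 46, series = FALSE)
  coh3 <- simulate_bp_cohort(n = 1000, seed = 46, series = FALSE)
  expect_identical(coh2$outcomes, coh3$outcomes)
  expect_identical(coh2$covariates, coh3$covariates)
})

test_that("exclusive outcome mode forbids joint deterioration and improvement", {
  cfg <- cohort_config(outcome_mode = "exclusive")
  coh <- simulate_bp_cohort(n = 50000, seed = 47, config = cfg, series = FALSE)
  expect_equal(sum(coh$outcomes$end_24h & coh$outcomes$eni_24h), 0)
  # the END marginal is preserved by construction
  expect_lt(abs(mean(coh$outcomes$end_24h) - 0.190), 0.01)
})

test_that("shipped trajectory sets match their descriptive bands", {
  sbp <- default_sbp_groups()
  expect_equal(sum(sbp$probs), 1, tolerance = 1e-10)
  # the very-high SBP group stays within its 162-173 mmHg band after the
  # initial drop (t in [2, 24])
  tt <- seq(2, 24, 0.5)
  g5 <- trajectory_value(sbp$shapes[[5]], tt)
  expect_true(all(g5 >= 162 & g5 <= 173))
  # group mean levels are strictly ordered over the stable period
  mu <- vapply(sbp$shapes, function(b) mean(trajectory_value(b, tt)), numeric(1))
  expect_false(is.unsorted(mu, strictly = TRUE))
  dbp <- default_dbp_groups()
  expect_equal(sum(dbp$probs), 1, tolerance = 1e-10)
  # the very-high DBP band holds over the stable period before the late
  # downward bend of the quartic
  g4 <- trajectory_value(dbp$shapes[[4]], seq(2, 20, 0.5))
  expect_true(all(g4 >= 92 & g4 <= 101.5))
})

test_that("end-to-end fits recover the generating group structure", {
  skip_if_not_installed("mclust")
  # SBP: at the generating group count, classification is near-perfect
  # (selection frequency over 2-6 groups is exercised in the acceptance suite)
  ari_sbp <- vapply(1:5, function(r) {
    coh <- reference_cohort(353, seed = 6000 + r)
    fit5 <- suppressWarnings(
      gbtm(gbtm_formula, coh$bp, ngroups = 5, orders = 4, seed = r,
           control = gbtm_control(n_starts = 2)))
    mclust::adjustedRandIndex(fit5$assignments, coh$truth$labels$SBP)
  }, numeric(1))
  expect_true(all(ari_sbp > 0.85))
  # DBP: selection over candidate group counts lands on the generating four
  picks_dbp <- vapply(1:5, function(r) {
    coh <- reference_cohort(353, seed = 6500 + r, channel = "DBP")
    sel <- suppressWarnings(
      gbtm_select(gbtm_formula, coh$bp, ngroups = 3:5, seed = r,
                  control = gbtm_control(n_starts = 2)))
    sel$best_J
  }, numeric(1))
  expect_gte(mean(picks_dbp == 4), 0.8)
})
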