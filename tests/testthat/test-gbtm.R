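test_that("posterior classification follows the likelihood ratio", {
  # J = 1: all posteriors are 1
  L1 <- matrix(c(-3, -5, -10), 3, 1)
  es <- bptraj:::gbtm_e_step(L1, 1)
  expect_equal(es$W, matrix(1, 3, 1))
  expect_equal(es$loglik, sum(L1))
  # identical groups with equal priors: rows are (0.5, 0.5)
  L2 <- matrix(c(-3, -5, -3, -5), 2, 2)
  expect_equal(bptraj:::gbtm_e_step(L2, c(0.5, 0.5))$W,
               matrix(0.5, 2, 2))
  # one observation y = 100 under means (100, 160), sd 10, equal priors:
  # posterior for group 1 is 1 / (1 + exp(-18))
  l <- c(dcnorm(100, 100, 10), dcnorm(100, 160, 10))
  W <- bptraj:::gbtm_e_step(matrix(l, 1), c(0.5, 0.5))$W
  expect_equal(W[1, 1], 1 / (1 + exp(-18)), tolerance = 1e-12)
})

test_that("mixture log-likelihood matches naive summation on small cases", {
  coh <- flat_cohort(5, c(120, 160), c(0.5, 0.5), sigma = 5, seed = 7,
                     grid = c(0, 8, 16, 24))
  fit <- gbtm(gbtm_formula, coh$bp, ngroups = 2, orders = 0, seed = 1,
              control = gbtm_control(n_starts = 2))
  # brute-force double loop over patients and groups in the raw domain
  naive <- 0
  for (pid in unique(coh$bp$patient_id)) {
    s <- coh$bp[coh$bp$patient_id == pid, ]
    lik <- sum(vapply(1:2, function(j)
      fit$pi[j] * exp(series_loglik(s$value_mmhg, s$time_h,
                                    fit$coefficients[[j]], fit$sigma)),
      numeric(1)))
    naive <- naive + log(lik)
  }
  expect_equal(fit$logLik, naive, tolerance = 1e-10)
  expect_equal(gbtm_loglik(fit, coh$bp), fit$logLik, tolerance = 1e-10)
  # degenerate one-group evaluation equals the summed series log-likelihood
  fit1 <- gbtm(gbtm_formula, coh$bp, ngroups = 1, orders = 0, seed = 1)
  direct <- sum(vapply(unique(coh$bp$patient_id), function(pid) {
    s <- coh$bp[coh$bp$patient_id == pid, ]
    series_loglik(s$value_mmhg, s$time_h, fit1$coefficients[[1]], fit1$sigma)
  }, numeric(1)))
  expect_equal(fit1$logLik, direct, tolerance = 1e-10)
})

test_that("M-step weighted least squares equals the replication oracle", {
  set.seed(42)
  t <- rep(c(0, 2, 6, 12, 24), 6)
  id <- rep(1:6, each = 5)
  y <- 130 - 0.8 * t + rnorm(30, 0, 3)
  B <- outer(t, 0:1, `^`)
  # integer-weight posteriors (quarters) so replication is exact
  wpat <- rep(c(1, 2, 3) / 4, 2)
  W <- cbind(wpat, 1 - wpat)
  ms <- bptraj:::gbtm_m_step_wls(y, id, B, W, orders = c(1L, 1L),
                                 sigma_min = 1e-8, group_sd = "common")
  # replicate each patient proportionally to 4*weight and fit unweighted
  for (j in 1:2) {
    reps <- round(4 * W[id, j])
    lmfit <- lm(rep(y, reps) ~ rep(t, reps))
    expect_equal(unname(ms$betas[[j]]), unname(coef(lmfit)), tolerance = 1e-8)
  }
  # full posterior mass with noiseless linear data: exact interpolation and
  # a floored residual scale
  y0 <- 140 - 1.5 * t
  ms0 <- bptraj:::gbtm_m_step_wls(y0, id, B, matrix(1, 6, 1), orders = 1L,
                                  sigma_min = 0.5, group_sd = "common")
  expect_equal(unname(ms0$betas[[1]]), c(140, -1.5), tolerance = 1e-8)
  expect_equal(ms0$sigma, 0.5)  # floored
  # equal posteriors: identical shapes across groups
  We <- matrix(0.5, 6, 2)
  mse <- bptraj:::gbtm_m_step_wls(y, id, B, We, orders = c(1L, 1L),
                                  sigma_min = 1e-8, group_sd = "common")
  expect_equal(mse$betas[[1]], mse$betas[[2]], tolerance = 1e-10)
  # singular design: one distinct time cannot support a line
  expect_error(bptraj:::gbtm_m_step_wls(y[1:6], 1:6, B[rep(1, 6), ],
                                        matrix(1, 6, 1), orders = 1L,
                                        sigma_min = 0.5, group_sd = "common"),
               "singular")
})

test_that("one-group fit reduces to closed-form polynomial least squares", {
  coh <- flat_cohort(25, 135, 1, sigma = 6, seed = 3, grid = seq(0, 24, 3))
  d <- coh$bp
  fit <- gbtm(gbtm_formula, d, ngroups = 1, orders = 2, seed = 5)
  ls <- lm(value_mmhg ~ time_h + I(time_h^2), data = d)
  expect_equal(unname(fit$coefficients[[1]]), unname(coef(ls)), tolerance = 1e-8)
  # sigma is the ML residual scale (divisor n)
  expect_equal(fit$sigma, sqrt(sum(residuals(ls)^2) / nrow(d)), tolerance = 1e-8)
  expect_equal(fit$pi, 1)
  expect_equal(unname(fit$posterior[, 1]), rep(1, 25))
})

test_that("EM recovers two well-separated flat groups and is monotone", {
  coh <- flat_cohort(200, c(120, 160), c(0.5, 0.5), sigma = 5, seed = 9,
                     grid = seq(0, 24, 2))
  fit <- gbtm(gbtm_formula, coh$bp, ngroups = 2, orders = 0, seed = 2,
              control = gbtm_control(n_starts = 3))
  expect_lt(abs(fit$coefficients[[1]][1] - 120), 1)
  expect_lt(abs(fit$coefficients[[2]][1] - 160), 1)
  expect_lt(abs(fit$pi[1] - 0.5), 0.05)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(fit$assignments, coh$truth$labels$SBP)
  expect_gt(ari, 0.95)
  # observed-data log-likelihood never decreases along the EM path
  expect_gte(min(diff(fit$loglik_trace)), -1e-8)
  # posterior rows and membership probabilities are normalised
  expect_equal(unname(rowSums(fit$posterior)), rep(1, 200), tolerance = 1e-10)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-10)
  expect_equal(fit$pi, exp(fit$theta) / sum(exp(fit$theta)), tolerance = 1e-10)
})

test_that("refitting with the same seed is bit-identical", {
  coh <- flat_cohort(60, c(125, 155), c(0.4, 0.6), sigma = 6, seed = 4)
  f1 <- gbtm(gbtm_formula, coh$bp, ngroups = 2, orders = 1, seed = 77,
             control = gbtm_control(n_starts = 3))
  f2 <- gbtm(gbtm_formula, coh$bp, ngroups = 2, orders = 1, seed = 77,
             control = gbtm_control(n_starts = 3))
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$posterior, f2$posterior)
  expect_identical(f1$logLik, f2$logLik)
})

test_that("groups are labelled by ascending mean trajectory", {
  coh <- flat_cohort(120, c(150, 110, 130), c(1, 1, 1) / 3, sigma = 4, seed = 8)
  for (s in c(1, 31)) {
    fit <- gbtm(gbtm_formula, coh$bp, ngroups = 3, orders = 0, seed = s,
                control = gbtm_control(n_starts = 3))
    gm <- vapply(fit$coefficients, function(b) mean(trajectory_value(b, fit$grid)),
                 numeric(1))
    expect_false(is.unsorted(gm))
  }
})

test_that("censored bounds reduce to the uncensored fit when inactive", {
  coh <- flat_cohort(40, c(120, 150), c(0.5, 0.5), sigma = 5, seed = 12)
  f_un <- gbtm(gbtm_formula, coh$bp, ngroups = 2, orders = 0, seed = 3,
               control = gbtm_control(n_starts = 2))
  f_cn <- gbtm(gbtm_formula, coh$bp, ngroups = 2, orders = 0, seed = 3,
               bounds = c(0, 400), control = gbtm_control(n_starts = 2))
  expect_equal(f_cn$coefficients[[1]][1], f_un$coefficients[[1]][1], tolerance = 1e-3)
  expect_equal(f_cn$coefficients[[2]][1], f_un$coefficients[[2]][1], tolerance = 1e-3)
  expect_equal(f_cn$sigma, f_un$sigma, tolerance = 1e-2)
})

test_that("information criteria follow the positive-form definitions", {
  expect_equal(unname(information_criteria(0, 3, 100)),
               c(6, 3 * log(100)))
  expect_equal(unname(information_criteria(-12.5, 0, 10)), c(25, 25))
  # BIC gap for equal likelihood, one extra parameter, n = 353
  a <- information_criteria(-1000, 5, 353)
  b <- information_criteria(-1000, 6, 353)
  expect_equal(unname(b["bic"] - a["bic"]), log(353), tolerance = 1e-9)
})

test_that("adequacy applies the 5% share and 0.7 APPA rules", {
  coh <- flat_cohort(30, 130, 1, sigma = 5, seed = 2)
  fit1 <- gbtm(gbtm_formula, coh$bp, ngroups = 1, orders = 0, seed = 1)
  ad1 <- adequacy(fit1)
  expect_equal(ad1$group_shares, 1)
  expect_equal(ad1$appa, 1)
  expect_true(ad1$passes)
  # constructed fits exercising each failure mode
  fake <- function(W) {
    structure(list(posterior = W, assignments = max.col(W, ties.method = "first"),
                   ngroups = ncol(W), n_patients = nrow(W)), class = "gbtm")
  }
  # 100 patients, 4 modal members in group 2: share 4% < 5%
  W <- matrix(0.05, 100, 2); W[, 1] <- 0.95
  W[1:4, ] <- c(0.05, 0.95)[col(W[1:4, ])]
  ad <- adequacy(fake(W))
  expect_equal(ad$group_shares, c(0.96, 0.04))
  expect_false(ad$passes_min_share)
  # a group with APPA 0.69 fails the posterior-probability rule
  W2 <- cbind(rep(c(0.69, 0.1), c(50, 50)), rep(c(0.31, 0.9), c(50, 50)))
  ad2 <- adequacy(fake(W2))
  expect_equal(ad2$appa, c(0.69, 0.9))
  expect_false(ad2$passes_appa)
  # an empty group yields share 0 and a failed flag, not an error
  W3 <- matrix(c(0.9, 0.1), 20, 2, byrow = TRUE)
  ad3 <- adequacy(fake(W3))
  expect_equal(ad3$group_shares, c(1, 0))
  expect_false(ad3$passes)
})

test_that("reference-cohort fits recover proportions and trajectory means", {
  # 20 replicates of the shipped five-group SBP generating conditions
  ok_prop <- ok_rmse <- logical(20)
  truth <- default_sbp_groups()
  grid <- measurement_grid()
  mu_true <- vapply(truth$shapes, trajectory_value, numeric(length(grid)), t = grid)
  for (r in 1:20) {
    coh <- reference_cohort(353, seed = 5000 + r)
    fit <- suppressWarnings(
      gbtm(gbtm_formula, coh$bp, ngroups = 5, orders = 4, seed = r,
           control = gbtm_control(n_starts = 2)))
    shares <- tabulate(fit$assignments, 5) / 353
    # compare against the replicate's realised label proportions: the
    # estimator cannot beat the sampling noise of the labels themselves
    realised <- tabulate(coh$truth$labels$SBP, 5) / 353
    ok_prop[r] <- all(abs(shares - realised) <= 0.03)
    mu_fit <- predict(fit, times = grid)
    ok_rmse[r] <- all(sqrt(colMeans((mu_fit - mu_true)^2)) <= 3)
  }
  expect_gte(mean(ok_prop & ok_rmse), 0.9)
})
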