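test_that("hazard MAE is exact on constructed offsets and matches a loop oracle", {
  set.seed(409)
  truth <- array(runif(2 * 2 * 3, 0.1, 0.4), c(2, 2, 3))
  expect_equal(hazard_mae(truth, truth), 0)
  expect_equal(hazard_mae(truth + 0.01, truth), 1.0)
  half <- truth
  half[1, , ] <- half[1, , ] + 0.02        # +0.02 on half the cells
  expect_equal(hazard_mae(half, truth), 1.0)
  expect_error(hazard_mae(truth, array(0.1, c(1, 2, 3))), "shape")

  for (rep in 1:20) {
    a <- array(runif(24), c(2, 3, 4)); b <- array(runif(24), c(2, 3, 4))
    expect_equal(hazard_mae(a, b), oracle_mae(a, b), tolerance = 1e-12)
  }
})

test_that("time-resolved MAE localizes errors and averages to the overall MAE", {
  set.seed(410)
  truth <- array(runif(5 * 2 * 4, 0.05, 0.3), c(5, 2, 4))
  expect_equal(hazard_mae_by_time(truth, truth), rep(0, 4))
  pred <- truth
  pred[, , 4] <- pred[, , 4] + 0.03
  series <- hazard_mae_by_time(pred, truth)
  expect_equal(series[1:3], rep(0, 3))
  expect_equal(series[4], 3.0)
  expect_equal(mean(series), hazard_mae(pred, truth), tolerance = 1e-12)
})

test_that("integrated Brier score reproduces closed-form cases", {
  # every patient experiences event 1 at t = 0 and the model says so
  n <- 30
  d <- competing_risks_dataset(matrix(0.5, n, 1), rep(1L, n), rep(0L, n), 1, 1)
  pred <- array(1 - 1e-9, c(n, 1, 1))
  expect_lt(integrated_brier_score(pred, d), 1e-6)

  # a coin: constant prediction 0.5 on a binary single-time outcome
  ev <- rep(c(1L, 0L), each = 15)
  d2 <- competing_risks_dataset(matrix(0.5, n, 1), ev, rep(0L, n), 1, 1)
  pred2 <- array(0.5, c(n, 1, 1))
  expect_equal(integrated_brier_score(pred2, d2), 0.25, tolerance = 1e-9)
})

test_that("the truth predictor is not beaten by patient-permuted predictions", {
  sim <- simulate_cohort(simulation_design(1000, seed = 51))
  d <- sim$data
  set.seed(52)
  perm <- sample(1000)
  ibs_truth <- integrated_brier_score(sim$truth, d)
  ibs_perm <- integrated_brier_score(sim$truth[perm, , , drop = FALSE], d)
  expect_lte(ibs_truth, ibs_perm)
  expect_gt(ibs_truth, 0); expect_lt(ibs_truth, 1)

  c_truth <- time_dependent_concordance(sim$truth, d)$mean
  c_perm <- time_dependent_concordance(sim$truth[perm, , , drop = FALSE], d)$mean
  expect_gte(c_truth, c_perm)
  expect_gte(c_truth, 0); expect_lte(c_truth, 1)
})

test_that("concordance hits its closed-form anchors", {
  # perfect ordering: higher true risk, earlier failure, E = 1, no censoring
  n <- 12
  haz <- array(rep(seq(0.9, 0.1, length.out = n), 3), c(n, 1, 3))
  ev <- rep(1L, n)
  tm <- as.integer(c(0, 0, 0, 0, 1, 1, 1, 1, 2, 2, 2, 2))
  d <- competing_risks_dataset(matrix(0.5, n, 1), ev, tm, 1, 3)
  expect_equal(time_dependent_concordance(haz, d)$mean, 1.0)

  # identical predictions for everyone: ties everywhere, 0.5
  flat <- array(0.2, c(n, 1, 3))
  expect_equal(time_dependent_concordance(flat, d)$mean, 0.5)
})

test_that("a covariate-free noise predictor scores near 0.5 concordance", {
  sim <- simulate_cohort(simulation_design(2000, seed = 53))
  set.seed(54)
  noise <- array(runif(2000 * 3 * 30, 0.005, 0.05), c(2000, 3, 30))
  ct <- time_dependent_concordance(noise, sim$data)$mean
  expect_lt(abs(ct - 0.5), 0.03)
})

test_that("bootstrap reports are seeded, bracketed and shrink with n", {
  sim <- simulate_cohort(simulation_design(500, seed = 55))
  metric <- function(pred, data) mean(pred)
  r1 <- bootstrap_ci(metric, sim$truth, sim$data, B = 200, seed = 9)
  r2 <- bootstrap_ci(metric, sim$truth, sim$data, B = 200, seed = 9)
  expect_identical(r1$values, r2$values)
  expect_lte(r1$lower, r1$estimate); expect_gte(r1$upper, r1$estimate)

  # constant metric: zero-width interval
  rc <- bootstrap_ci(function(p, d) 0.7, sim$truth, sim$data, B = 100, seed = 9)
  expect_equal(rc$lower, rc$upper)
  expect_equal(rc$estimate, 0.7)

  sim2 <- simulate_cohort(simulation_design(2000, seed = 55))
  r3 <- bootstrap_ci(metric, sim2$truth, sim2$data, B = 200, seed = 9)
  ratio <- (r1$upper - r1$lower) / (r3$upper - r3$lower)
  expect_gt(ratio, 1.4)   # ~2 expected from sqrt(2000/500)
  expect_lt(ratio, 2.9)
})

test_that("the Schoenfeld screen flags a constructed violation and not a null", {
  # hazard ratio reversing mid-study: x raises early hazard, lowers late
  set.seed(56)
  n <- 4000
  X <- cbind(Z1 = runif(n), Z2 = runif(n))
  T <- 12
  lam <- array(NA_real_, c(n, 1, T))
  for (t in 0:(T - 1)) {
    eff <- if (t < 6) 2.2 * (X[, 1] - 0.5) else -2.2 * (X[, 1] - 0.5)
    lam[, 1, t + 1] <- 0.08 * exp(eff)
  }
  out <- sample_outcomes(lam, seed = 57)
  d <- competing_risks_dataset(X, out$events, out$times, 1, T)
  tab <- proportional_hazards_screen(d)
  expect_true(tab$flagged[tab$variable == "Z1"])

  expect_error(proportional_hazards_screen(
    competing_risks_dataset(matrix(0.5, 50, 1), rep(1L, 50), rep(0L, 50), 1, 2)),
    "2 covariates")
})
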