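# builds a deephit model whose logit is exactly linear in the input on
# [0,1]^p (ReLU kept in its linear region), so integrated gradients has a
# closed form to compare against
linear_logit_model <- function(A, W2, b2 = 0) {
  p <- ncol(A); h <- nrow(A)
  m <- hazard_model(deephit_config(p, 1, 1, hidden_units = h), seed = 1)
  m$params$ev1_W1 <- A
  m$params$ev1_b1 <- matrix(2, h, 1)
  m$params$ev1_W2 <- W2
  m$params$ev1_b2 <- matrix(b2, 1, 1)
  m
}

test_that("integrated gradients recovers the closed form of a linear-logit model", {
  A <- rbind(c(0.3, -0.2, 0.5), c(0.1, 0.4, -0.3))
  W2 <- matrix(c(0.8, -0.6), 1, 2)
  m <- linear_logit_model(A, W2)
  w <- drop(W2 %*% A)
  cc <- 2 * sum(W2)
  x <- c(0.9, 0.2, 0.7); b <- c(0.1, 0.5, 0.3)
  s <- sum(w * (x - b))
  total <- plogis(sum(w * x) + cc) - plogis(sum(w * b) + cc)
  expected <- w * (x - b) / s * total

  ig <- integrated_gradients(m, x, b, steps = 512)
  expect_equal(unname(ig$attributions), expected, tolerance = 1e-6)
  expect_lt(ig$completeness_gap, 1e-8)

  # input = baseline: all-zero attribution
  ig0 <- integrated_gradients(m, b, b, steps = 64)
  expect_equal(unname(ig0$attributions), rep(0, 3))
})

test_that("the completeness gap closes as the Riemann grid refines", {
  set.seed(411)
  m <- hazard_model(tiny_tf_config(p = 4), seed = 21)
  x <- runif(4); b <- rep(0, 4)
  gaps <- vapply(c(32L, 128L, 512L), function(s)
    integrated_gradients(m, x, b, steps = s)$completeness_gap, numeric(1))
  expect_true(all(diff(gaps) <= 1e-12))
  expect_lt(gaps[2], 1e-3)
  expect_error(integrated_gradients(m, x, b, steps = 8), "at least 16")
})

test_that("ignored and duplicated features are attributed accordingly", {
  # column 3 carries zero weight: attribution exactly 0, ranked last
  A <- rbind(c(0.4, 0.3, 0), c(-0.2, 0.5, 0))
  m <- linear_logit_model(A, matrix(c(0.7, 0.4), 1, 2))
  ig <- integrated_gradients(m, c(0.8, 0.6, 0.9), rep(0, 3), steps = 64)
  expect_equal(unname(ig$attributions[3]), 0)

  d <- competing_risks_dataset(matrix(runif(60), 20, 3), rep(1L, 20),
                               rep(0L, 20), 1, 1)
  imp <- cohort_importance(m, d, steps = 32)
  expect_identical(as.character(imp$feature[3]), "Z3")
  expect_equal(imp$importance[3], 0)

  # symmetric duplicated columns receive equal attribution at equal inputs
  A2 <- rbind(c(0.4, 0.4, 0.1), c(0.2, 0.2, -0.3))
  m2 <- linear_logit_model(A2, matrix(c(0.5, 0.3), 1, 2))
  ig2 <- integrated_gradients(m2, c(0.7, 0.7, 0.5), rep(0, 3), steps = 64)
  expect_equal(unname(ig2$attributions[1]), unname(ig2$attributions[2]),
               tolerance = 1e-10)
})

test_that("attribution is invariant to patient ordering in cohort summaries", {
  set.seed(412)
  m <- hazard_model(tiny_dh_config(p = 3, E = 1, T = 2), seed = 22)
  X <- matrix(runif(30), 10, 3)
  colnames(X) <- paste0("Z", 1:3)
  d1 <- competing_risks_dataset(X, rep(1L, 10), rep(0L, 10), 1, 2)
  d2 <- competing_risks_dataset(X[10:1, ], rep(1L, 10), rep(0L, 10), 1, 2)
  i1 <- cohort_importance(m, d1, steps = 32)
  i2 <- cohort_importance(m, d2, steps = 32)
  expect_equal(i1, i2, tolerance = 1e-12)
})

test_that("a trained model ranks the planted driving covariate first", {
  # only Z1 drives the hazard; after a short fit it must dominate importance
  set.seed(413)
  n <- 1500
  X <- draw_covariates(n, 4, seed = 61)
  lam <- array(NA_real_, c(n, 1, 8))
  for (t in 0:7) lam[, 1, t + 1] <- 0.02 + 0.25 * X[, 1]
  out <- sample_outcomes(lam, seed = 62)
  d <- competing_risks_dataset(X, out$events, out$times, 1, 8)
  sp <- split_dataset(d, 0.8, seed = 63)
  m <- fit(hazard_model(deephit_config(4, 1, 8), seed = 64),
           sp$train, sp$validation,
           train_config(epochs = 80, patience = 20, seed = 65))
  imp <- cohort_importance(m, d, steps = 32)
  expect_identical(as.character(imp$feature[1]), "Z1")
  expect_gt(imp$importance[1], 2 * imp$importance[2])
})
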