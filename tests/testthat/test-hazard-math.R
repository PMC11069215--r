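test_that("incidence follows the geometric law for a single constant hazard", {
  lam <- matrix(0.5, 1, 2)
  expect_equal(incidence_curve(lam, 1), c(0.5, 0.25))
  expect_equal(cumulative_incidence(lam, 1, 1), 0.75)
})

test_that("incidence handles the boundary where total hazard reaches 1", {
  lam <- matrix(0.5, 2, 2)
  i1 <- incidence_curve(lam, 1)
  expect_equal(i1, c(0.5, 0))
})

test_that("incidence and cumulative incidence match hand-computed values", {
  lam <- rbind(rep(0.2, 3), rep(0.1, 3))
  expect_equal(incidence_curve(lam, 1), c(0.2, 0.2 * 0.7, 0.2 * 0.49))
  expect_equal(cumulative_incidence(lam, 1, 2), 0.438)
  # t = 0 reduces to the hazard itself
  expect_equal(cumulative_incidence(lam, 2, 0), 0.1)
})

test_that("incidence rejects bad events and invalid hazard matrices", {
  lam <- matrix(0.2, 2, 3)
  expect_error(incidence_curve(lam, 3), "event")
  expect_error(incidence_curve(lam, 0), "event")
  expect_error(cumulative_incidence(lam, 1, 3), "t must")
  expect_error(incidence_curve(matrix(0.6, 2, 3), 1), "exceeds 1")
})

test_that("cumulative incidences and survival are conserved", {
  set.seed(401)
  for (rep in 1:25) {
    E <- sample(1:4, 1); T <- sample(1:8, 1)
    lam <- random_hazard_matrix(E, T)
    curves <- incidence_curves(lam)
    total <- colSums(curves$cif) + curves$survival
    expect_true(all(abs(total - 1) < 1e-12))
    # per-event cumulative incidence is non-decreasing
    expect_true(all(apply(curves$cif, 1, function(r) all(diff(r) >= -1e-15))))
  }
})

test_that("collapsed log-likelihood matches the stated closed forms", {
  lam <- matrix(0.5, 2, 3)
  expect_equal(collapsed_log_likelihood(lam, 1, 1), 4 * log(0.5))
  # censored at t = 2: cells k < 2 for both events
  expect_equal(collapsed_log_likelihood(lam, 0, 2), 4 * log(0.5))
  expect_equal(collapsed_log_likelihood(matrix(0.9, 1, 1), 1, 0), log(0.9))
  expect_error(collapsed_log_likelihood(lam, 3, 0), "event")
  expect_error(collapsed_log_likelihood(lam, 1, 5), "time")
})

test_that("likelihood and incidence agree with brute-force oracles", {
  set.seed(402)
  for (rep in 1:100) {
    E <- sample(1:3, 1); T <- sample(1:6, 1)
    lam <- random_hazard_matrix(E, T)
    ev <- sample(0:E, 1); tm <- sample(seq_len(T), 1) - 1L
    expect_equal(collapsed_log_likelihood(lam, ev, tm),
                 oracle_cll(lam, ev, tm), tolerance = 1e-10)
    e <- sample(seq_len(E), 1)
    expect_equal(incidence_curve(lam, e), oracle_incidence(lam, e),
                 tolerance = 1e-10)
  }
})

test_that("the likelihood maximizer saturates at the observed cell", {
  # single patient, outcome (e=1, t=1) on a free 2x3 hazard grid: maximize
  # the collapsed log-likelihood numerically over logits
  obj <- function(z) -collapsed_log_likelihood(plogis(matrix(z, 2, 3)), 1, 1)
  opt <- optim(rep(0, 6), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  lam_hat <- plogis(matrix(opt$par, 2, 3))
  expect_gt(lam_hat[1, 2], 0.99)           # observed cell pushed to 1
  included <- rbind(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  included[1, 2] <- FALSE                  # cells (j, k <= t) except observed
  expect_true(all(lam_hat[included] < 0.01))
})

test_that("batch loss is the mean negative log-likelihood and behaves monotonically", {
  lam <- matrix(0.5, 2, 3)
  arr1 <- array(lam, c(1, 2, 3))
  d1 <- competing_risks_dataset(matrix(0.3, 1, 1), 1L, 1L, 2, 3)
  expect_equal(batch_negative_loss(arr1, d1), -4 * log(0.5), tolerance = 1e-9)

  # two identical patients: same mean
  arr2 <- array(rep(lam, each = 2), c(2, 2, 3))
  d2 <- competing_risks_dataset(matrix(0.3, 2, 1), c(1L, 1L), c(1L, 1L), 2, 3)
  expect_equal(batch_negative_loss(arr2, d2),
               batch_negative_loss(arr1, d1), tolerance = 1e-9)

  # pushing the observed cell's hazard toward 1 strictly decreases the loss
  better <- arr1; better[1, 1, 2] <- 0.9
  expect_lt(batch_negative_loss(better, d1), batch_negative_loss(arr1, d1))
  expect_gte(batch_negative_loss(arr1, d1), 0)
})
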