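# Independent brute-force oracles and small fixtures used across tests.
# These deliberately mirror the definitions, not the package implementation.

# collapsed log-likelihood by explicit double loop over (event, time) cells
oracle_cll <- function(lam, event, time) {
  E <- nrow(lam); T <- ncol(lam)
  lam <- pmin(pmax(lam, 1e-7), 1 - 1e-7)
  kmax <- if (event > 0) time else time - 1
  total <- 0
  for (j in seq_len(E)) {
    for (k in seq_len(kmax + 1L) - 1L) {
      if (k > kmax) next
      delta <- as.numeric(event > 0 && j == event && k == time)
      total <- total + delta * log(lam[j, k + 1]) +
        (1 - delta) * log(1 - lam[j, k + 1])
    }
  }
  total
}

# incidence by explicit product loop
oracle_incidence <- function(lam, event) {
  E <- nrow(lam); T <- ncol(lam)
  out <- numeric(T)
  for (tau in seq_len(T) - 1L) {
    surv <- 1
    for (k in seq_len(tau)) surv <- surv * (1 - sum(lam[, k]))
    out[tau + 1] <- lam[event, tau + 1] * surv
  }
  out
}

# MAE by explicit triple loop
oracle_mae <- function(pred, truth) {
  d <- dim(pred)
  acc <- 0
  for (i in seq_len(d[1])) for (e in seq_len(d[2])) for (t in seq_len(d[3]))
    acc <- acc + abs(pred[i, e, t] - truth[i, e, t])
  100 * acc / prod(d)
}

# random valid hazard matrix (E x T), total per-step hazard bounded below 1
random_hazard_matrix <- function(E, T, max_total = 0.8) {
  raw <- matrix(runif(E * T, 0.01, 1), E, T)
  share <- sweep(raw, 2, colSums(raw), "/")
  share * matrix(runif(T, 0.05, max_total), E, T, byrow = TRUE)
}

# small deterministic cohort for io/metric tests
tiny_cohort <- function(n = 40, seed = 1) {
  des <- simulation_design(n, horizon = 6L, n_events = 2L, censor_high = 9L,
                           seed = seed)
  specs <- list(
    hazard_spec("proportional", function(X, tgrid, p)
      matrix(0.08 + 0.1 * X[, 1], nrow(X), length(tgrid)), list()),
    hazard_spec("increasing", function(X, tgrid, p)
      0.02 + 0.1 * outer(X[, 2], tgrid / max(tgrid)), list()))
  simulate_cohort(des, specs)
}

# tiny transformer configuration for fast gradient/shape tests
tiny_tf_config <- function(p = 3, E = 2, T = 4)
  transformer_config(p, E, T, d_cov = 4, d_emb = 4, n_layers = 2,
                     n_heads = 2, hidden_units = 8)

tiny_dh_config <- function(p = 3, E = 2, T = 4)
  deephit_config(p, E, T, hidden_units = 8)
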