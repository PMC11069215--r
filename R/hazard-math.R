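# Discrete-time cause-specific hazard mathematics: incidence, cumulative
# incidence, overall survival and the collapsed log-likelihood.
#
# Conventions. A single patient's hazards form an E x T matrix lam with
# lam[e, t + 1] = P(event e at step t | event-free up to t), t = 0..T-1.
# The survival factor entering the incidence at step tau is the product of
# (1 - total hazard) over steps strictly before tau, so that the cumulative
# incidences and overall survival always sum to one.

check_hazard_matrix <- function(hazards) {
  hazards <- as.matrix(hazards)
  if (any(hazards <= 0) || any(hazards >= 1))
    stop_domain("hazards must lie strictly inside (0, 1)")
  tot <- colSums(hazards)
  if (any(tot > 1 + 1e-12))
    stop_domain("invalid hazard matrix: total per-step hazard exceeds 1")
  hazards
}

#' Incidence function of one competing event
#'
#' Probability of experiencing event \code{e} exactly at step \code{tau}:
#' \code{i_e(tau) = lambda_e(tau) * prod_{k < tau} (1 - sum_j lambda_j(k))},
#' the hazard at \code{tau} times the probability of remaining event-free
#' through all earlier steps.
#'
#' @param hazards E x T matrix of cause-specific hazard probabilities for a
#'   single patient (rows = events, columns = time steps 0..T-1).
#' @param event event code in \code{1..E}.
#' @return numeric vector of length T with the incidence at each step.
#' @seealso [cumulative_incidence()], [incidence_curves()]
#' @export
incidence_curve <- function(hazards, event) {
  hazards <- check_hazard_matrix(hazards)
  E <- nrow(hazards); T <- ncol(hazards)
  event <- as.integer(event)
  if (event < 1L || event > E)
    stop_domain("event must lie in {1, ..., ", E, "}")
  tot <- colSums(hazards)
  event_free <- c(1, cumprod(pmax(1 - tot, 0))[-T])
  hazards[event, ] * event_free
}

#' Cumulative incidence of one competing event
#'
#' \code{I_e(t) = sum_{tau <= t} i_e(tau)}: the probability of having
#' experienced event \code{e} by step \code{t}, accounting for the competing
#' events through the shared survival factor.
#'
#' @inheritParams incidence_curve
#' @param t 0-based time step in \code{0..T-1}.
#' @return probability in \code{[0, 1]}.
#' @export
cumulative_incidence <- function(hazards, event, t) {
  T <- ncol(as.matrix(hazards))
  t <- as.integer(t)
  if (t < 0L || t >= T)
    stop_domain("t must lie in {0, ..., ", T - 1L, "}")
  sum(incidence_curve(hazards, event)[seq_len(t + 1L)])
}

#' Incidence, cumulative incidence and survival series of a hazard matrix
#'
#' @inheritParams incidence_curve
#' @return list with components \code{incidence} (E x T), \code{cif} (E x T,
#'   rows non-decreasing), and \code{survival} (length T); at every step the
#'   cumulative incidences and survival sum to 1.
#' @export
incidence_curves <- function(hazards) {
  hazards <- check_hazard_matrix(hazards)
  E <- nrow(hazards); T <- ncol(hazards)
  inc <- matrix(NA_real_, E, T)
  for (e in seq_len(E)) inc[e, ] <- incidence_curve(hazards, e)
  cif <- matrix(NA_real_, E, T)
  for (e in seq_len(E)) cif[e, ] <- cumsum(inc[e, ])
  surv <- cumprod(pmax(1 - colSums(hazards), 0))
  list(incidence = inc, cif = cif, survival = surv)
}

#' Collapsed log-likelihood of one observed outcome
#'
#' Discrete-time likelihood treating each at-risk (event, time) cell as an
#' independent Bernoulli trial. For an observed event \code{e > 0} at time
#' \code{t}, all cells \code{(j, k)} with \code{k <= t} contribute, the
#' target being 1 only at \code{(e, t)}. A patient censored at \code{t}
#' contributes only cells with \code{k < t}, all with target 0 (the status
#' at the censoring step itself is unknown).
#'
#' Hazards are clipped to \code{[1e-7, 1 - 1e-7]} before taking logs.
#'
#' @inheritParams incidence_curve
#' @param event event code in \code{0..E} (0 = censored).
#' @param time 0-based outcome time in \code{0..T-1}; a censored time of
#'   exactly \code{T} (event-free through the whole horizon) is allowed and
#'   contributes event-free terms at every step.
#' @return log-likelihood contribution (always \eqn{\le 0}).
#' @export
collapsed_log_likelihood <- function(hazards, event, time) {
  hazards <- as.matrix(hazards)
  E <- nrow(hazards); T <- ncol(hazards)
  event <- as.integer(event); time <- as.integer(time)
  if (event < 0L || event > E)
    stop_domain("event must lie in {0, ..., ", E, "}")
  tmax <- if (event == 0L) T else T - 1L
  if (time < 0L || time > tmax)
    stop_domain("time must lie in {0, ..., ", tmax, "}")
  kmax <- if (event > 0L) time else time - 1L
  if (kmax < 0L) return(0)
  lam <- pmin(pmax(hazards[, seq_len(kmax + 1L), drop = FALSE], 1e-7), 1 - 1e-7)
  ll <- sum(log1p(-lam))
  if (event > 0L) {
    cell <- lam[event, time + 1L]
    ll <- ll - log1p(-cell) + log(cell)
  }
  ll
}

#' Mean negative collapsed log-likelihood of a dataset
#'
#' The training objective: \code{-1/n} times the summed collapsed
#' log-likelihood over patients, given each patient's predicted hazard
#' matrix. Non-negative, and differentiable with respect to the hazards.
#'
#' @param hazards \code{(n, E, T)} array of predicted hazards.
#' @param data a [competing_risks_dataset()].
#' @return mean negative log-likelihood (a non-negative scalar).
#' @export
batch_negative_loss <- function(hazards, data) {
  d <- dim(hazards)
  if (length(d) != 3L || d[1] != length(data$events) ||
      d[2] != data$n_events || d[3] != data$horizon)
    stop_domain("hazard tensor dimensions do not match the dataset")
  cpp_collapsed_nll(haz_Ln_from_array(hazards), data$events, data$times,
                    data$n_events, data$horizon)
}
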