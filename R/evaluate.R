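# Evaluation metrics: hazard MAE (x100), time-resolved MAE, IPCW integrated
# Brier score, cause-specific time-dependent concordance, bootstrap CIs and
# the Schoenfeld proportional-hazards screen.

#' Mean absolute error of hazard predictions (x100)
#'
#' \code{100 * mean(|predicted - truth|)} over all (patient, event, time)
#' cells; the x100 scale is used for readability.
#'
#' @param predicted,truth hazard arrays of identical shape.
#' @return non-negative scalar.
#' @export
hazard_mae <- function(predicted, truth) {
  if (!identical(dim(predicted), dim(truth)))
    stop_domain("predicted and truth hazard tensors must have the same shape")
  100 * mean(abs(predicted - truth))
}

#' Time-resolved hazard MAE (x100)
#'
#' MAE restricted to each time index; its unweighted mean over time equals
#' [hazard_mae()].
#'
#' @param predicted,truth \code{(n, E, T)} hazard arrays.
#' @return numeric vector of length T.
#' @export
hazard_mae_by_time <- function(predicted, truth) {
  if (!identical(dim(predicted), dim(truth)))
    stop_domain("predicted and truth hazard tensors must have the same shape")
  T <- dim(predicted)[3]
  vapply(seq_len(T), function(t)
    100 * mean(abs(predicted[, , t] - truth[, , t])), numeric(1))
}

# per-patient cumulative incidence curves from an (n, E, T) hazard tensor:
# returns an (n, E, T) array of CIF values
cif_from_hazard <- function(hazards) {
  d <- dim(hazards); n <- d[1]; E <- d[2]; T <- d[3]
  tot <- hazards[, 1, , drop = TRUE]
  if (E > 1L) for (e in 2:E) tot <- tot + hazards[, e, , drop = TRUE]
  tot <- matrix(tot, n, T)
  cp <- t(apply(pmax(1 - tot, 0), 1, cumprod))
  if (T == 1L) cp <- matrix(cp, n, 1L)
  event_free <- cbind(rep(1, n), cp[, -T, drop = FALSE])
  out <- array(NA_real_, d)
  for (e in seq_len(E)) {
    inc <- matrix(hazards[, e, ], n, T) * event_free
    ci <- t(apply(inc, 1, cumsum))
    out[, e, ] <- if (T == 1L) matrix(ci, n, 1L) else ci
  }
  out
}

# Kaplan-Meier estimate of the censoring survival G(u) = P(C > u) on the
# shifted time scale u = t + 1; returns a step-function evaluator
km_censor_survival <- function(data) {
  fit <- survival::survfit(survival::Surv(data$times + 1, data$events == 0L) ~ 1)
  function(u) {
    u <- pmax(u, 0)
    s <- summary(fit, times = sort(unique(u)), extend = TRUE)
    s$surv[match(u, s$time)]
  }
}

#' Integrated Brier score with IPCW censoring weights
#'
#' Predictions are converted to per-event cumulative incidence curves; at
#' each grid time t and event e the Brier score compares the predicted
#' \code{I_e(t)} with the observed indicator of event e by t. Censoring is
#' handled by inverse-probability-of-censoring weights from a Kaplan-Meier
#' estimate of the censoring distribution (patients censored by t get weight
#' 0; weights are renormalized at each grid time, which keeps the score in
#' \code{[0, 1]}). The score is averaged over the time grid with equal
#' weights and over events.
#'
#' @param predicted \code{(n, E, T)} hazard array.
#' @param data a [competing_risks_dataset()] with the observed outcomes.
#' @return scalar integrated Brier score (lower is better).
#' @export
integrated_brier_score <- function(predicted, data) {
  d <- dim(predicted)
  n <- d[1]; E <- d[2]; T <- d[3]
  if (n != length(data$events))
    stop_domain("prediction and dataset sizes differ")
  cif <- cif_from_hazard(predicted)
  G <- km_censor_survival(data)
  g_at_event <- G(data$times)      # P(C >= T_i): weight for observed events
  g_at_grid <- G(seq_len(T))       # P(C > t) at grid t = 0..T-1
  total <- 0; n_terms <- 0L
  for (t in seq_len(T) - 1L) {
    had_event <- data$events > 0L & data$times <= t
    at_risk <- data$times > t
    w <- numeric(n)
    w[had_event] <- 1 / pmax(g_at_event[had_event], 1e-10)
    w[at_risk] <- 1 / pmax(g_at_grid[t + 1L], 1e-10)
    if (sum(w) <= 0) next
    for (e in seq_len(E)) {
      obs <- as.numeric(had_event & data$events == e)
      err <- (obs - cif[, e, t + 1L])^2
      total <- total + sum(w * err) / sum(w)
      n_terms <- n_terms + 1L
    }
  }
  if (n_terms == 0L)
    stop_domain("integrated Brier score undefined: no usable grid points")
  total / n_terms
}

#' Cause-specific time-dependent concordance index
#'
#' Over admissible pairs (patient i experienced event e at \code{t_i};
#' patient j still under observation after \code{t_i}), the fraction of
#' pairs in which the predicted cumulative incidence \code{I_e(t_i)} of i
#' exceeds that of j; prediction ties count 1/2. Reported per event and as
#' the unweighted mean over events.
#'
#' @inheritParams integrated_brier_score
#' @return list with \code{mean} and per-event vector \code{by_event}.
#' @export
time_dependent_concordance <- function(predicted, data) {
  d <- dim(predicted)
  E <- d[2]
  cif <- cif_from_hazard(predicted)
  by_event <- rep(NA_real_, E)
  for (e in seq_len(E)) {
    conc <- 0; pairs <- 0
    fail <- which(data$events == e)
    for (i in fail) {
      t_i <- data$times[i]
      comp <- data$times > t_i
      if (!any(comp)) next
      ri <- cif[i, e, t_i + 1L]
      rj <- cif[comp, e, t_i + 1L]
      conc <- conc + sum(ri > rj) + 0.5 * sum(ri == rj)
      pairs <- pairs + length(rj)
    }
    by_event[e] <- if (pairs > 0) conc / pairs else NA_real_
  }
  if (all(is.na(by_event)))
    stop_domain("concordance undefined: no comparable pairs")
  list(mean = mean(by_event, na.rm = TRUE), by_event = by_event)
}

#' Bootstrap confidence interval for an evaluation metric
#'
#' Resamples patients with replacement B times and reports the mean with
#' empirical 2.5/97.5 percentiles. Degenerate resamples on which the metric
#' is undefined are redrawn (counted and warned about).
#'
#' @param metric function \code{(predicted, data) -> scalar}.
#' @param predicted \code{(n, E, T)} hazard array.
#' @param data a [competing_risks_dataset()].
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return list of class \code{"eval_report"}: \code{estimate}, \code{lower},
#'   \code{upper}, \code{n_bootstrap}, \code{n_redrawn}, \code{values}.
#' @export
bootstrap_ci <- function(metric, predicted, data, B = 1000L, seed = NULL) {
  if (B < 100L) stop_domain("B must be at least 100")
  n <- length(data$events)
  point <- metric(predicted, data)
  vals <- numeric(B)
  redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      val <- NA_real_
      for (attempt in 1:10) {
        idx <- sample.int(n, replace = TRUE)
        val <- tryCatch(metric(predicted[idx, , , drop = FALSE],
                               subset_crdata(data, idx)),
                        error = function(e) NA_real_)
        if (is.finite(val)) break
        redrawn <- redrawn + 1L
      }
      vals[b] <- val
    }
  })
  if (redrawn > 0L)
    warning(redrawn, " degenerate bootstrap resample(s) redrawn")
  structure(list(estimate = point, mean = mean(vals, na.rm = TRUE),
                 lower = unname(quantile(vals, 0.025, na.rm = TRUE)),
                 upper = unname(quantile(vals, 0.975, na.rm = TRUE)),
                 n_bootstrap = B, n_redrawn = redrawn, values = vals),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%.4f (95%% CI %.4f-%.4f; %d bootstrap resamples)\n",
              x$estimate, x$lower, x$upper, x$n_bootstrap))
  invisible(x)
}

#' Schoenfeld-residual proportional-hazards screen
#'
#' Per competing event, fits a cause-specific Cox proportional-hazards model
#' (competing events treated as censored at their time) and tests each
#' covariate's Schoenfeld residuals for association with time. Covariates
#' with p < \code{alpha} are flagged as violating the proportional-hazards
#' assumption. P-values are reported raw (no multiplicity correction).
#'
#' @param data a [competing_risks_dataset()] with at least 2 covariates and
#'   at least 10 observed events per cause.
#' @param alpha flagging threshold (default 0.05).
#' @return data.frame with columns \code{event}, \code{variable}, \code{p},
#'   \code{flagged}.
#' @export
proportional_hazards_screen <- function(data, alpha = 0.05) {
  p <- ncol(data$covariates)
  if (p < 2L) stop_domain("screen requires at least 2 covariates")
  vars <- colnames(data$covariates) %||% paste0("Z", seq_len(p))
  df <- as.data.frame(data$covariates)
  names(df) <- vars
  out <- list()
  for (e in seq_len(data$n_events)) {
    status <- as.integer(data$events == e)
    if (sum(status) < 10L)
      stop_domain("fewer than 10 observed events for cause ", e)
    pv <- tryCatch({
      fml <- stats::as.formula(paste("survival::Surv(time, status) ~",
                                     paste(vars, collapse = " + ")))
      dfe <- cbind(df, time = data$times + 1, status = status)
      cfit <- survival::coxph(fml, data = dfe)
      zph <- survival::cox.zph(cfit)
      zph$table[vars, "p"]
    }, error = function(err) {
      warning("Schoenfeld screen failed for event ", e, ": ",
              conditionMessage(err))
      rep(NA_real_, p)
    })
    out[[e]] <- data.frame(event = e, variable = vars, p = unname(pv),
                           flagged = !is.na(pv) & pv < alpha)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
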