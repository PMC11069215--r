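# Synthetic competing-risks cohort generation: covariates, ground-truth
# hazards, sequential outcome sampling and independent uniform censoring.

#' Draw a covariate matrix
#'
#' Independent Uniform(0, 1) covariates, reproducible under a fixed seed.
#'
#' @param n,p number of patients and covariates.
#' @param seed integer seed (optional).
#' @return n x p numeric matrix with columns named \code{Z1..Zp}.
#' @export
draw_covariates <- function(n, p, seed = NULL) {
  n <- as.integer(n); p <- as.integer(p)
  if (n < 1L || p < 1L) stop_domain("n and p must be positive")
  X <- with_seed(seed, matrix(runif(n * p), n, p))
  colnames(X) <- paste0("Z", seq_len(p))
  X
}

#' Ground-truth hazard tensor from hazard specifications
#'
#' Evaluates one [hazard_spec()] per competing event on every patient and
#' time step.
#'
#' @param covariates n x p covariate matrix.
#' @param specs list of E hazard specs, one per event.
#' @param horizon number of time steps T.
#' @return \code{(n, E, T)} hazard array.
#' @export
truth_hazards <- function(covariates, specs, horizon) {
  covariates <- as.matrix(covariates)
  n <- nrow(covariates); E <- length(specs); T <- as.integer(horizon)
  tgrid <- seq_len(T) - 1L
  out <- array(NA_real_, dim = c(n, E, T))
  for (e in seq_len(E)) {
    lam <- specs[[e]]$rule(covariates, tgrid, specs[[e]]$params)
    if (any(lam <= 0) || any(lam >= 1))
      stop_domain("invalid spec '", specs[[e]]$name,
                  "': hazard outside the open interval (0, 1)")
    out[, e, ] <- lam
  }
  tot <- out[, 1, , drop = TRUE]
  if (E > 1L) for (e in 2:E) tot <- tot + out[, e, , drop = TRUE]
  if (max(tot) >= 1)
    stop_domain("invalid specs: total per-step hazard reaches ", round(max(tot), 4))
  out
}

#' Sample competing-risks outcomes from a hazard tensor
#'
#' Sequential discrete-time sampling: at each event-free step t a categorical
#' outcome is drawn with probabilities \code{(lambda_1(t), ...,
#' lambda_E(t), 1 - sum lambda)}; the first non-survival draw fixes
#' \code{(e, t)}. Patients event-free past the horizon are coded as censored
#' at \code{T} (administrative end of study, known event-free at every grid
#' step).
#'
#' @param truth \code{(n, E, T)} hazard array.
#' @param seed integer seed (optional).
#' @return list with integer vectors \code{events} and \code{times}.
#' @export
sample_outcomes <- function(truth, seed = NULL) {
  d <- dim(truth)
  n <- d[1]; E <- d[2]; T <- d[3]
  with_seed(seed, {
    events <- integer(n)
    times <- rep.int(T, n)
    alive <- seq_len(n)
    for (t in seq_len(T)) {
      if (!length(alive)) break
      lam <- matrix(truth[alive, , t], nrow = length(alive), ncol = E)
      cum <- lam
      if (E > 1L) for (e in 2:E) cum[, e] <- cum[, e - 1L] + lam[, e]
      u <- runif(length(alive))
      k <- rowSums(u >= cum)          # number of event thresholds exceeded
      hit <- k < E
      if (any(hit)) {
        events[alive[hit]] <- k[hit] + 1L
        times[alive[hit]] <- t - 1L
      }
      alive <- alive[!hit]
    }
    list(events = events, times = times)
  })
}

#' Apply independent uniform censoring
#'
#' Draws a censoring time C uniformly on \code{\{low, ..., high\}} per
#' patient; when C is strictly anterior to the recorded time (\code{C < t})
#' the outcome is replaced by \code{(0, C)}. Ties (\code{C = t}) keep the
#' event.
#'
#' @param events,times outcome vectors from [sample_outcomes()].
#' @param low,high support of the uniform censoring draw (defaults 1 and 49).
#' @param seed integer seed (optional).
#' @return list with the censored \code{events} and \code{times}.
#' @export
apply_censoring <- function(events, times, low = 1L, high = 49L, seed = NULL) {
  low <- as.integer(low); high <- as.integer(high)
  if (low > high) stop_domain("censoring support is empty (low > high)")
  n <- length(events)
  with_seed(seed, {
    C <- sample.int(high - low + 1L, n, replace = TRUE) + low - 1L
    cens <- C < times
    events[cens] <- 0L
    times[cens] <- C[cens]
    list(events = events, times = times)
  })
}

#' Simulate one synthetic competing-risks cohort
#'
#' Covariates, ground-truth hazards, sampled outcomes and censoring under a
#' [simulation_design()], with sub-seeds derived from the design's master
#' seed.
#'
#' @param design a [simulation_design()].
#' @param specs list of hazard specs (default [default_hazard_specs()]).
#' @return list with \code{data} (a [competing_risks_dataset()]) and
#'   \code{truth} (the \code{(n, E, T)} ground-truth hazard array).
#' @export
simulate_cohort <- function(design, specs = default_hazard_specs(design$horizon)) {
  X <- draw_covariates(design$n_patients, design$n_covariates,
                       seed = seed_stream(design$seed, 1L))
  truth <- truth_hazards(X, specs, design$horizon)
  out <- sample_outcomes(truth, seed = seed_stream(design$seed, 2L))
  out <- apply_censoring(out$events, out$times, design$censor_low,
                         design$censor_high, seed = seed_stream(design$seed, 3L))
  list(data = competing_risks_dataset(X, out$events, out$times,
                                      length(specs), design$horizon),
       truth = truth)
}

#' Generate benchmark replicates
#'
#' One covariate draw per cohort; outcomes and censoring are redrawn
#' \code{n_replicates} times under distinct sub-seeds, retaining the shared
#' ground-truth hazards for scoring.
#'
#' @inheritParams simulate_cohort
#' @return list with \code{covariates}, \code{truth} and \code{replicates}
#'   (a list of [competing_risks_dataset()]s).
#' @export
generate_benchmark_replicates <- function(design,
                                          specs = default_hazard_specs(design$horizon)) {
  X <- draw_covariates(design$n_patients, design$n_covariates,
                       seed = seed_stream(design$seed, 1L))
  truth <- truth_hazards(X, specs, design$horizon)
  reps <- lapply(seq_len(design$n_replicates), function(r) {
    out <- sample_outcomes(truth, seed = seed_stream(design$seed, 100L + r))
    out <- apply_censoring(out$events, out$times, design$censor_low,
                           design$censor_high,
                           seed = seed_stream(design$seed, 200L + r))
    competing_risks_dataset(X, out$events, out$times, length(specs),
                            design$horizon)
  })
  list(covariates = X, truth = truth, replicates = reps)
}

#' Write / read a cohort as delimited text
#'
#' Columns \code{Z1..Zp, event, time} with a header row; the reader restores
#' a [competing_risks_dataset()] exactly.
#'
#' @param data a [competing_risks_dataset()].
#' @param path file path.
#' @export
write_cohort <- function(data, path) {
  df <- as.data.frame(data$covariates)
  df$event <- data$events
  df$time <- data$times
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param n_events,horizon dataset dimensions (stored outside the file).
#' @export
read_cohort_simple <- function(path, n_events, horizon) {
  df <- read.csv(path)
  cov <- as.matrix(df[, setdiff(names(df), c("event", "time")), drop = FALSE])
  competing_risks_dataset(cov, df$event, df$time, n_events, horizon)
}
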