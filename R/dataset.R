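#' Discrete-time competing-risks dataset
#'
#' Bundles a covariate matrix with per-patient outcomes \code{(event, time)}.
#' Event codes are integers in \code{0, ..., E} with \code{0} denoting
#' censoring; times are 0-based integers in \code{0, ..., T - 1}. A censored
#' time of exactly \code{T} is additionally allowed and means the patient is
#' known event-free through the whole horizon (administrative end of study):
#' such a record contributes event-free information at every step, unlike a
#' censoring inside the grid whose status at its own step is unknown.
#'
#' @param covariates numeric matrix, one row per patient.
#' @param events integer vector of event codes (0 = censored).
#' @param times integer vector of 0-based event/censoring times.
#' @param n_events number of competing events E.
#' @param horizon number of discrete time steps T.
#' @return An object of class \code{"crdata"} with fields \code{covariates},
#'   \code{events}, \code{times}, \code{n_events}, \code{horizon}.
#' @examples
#' d <- competing_risks_dataset(matrix(runif(20), 10, 2),
#'                              events = rep(c(0L, 1L), 5),
#'                              times = rep(c(3L, 1L), 5),
#'                              n_events = 1, horizon = 5)
#' d
#' @export
competing_risks_dataset <- function(covariates, events, times, n_events, horizon) {
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  events <- as.integer(events)
  times <- as.integer(times)
  n <- nrow(covariates)
  if (length(events) != n || length(times) != n)
    stop_domain("events and times must have one entry per covariate row")
  if (anyNA(covariates))
    stop_domain("covariates contain missing values; impute before constructing the dataset")
  if (anyNA(events) || anyNA(times))
    stop_domain("events and times must not contain missing values")
  n_events <- as.integer(n_events)
  horizon <- as.integer(horizon)
  if (n_events < 1L || horizon < 1L)
    stop_domain("n_events and horizon must be positive integers")
  if (any(events < 0L) || any(events > n_events))
    stop_domain("event codes must lie in {0, ..., ", n_events, "}")
  if (any(times < 0L) || any(times > horizon))
    stop_domain("times must lie in {0, ..., ", horizon, "}")
  if (any(times == horizon & events != 0L))
    stop_domain("time ", horizon, " (past the grid) is reserved for ",
                "censored, fully event-free patients")
  structure(
    list(covariates = covariates, events = events, times = times,
         n_events = n_events, horizon = horizon),
    class = "crdata")
}

#' @export
print.crdata <- function(x, ...) {
  n <- nrow(x$covariates)
  cens <- mean(x$events == 0L)
  cat(sprintf("Discrete-time competing-risks dataset: %d patients, %d covariates\n",
              n, ncol(x$covariates)))
  cat(sprintf("  %d competing events over %d time steps; %.1f%% censored\n",
              x$n_events, x$horizon, 100 * cens))
  invisible(x)
}

#' @export
dim.crdata <- function(x) c(nrow(x$covariates), ncol(x$covariates))

# subset a dataset by patient index
subset_crdata <- function(data, idx) {
  competing_risks_dataset(data$covariates[idx, , drop = FALSE],
                          data$events[idx], data$times[idx],
                          data$n_events, data$horizon)
}

#' Validate a hazard tensor
#'
#' A hazard tensor is an \code{(n, E, T)} array of discrete-time hazard
#' probabilities; each entry must lie in the open interval (0, 1) and, for
#' every patient and time step, the total hazard summed over events must not
#' exceed 1 (strictly less than 1 in the interior; a total of exactly 1 is
#' the degenerate boundary at which the survival factor reaches 0).
#'
#' @param x numeric array of dimension \code{(n, E, T)}.
#' @param strict if \code{TRUE}, require the per-step total hazard to be
#'   strictly below 1.
#' @return \code{x}, invisibly, if valid; otherwise an error.
#' @export
validate_hazard_tensor <- function(x, strict = FALSE) {
  if (length(dim(x)) != 3L)
    stop_domain("hazard tensor must be an (n, E, T) array")
  if (any(x <= 0) || any(x >= 1))
    stop_domain("hazard entries must lie strictly inside (0, 1)")
  tot <- apply(x, c(1, 3), sum)
  lim <- if (strict) 1 else 1 + 1e-12
  if (any(tot > lim) || (strict && any(tot >= 1)))
    stop_domain("total per-step hazard across events must not exceed 1")
  invisible(x)
}
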