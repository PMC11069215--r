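# Integrated-gradients feature attribution for differentiable hazard models.
#
# For a scalar target F (by default the sum of all predicted hazards, or the
# sum over one event's row), the attribution of feature i is
#   (x_i - b_i) * mean over path points of dF/dx_i at b + alpha (x - b),
# approximated by a midpoint Riemann sum. The completeness axiom
# sum_i attribution_i = F(x) - F(b) holds up to the Riemann error.

ig_mask <- function(config, target, event) {
  E <- config$n_events; T <- config$horizon
  m <- matrix(0, E, T)
  if (target == "all") m[] <- 1
  else {
    if (is.null(event) || event < 1 || event > E)
      stop_domain("target = 'event' requires an event code in 1..", E)
    m[event, ] <- 1
  }
  as.vector(t(m))  # token order l = (e-1)*T + t
}

ig_target_value <- function(model, X, mask) {
  M <- if (model$kind == "transformer")
    cpp_tf_forward(X, model$params, model$config)
  else
    cpp_dh_forward(X, model$params, model$config)
  drop(crossprod(M, mask))
}

#' Integrated-gradients attribution for one patient
#'
#' @param model a fitted [hazard_model()].
#' @param input covariate vector of length p.
#' @param baseline reference covariate vector (default all zeros).
#' @param target \code{"all"} (sum of predicted hazards over all (event,
#'   time) cells) or \code{"event"} (sum over one event's row).
#' @param event event code when \code{target = "event"}.
#' @param steps number of midpoint Riemann steps (at least 16; default 128).
#' @return object of class \code{"attribution"}: per-feature
#'   \code{attributions}, the \code{baseline}, \code{steps}, the target
#'   values at input and baseline and the \code{completeness_gap}.
#' @export
integrated_gradients <- function(model, input, baseline = NULL,
                                 target = c("all", "event"), event = NULL,
                                 steps = 128L) {
  target <- match.arg(target)
  steps <- as.integer(steps)
  if (steps < 16L) stop_domain("steps must be at least 16")
  p <- model$config$p
  input <- as.numeric(input)
  if (length(input) != p) stop_domain("input must have length ", p)
  baseline <- if (is.null(baseline)) numeric(p) else as.numeric(baseline)
  if (length(baseline) != p) stop_domain("baseline must have length ", p)

  mask <- ig_mask(model$config, target, event)
  alphas <- (seq_len(steps) - 0.5) / steps
  path <- outer(alphas, input - baseline) +
    matrix(baseline, steps, p, byrow = TRUE)
  vjp <- model_vjp(model, path, matrix(mask, length(mask), steps))
  grads <- colMeans(vjp$dX)
  attr <- (input - baseline) * grads

  f_x <- ig_target_value(model, matrix(input, 1, p), mask)
  f_b <- ig_target_value(model, matrix(baseline, 1, p), mask)
  names(attr) <- colnames(model$params$Wx) %||% paste0("Z", seq_len(p))
  structure(list(attributions = attr, baseline = baseline, steps = steps,
                 target_input = f_x, target_baseline = f_b,
                 completeness_gap = abs(sum(attr) - (f_x - f_b))),
            class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf("Integrated gradients (%d steps, completeness gap %.2e)\n",
              x$steps, x$completeness_gap))
  print(round(x$attributions, 5))
  invisible(x)
}

# cohort baseline: per-feature median for continuous features, most frequent
# value for binary features (ties toward 0)
cohort_baseline <- function(covariates) {
  apply(covariates, 2, function(col) {
    obs <- col[!is.na(col)]
    if (all(obs %in% c(0, 1))) {
      as.numeric(mean(obs) > 0.5)   # tie (0.5) broken toward 0
    } else {
      median(obs)
    }
  })
}

#' Cohort-level feature importance
#'
#' Mean absolute integrated-gradients attribution per feature across all
#' patients, against a "typical patient" baseline (per-feature cohort
#' median; most frequent value for binary features), ranked in descending
#' order.
#'
#' @param model a fitted [hazard_model()].
#' @param data a [competing_risks_dataset()].
#' @param target,event scalar target passed to [integrated_gradients()].
#' @param steps Riemann steps per patient (default 128).
#' @param top_k optionally keep only the k most important features.
#' @return data.frame with columns \code{feature}, \code{importance},
#'   ordered by decreasing importance.
#' @export
cohort_importance <- function(model, data, target = c("all", "event"),
                              event = NULL, steps = 128L, top_k = NULL) {
  target <- match.arg(target)
  X <- data$covariates
  n <- nrow(X)
  if (n == 0L) stop_domain("empty dataset")
  p <- ncol(X)
  b <- cohort_baseline(X)
  mask <- ig_mask(model$config, target, event)
  alphas <- (seq_len(steps) - 0.5) / steps

  # stack (patient, step) rows and evaluate input gradients in chunks
  scores <- matrix(NA_real_, n, p)
  chunk <- max(1L, 4096L %/% steps)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    diff <- X[idx, , drop = FALSE] - matrix(b, length(idx), p, byrow = TRUE)
    path <- matrix(NA_real_, length(idx) * steps, p)
    for (k in seq_along(idx))
      path[(k - 1L) * steps + seq_len(steps), ] <-
        outer(alphas, diff[k, ]) + matrix(b, steps, p, byrow = TRUE)
    vjp <- model_vjp(model, path, matrix(mask, length(mask), nrow(path)))
    for (k in seq_along(idx)) {
      g <- colMeans(vjp$dX[(k - 1L) * steps + seq_len(steps), , drop = FALSE])
      scores[idx[k], ] <- diff[k, ] * g
    }
  }
  imp <- colMeans(abs(scores))
  out <- data.frame(feature = colnames(X) %||% paste0("Z", seq_len(p)),
                    importance = imp)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- head(out, top_k)
  out
}
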