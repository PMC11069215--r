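# Model fitting: seeded train/validation split and Adam minimization of the
# mean negative collapsed log-likelihood with early stopping on validation
# loss.

#' Split a dataset into training and validation parts
#'
#' Disjoint, exhaustive, seeded random partition by patient.
#'
#' @param data a [competing_risks_dataset()].
#' @param fraction training fraction (default 0.8).
#' @param seed integer seed.
#' @return list with \code{train}, \code{validation} and the index vectors
#'   \code{train_idx}, \code{validation_idx}.
#' @export
split_dataset <- function(data, fraction = 0.8, seed = NULL) {
  if (fraction <= 0 || fraction >= 1)
    stop_domain("fraction must lie strictly between 0 and 1")
  n <- length(data$events)
  n_train <- round(fraction * n)
  idx <- with_seed(seed, sample.int(n))
  tr <- sort(idx[seq_len(n_train)])
  va <- sort(idx[-seq_len(n_train)])
  list(train = subset_crdata(data, tr), validation = subset_crdata(data, va),
       train_idx = tr, validation_idx = va)
}

#' Training configuration
#'
#' @param split_fraction training fraction of the 80/20 split.
#' @param epochs maximum number of epochs.
#' @param batch_size minibatch size.
#' @param learning_rate initial Adam step size.
#' @param patience early-stopping patience (epochs without validation
#'   improvement); the best-validation parameters are restored.
#' @param lr_patience,lr_factor reduce-on-plateau schedule: after
#'   \code{lr_patience} epochs without validation improvement the learning
#'   rate is multiplied by \code{lr_factor}.
#' @param seed seed controlling initialization and batch shuffling.
#' @return list of class \code{"train_config"}.
#' @export
train_config <- function(split_fraction = 0.8, epochs = 200L, batch_size = 256L,
                         learning_rate = 1e-3, patience = 20L,
                         lr_patience = 5L, lr_factor = 0.5, seed = 1L) {
  structure(list(split_fraction = split_fraction, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, patience = as.integer(patience),
                 lr_patience = as.integer(lr_patience), lr_factor = lr_factor,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Base-rate output-bias initialization: start the sigmoid outputs at the
# training data's marginal per-event discrete hazard (events of cause e per
# at-risk patient-step) instead of an arbitrary level, so early epochs fit
# covariate and time effects rather than the overall scale.
calibrate_output_bias <- function(model, train) {
  at_risk <- sum(train$times + as.integer(train$events > 0L))
  h <- vapply(seq_len(train$n_events), function(e)
    sum(train$events == e) / max(at_risk, 1L), numeric(1))
  h <- pmin(pmax(h, 1e-4), 0.5)
  params <- model$params
  if (model$kind == "transformer") {
    params$bout[] <- qlogis(mean(h))
  } else {
    for (e in seq_len(train$n_events))
      params[[paste0("ev", e, "_b2")]][] <- qlogis(h[e])
  }
  params
}

# negative collapsed log-likelihood of a model on a dataset (no gradients)
model_loss <- function(model, data) {
  M <- if (model$kind == "transformer")
    cpp_tf_forward(data$covariates, model$params, model$config)
  else
    cpp_dh_forward(data$covariates, model$params, model$config)
  cpp_collapsed_nll(M, data$events, data$times, data$n_events, data$horizon)
}

#' Fit a hazard model
#'
#' Minimizes the mean negative collapsed log-likelihood by Adam over
#' shuffled minibatches; tracks per-epoch training and validation loss and
#' restores the parameters of the best validation epoch.
#'
#' @param model a [hazard_model()].
#' @param train,validation [competing_risks_dataset()]s.
#' @param config a [train_config()].
#' @param verbose print per-epoch losses.
#' @return the fitted model, with a \code{trace} data.frame (epoch,
#'   train_loss, val_loss) and \code{best_epoch} attached.
#' @export
fit <- function(model, train, validation, config = train_config(),
                verbose = FALSE) {
  if (ncol(train$covariates) != model$config$p)
    stop_domain("training covariate dimension does not match the model")
  n <- length(train$events)
  model$params <- calibrate_output_bias(model, train)
  params <- model$params
  m1 <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  m2 <- m1
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  step <- 0L

  best <- list(loss = Inf, params = params, epoch = 0L)
  trace <- data.frame(epoch = integer(), train_loss = double(),
                      val_loss = double())
  wait <- 0L
  lr_wait <- 0L

  with_seed(config$seed, {
    # epoch 0: validation loss of the untrained model is the selection floor
    val0 <- model_loss(model, validation)
    best$loss <- val0
    trace <- rbind(trace, data.frame(epoch = 0L, train_loss = NA_real_,
                                     val_loss = val0))
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        bi <- ord[s:min(s + config$batch_size - 1L, n)]
        model$params <- params
        lg <- model_loss_grad(model, train$covariates[bi, , drop = FALSE],
                              train$events[bi], train$times[bi])
        if (!is.finite(lg$loss)) {
          err <- simpleError("training diverged: non-finite loss")
          err$trace <- trace
          stop(err)
        }
        ep_loss <- ep_loss + lg$loss * length(bi)
        step <- step + 1L
        corr <- sqrt(1 - b2^step) / (1 - b1^step)
        for (nm in names(params)) {
          g <- as.numeric(lg$grads[[nm]])
          m1[[nm]] <- b1 * m1[[nm]] + (1 - b1) * g
          m2[[nm]] <- b2 * m2[[nm]] + (1 - b2) * g * g
          params[[nm]] <- params[[nm]] - lr * corr * m1[[nm]] /
            (sqrt(m2[[nm]]) + eps)
        }
      }
      model$params <- params
      vl <- model_loss(model, validation)
      trace <- rbind(trace, data.frame(epoch = ep, train_loss = ep_loss / n,
                                       val_loss = vl))
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", ep, ep_loss / n, vl))
      # epoch selection and patience run on a 3-epoch moving average of the
      # validation loss: per-epoch differences near convergence are smaller
      # than the validation set's sampling noise, and raw-argmin selection
      # whipsaws on that noise
      k <- nrow(trace)
      vl_s <- mean(trace$val_loss[max(2, k - 2):k])
      if (vl_s < best$loss - 1e-9) {
        best <- list(loss = vl_s, params = params, epoch = ep)
        wait <- 0L
        lr_wait <- 0L
      } else {
        wait <- wait + 1L
        lr_wait <- lr_wait + 1L
        if (wait >= config$patience) break
        if (lr_wait >= (config$lr_patience %||% config$patience)) {
          lr <- lr * (config$lr_factor %||% 1)
          lr_wait <- 0L
        }
      }
    }
  })
  model$params <- best$params
  model$trace <- trace
  model$best_epoch <- best$epoch
  model
}
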