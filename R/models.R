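# Hazard models: a transformer encoder over (event, time) tokens and a
# DeepHit-style per-event feed-forward baseline. Both map an n x p covariate
# matrix to an (n, E, T) tensor of hazard probabilities; the numerical
# forward/backward passes live in src/nn.cpp.

#' Transformer hazard model configuration
#'
#' The covariate vector is linearly encoded, broadcast across a token
#' sequence of length E x T (one token per (event, time) cell), concatenated
#' with a learned embedding of the token's (event, time) index, summed with a
#' sinusoidal positional encoding, passed through a transformer encoder, and
#' decoded token-wise by a single linear layer with a sigmoid link.
#'
#' @param p covariate dimension.
#' @param n_events,horizon output dimensions E and T.
#' @param d_cov,d_emb width of the covariate encoding and of the token-index
#'   embedding; the model width is their sum.
#' @param n_layers,n_heads encoder depth and attention heads. One encoder
#'   layer with two heads is the default: the covariates enter as a
#'   singleton-length sequence, so a single round of attention mixing over
#'   the (event, time) tokens suffices and keeps single-CPU training within
#'   minutes.
#' @param hidden_units width of the encoder's position-wise (ReLU)
#'   feed-forward hidden layer (64 reproduces the benchmark setting).
#' @param dropout dropout probability (0 reproduces the benchmark setting;
#'   only 0 is supported).
#' @return configuration list of class \code{"transformer_config"}.
#' @export
transformer_config <- function(p, n_events, horizon, d_cov = 16L, d_emb = 16L,
                               n_layers = 1L, n_heads = 2L, hidden_units = 64L,
                               dropout = 0) {
  if (dropout != 0) stop_domain("only dropout = 0 is supported")
  cfg <- list(p = as.integer(p), n_events = as.integer(n_events),
              horizon = as.integer(horizon), d_cov = as.integer(d_cov),
              d_emb = as.integer(d_emb), n_layers = as.integer(n_layers),
              n_heads = as.integer(n_heads), ffn_dim = as.integer(hidden_units),
              hidden_units = as.integer(hidden_units), dropout = 0)
  if ((cfg$d_cov + cfg$d_emb) %% cfg$n_heads != 0L)
    stop_domain("model width (d_cov + d_emb) must be divisible by n_heads")
  class(cfg) <- c("transformer_config", "model_config")
  cfg
}

#' DeepHit-style baseline configuration
#'
#' One independent feed-forward subnetwork per competing event: a single
#' ReLU hidden layer of \code{hidden_units} neurons mapping the covariates
#' to T per-time outputs with a sigmoid link.
#'
#' @inheritParams transformer_config
#' @param hidden_units hidden-layer width (64 reproduces the benchmark
#'   setting).
#' @return configuration list of class \code{"deephit_config"}.
#' @export
deephit_config <- function(p, n_events, horizon, hidden_units = 64L,
                           dropout = 0) {
  if (dropout != 0) stop_domain("only dropout = 0 is supported")
  cfg <- list(p = as.integer(p), n_events = as.integer(n_events),
              horizon = as.integer(horizon),
              hidden_units = as.integer(hidden_units), dropout = 0)
  class(cfg) <- c("deephit_config", "model_config")
  cfg
}

glorot <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)

# Framework-default initialization (Glorot weights, zero biases) under a
# seeded generator; fit() recalibrates the output bias to the training
# data's marginal hazard before the first step.
init_params <- function(config, seed = NULL) {
  if (inherits(config, "transformer_config")) init_params_transformer(config, seed)
  else init_params_deephit(config, seed)
}

init_params_transformer <- function(config, seed = NULL) {
  with_seed(seed, {
    d <- config$d_cov + config$d_emb
    L <- config$n_events * config$horizon
    P <- list(Wx = glorot(config$d_cov, config$p),
              bx = matrix(0, config$d_cov, 1),
              Emb = matrix(rnorm(config$d_emb * L, sd = 0.1), config$d_emb, L))
    for (i in seq_len(config$n_layers)) {
      pr <- paste0("enc", i, "_")
      for (w in c("Wq", "Wk", "Wv", "Wo")) P[[paste0(pr, w)]] <- glorot(d, d)
      for (b in c("bq", "bk", "bv", "bo")) P[[paste0(pr, b)]] <- matrix(0, d, 1)
      P[[paste0(pr, "W1")]] <- glorot(config$ffn_dim, d)
      P[[paste0(pr, "b1")]] <- matrix(0, config$ffn_dim, 1)
      P[[paste0(pr, "W2")]] <- glorot(d, config$ffn_dim)
      P[[paste0(pr, "b2")]] <- matrix(0, d, 1)
      P[[paste0(pr, "g1")]] <- matrix(1, d, 1)
      P[[paste0(pr, "be1")]] <- matrix(0, d, 1)
      P[[paste0(pr, "g2")]] <- matrix(1, d, 1)
      P[[paste0(pr, "be2")]] <- matrix(0, d, 1)
    }
    P$wout <- matrix(rnorm(d, sd = sqrt(2 / (d + 1))), 1, d)
    P$bout <- matrix(0, 1, 1)
    P
  })
}

init_params_deephit <- function(config, seed = NULL) {
  with_seed(seed, {
    P <- list()
    for (e in seq_len(config$n_events)) {
      pr <- paste0("ev", e, "_")
      P[[paste0(pr, "W1")]] <- glorot(config$hidden_units, config$p)
      P[[paste0(pr, "b1")]] <- matrix(0, config$hidden_units, 1)
      P[[paste0(pr, "W2")]] <- glorot(config$horizon, config$hidden_units)
      P[[paste0(pr, "b2")]] <- matrix(0, config$horizon, 1)
    }
    P
  })
}

#' Build a hazard model
#'
#' @param config a [transformer_config()] or [deephit_config()].
#' @param seed seed for parameter initialization.
#' @return object of class \code{"hazard_model"} holding the configuration
#'   and trainable parameters.
#' @examples
#' m <- hazard_model(deephit_config(p = 5, n_events = 3, horizon = 30))
#' count_parameters(m)
#' @export
hazard_model <- function(config, seed = NULL) {
  kind <- if (inherits(config, "transformer_config")) "transformer" else "deephit"
  structure(list(kind = kind, config = config,
                 params = init_params(config, seed = seed)),
            class = "hazard_model")
}

#' @export
print.hazard_model <- function(x, ...) {
  cat(sprintf("%s hazard model: p=%d -> E=%d x T=%d (%d trainable parameters)\n",
              x$kind, x$config$p, x$config$n_events, x$config$horizon,
              count_parameters(x)))
  invisible(x)
}

#' Predict the cause-specific hazard tensor
#'
#' @param model a [hazard_model()].
#' @param covariates n x p matrix.
#' @return \code{(n, E, T)} array of hazard probabilities in (0, 1).
#' @export
predict_hazard <- function(model, covariates) {
  X <- as.matrix(covariates)
  if (ncol(X) != model$config$p)
    stop_domain("covariate dimension ", ncol(X), " does not match the model (",
                model$config$p, ")")
  M <- if (model$kind == "transformer")
    cpp_tf_forward(X, model$params, model$config)
  else
    cpp_dh_forward(X, model$params, model$config)
  haz_array_from_Ln(M, model$config$n_events, model$config$horizon)
}

#' Count trainable parameters
#'
#' @param model a [hazard_model()].
#' @return integer number of trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# loss + gradient of the mean negative collapsed log-likelihood for a batch;
# returns list(loss, grads, hazard)
model_loss_grad <- function(model, X, events, times) {
  if (model$kind == "transformer")
    cpp_tf_loss_grad(X, events, times, model$params, model$config)
  else
    cpp_dh_loss_grad(X, events, times, model$params, model$config)
}

# vector-Jacobian product: gradients of sum(dhaz * hazard) w.r.t. parameters
# and inputs; dhaz is an (n, E, T) array (or L x n matrix)
model_vjp <- function(model, X, dhaz) {
  if (length(dim(dhaz)) == 3L) dhaz <- haz_Ln_from_array(dhaz)
  if (model$kind == "transformer")
    cpp_tf_vjp(X, model$params, model$config, dhaz)
  else
    cpp_dh_vjp(X, model$params, model$config, dhaz)
}

#' Save / load a model checkpoint
#'
#' Parameters and configuration are serialized together as JSON (full double
#' precision) so a saved model is reloadable without the training script.
#'
#' @param model a [hazard_model()].
#' @param path file path for the JSON checkpoint.
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(kind = model$kind,
                  config = unclass(model$config),
                  params = lapply(model$params, function(m)
                    list(dim = dim(m), data = as.vector(m))))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- payload$config
  config <- if (payload$kind == "transformer")
    transformer_config(cfg$p, cfg$n_events, cfg$horizon, cfg$d_cov, cfg$d_emb,
                       cfg$n_layers, cfg$n_heads, cfg$hidden_units)
  else
    deephit_config(cfg$p, cfg$n_events, cfg$horizon, cfg$hidden_units)
  params <- lapply(payload$params, function(m)
    matrix(m$data, m$dim[1], m$dim[2]))
  structure(list(kind = payload$kind, config = config, params = params),
            class = "hazard_model")
}
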