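test_that("both models emit (n, E, T) hazards in (0,1), deterministically", {
  set.seed(404)
  X <- matrix(runif(21), 7, 3)
  for (cfg in list(tiny_tf_config(), tiny_dh_config())) {
    m <- hazard_model(cfg, seed = 5)
    H <- predict_hazard(m, X)
    expect_equal(dim(H), c(7, 2, 4))
    expect_true(all(H > 0 & H < 1))
    expect_identical(H, predict_hazard(m, X))
    expect_error(predict_hazard(m, matrix(0.5, 2, 9)), "dimension")
  }
})

test_that("permuting patients permutes predictions identically", {
  set.seed(405)
  X <- matrix(runif(30), 10, 3)
  perm <- sample(10)
  for (cfg in list(tiny_tf_config(), tiny_dh_config())) {
    m <- hazard_model(cfg, seed = 6)
    expect_equal(predict_hazard(m, X)[perm, , ],
                 predict_hazard(m, X[perm, , drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("deephit subnetworks are independent across events", {
  set.seed(406)
  m <- hazard_model(tiny_dh_config(), seed = 7)
  X <- matrix(runif(15), 5, 3)
  before <- predict_hazard(m, X)
  m$params$ev2_W1[] <- 0; m$params$ev2_b1[] <- 0
  m$params$ev2_W2[] <- 0; m$params$ev2_b2[] <- 0
  after <- predict_hazard(m, X)
  expect_identical(before[, 1, ], after[, 1, ])
  expect_false(identical(before[, 2, ], after[, 2, ]))
})

test_that("parameter counts follow the layer arithmetic", {
  dh <- hazard_model(deephit_config(p = 5, n_events = 3, horizon = 30,
                                    hidden_units = 64), seed = 1)
  expect_identical(count_parameters(dh), 3L * ((5L + 1L) * 64L + (64L + 1L) * 30L))
  expect_identical(count_parameters(dh), 7002L)

  tf <- hazard_model(transformer_config(p = 5, n_events = 3, horizon = 30),
                     seed = 1)
  expect_gt(count_parameters(tf), count_parameters(dh))

  dh2 <- hazard_model(deephit_config(5, 3, 30, hidden_units = 128), seed = 1)
  expect_gt(count_parameters(dh2), count_parameters(dh))
})

test_that("analytic gradients agree with central finite differences", {
  ns <- asNamespace("transhaz")
  set.seed(407)
  X <- matrix(runif(9), 3, 3)
  ev <- c(1L, 0L, 2L); tm <- c(2L, 3L, 0L)
  h <- 1e-6

  for (kind in c("transformer", "deephit")) {
    cfg <- if (kind == "transformer") tiny_tf_config() else tiny_dh_config()
    m <- hazard_model(cfg, seed = 11)
    lg <- ns$model_loss_grad(m, X, ev, tm)
    loss_at <- function(P) {
      m2 <- m; m2$params <- P
      ns$model_loss_grad(m2, X, ev, tm)$loss
    }
    for (nm in names(m$params)) {
      for (ii in sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))) {
        Pp <- m$params; Pp[[nm]][ii] <- Pp[[nm]][ii] + h
        Pm <- m$params; Pm[[nm]][ii] <- Pm[[nm]][ii] - h
        num <- (loss_at(Pp) - loss_at(Pm)) / (2 * h)
        ana <- as.numeric(lg$grads[[nm]])[ii]
        if (abs(num) + abs(ana) > 1e-8)
          expect_equal(ana, num, tolerance = 1e-4,
                       label = sprintf("%s grad %s[%d]", kind, nm, ii))
      }
    }
    # input gradients through the vjp used by integrated gradients
    mask <- array(1, c(3, cfg$n_events, cfg$horizon))
    vj <- ns$model_vjp(m, X, mask)
    f <- function(Xm) sum(predict_hazard(m, Xm))
    for (ii in seq_along(X)) {
      Xp <- X; Xp[ii] <- Xp[ii] + h
      Xm2 <- X; Xm2[ii] <- Xm2[ii] - h
      expect_equal(vj$dX[ii], (f(Xp) - f(Xm2)) / (2 * h), tolerance = 1e-5)
    }
  }
})

test_that("losses and gradients stay finite over random inputs", {
  ns <- asNamespace("transhaz")
  set.seed(408)
  for (kind in c("transformer", "deephit")) {
    cfg <- if (kind == "transformer") tiny_tf_config() else tiny_dh_config()
    m <- hazard_model(cfg, seed = 3)
    for (rep in 1:20) {
      X <- matrix(runif(12, -1, 2), 4, 3)   # deliberately off-support inputs
      ev <- sample(0:2, 4, TRUE); tm <- sample(0:3, 4, TRUE)
      lg <- ns$model_loss_grad(m, X, as.integer(ev), as.integer(tm))
      expect_true(is.finite(lg$loss))
      expect_true(all(vapply(lg$grads, function(g) all(is.finite(as.numeric(g))),
                             logical(1))))
    }
  }
})

test_that("models can overfit a small dataset past the best constant predictor", {
  sim <- tiny_cohort(n = 50, seed = 31)
  d <- sim$data
  # best constant-hazard predictor: per-cell MLE over the collapsed cells
  E <- d$n_events; T <- d$horizon
  const <- matrix(NA_real_, E, T)
  for (j in seq_len(E)) for (k in seq_len(T) - 1L) {
    kmax <- ifelse(d$events > 0L, d$times, d$times - 1L)
    inrisk <- kmax >= k
    y <- d$events == j & d$times == k
    const[j, k + 1] <- if (any(inrisk)) min(max(mean(y[inrisk]), 1e-4), 1 - 1e-4)
                       else 1e-4
  }
  arr <- aperm(array(const, c(E, T, 50)), c(3, 1, 2))
  floor_loss <- batch_negative_loss(arr, d)

  for (kind in c("transformer", "deephit")) {
    cfg <- if (kind == "transformer")
      transformer_config(5, E, T, d_cov = 8, d_emb = 8, n_heads = 2,
                         hidden_units = 32)
    else deephit_config(5, E, T, hidden_units = 32)
    m <- hazard_model(cfg, seed = 13)
    fitted <- fit(m, d, d, train_config(epochs = 150, batch_size = 50,
                                        learning_rate = 5e-3, patience = 150,
                                        seed = 14))
    expect_lt(min(fitted$trace$val_loss, na.rm = TRUE), floor_loss)
  }
})

test_that("checkpoints round-trip through JSON", {
  m <- hazard_model(tiny_tf_config(), seed = 17)
  tmp <- tempfile(fileext = ".json")
  save_checkpoint(m, tmp)
  m2 <- load_checkpoint(tmp)
  X <- matrix(runif(9), 3, 3)
  expect_equal(predict_hazard(m2, X), predict_hazard(m, X), tolerance = 1e-12)
  expect_identical(m2$kind, "transformer")
  unlink(tmp)
})
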