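# Internal helpers: seeding, reshapes, small validators.

# Evaluate expr with a temporarily-set RNG seed, restoring the caller's RNG
# state afterwards so package functions do not disturb the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Deterministic sub-seed derivation: one master seed spawns named streams so
# covariates, per-replicate outcomes and censoring are independently
# reproducible. Kept below 2^31 and within double precision.
seed_stream <- function(seed, k) {
  as.integer((as.double(seed) * 69069 + as.double(k) * 1234567) %% 2147483629)
}

# L x n hazard matrix (token-major, l = (e-1)*T + t + 1) <-> (n, E, T) array
haz_array_from_Ln <- function(M, E, T) {
  n <- ncol(M)
  aperm(array(M, dim = c(T, E, n)), c(3, 2, 1))
}

haz_Ln_from_array <- function(A) {
  d <- dim(A)
  matrix(aperm(A, c(3, 2, 1)), nrow = d[2] * d[3], ncol = d[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)
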