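# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never perturbs user
# simulations.
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Child seed derivation: a documented counter scheme so pipeline stages and
# subjects are independently reproducible. Kept below 2^31 - 1.
child_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (as.integer(seed) %% 1000003L) * 2011L + stage * 101L + index
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

check_symmetric <- function(m, tol = 1e-10, what = "matrix") {
  if (max(abs(m - t(m))) > tol) {
    stop_invalid("%s is not symmetric within tolerance %g", what, tol)
  }
  invisible(TRUE)
}

# Pairwise great-circle distance between unit-sphere centroids (radians).
great_circle_dist <- function(xyz) {
  g <- tcrossprod(as.matrix(xyz))
  acos(clip(g, -1, 1))
}
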