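# Internal helpers: seed scoping, validation.

# Evaluate `code` under a local RNG stream started from `seed`, restoring the
# caller's RNG state afterwards. All exported stochastic functions take an
# explicit seed and route through this, so no call mutates global RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` child seeds from a parent seed, deterministically and below 2^31,
# so each pipeline stage (or simulation run) gets an independent stream that is
# reproducible in isolation.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_if_not_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  invisible(x)
}

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

check_symmetric <- function(m, tol = 1e-9, name = "matrix") {
  if (!is_square(m)) stop(sprintf("`%s` must be square", name), call. = FALSE)
  if (max(abs(m - t(m))) > tol)
    stop(sprintf("`%s` is asymmetric beyond tolerance %g", name, tol),
         call. = FALSE)
  invisible(m)
}

upper_tri_vec <- function(m) m[upper.tri(m)]
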