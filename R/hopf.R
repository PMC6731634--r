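# Whole-brain model: network-coupled Stuart-Landau (Hopf normal form)
# oscillators. Integrated with the stochastic Heun scheme: a forward-Euler
# predictor creates a sample, and the drift is averaged between the current
# and predicted states (noise enters as plain Euler-Maruyama increments).
# Plain Euler inflates the limit-cycle radius by ~dt*omega^2/2 (6% at
# dt = 0.1 s, omega = 2*pi*0.05); the Heun corrector removes that bias, so
# the radius matches sqrt(a) at the default step.

#' Simulate the coupled Stuart-Landau whole-brain model
#'
#' Integrates, for each node n,
#' \deqn{dx_n = [(a_n - x_n^2 - y_n^2) x_n - \omega_n y_n +
#'   G \sum_p C_{np}(x_p - x_n)] dt + \beta dW}
#' and the symmetric equation for `y_n` (with `+omega_n x_n` and coupling in
#' `y`), with step `dt_s` using a stochastic Heun scheme (second-order drift,
#' Euler-Maruyama noise) and independent Gaussian increments for every node
#' and component. The `x` channel - the model's
#' BOLD-like observable - is subsampled at `tr_s` after discarding the
#' initial `transient_s` seconds. With `G = 0` the system reduces to
#' uncoupled oscillators: a stable limit cycle of radius `sqrt(a)` and
#' frequency `omega/2/pi` for `a > 0`, a stable fixed point for `a < 0`.
#'
#' @param conn a [connectome], or a plain square non-negative coupling
#'   matrix (e.g. an optimized effective connectivity).
#' @param params a [hopf_params].
#' @param duration_s total simulated time, seconds (must exceed the
#'   transient).
#' @param seed integer seed for the noise stream and initial condition.
#' @return Object of class `simulation_result`: `series` (a [regional_ts]
#'   of x), `seed`, `params_snapshot`, `connectome_id`.
#' @export
simulate_hopf <- function(conn, params, duration_s, seed = 1L) {
  C <- if (inherits(conn, "connectome")) conn$weights else as.matrix(conn)
  n <- nrow(C)
  stopifnot(is.numeric(C), ncol(C) == n)
  p <- expand_params(params, n)
  stop_if_not_scalar(duration_s, "duration_s", positive = TRUE)
  if (duration_s <= p$transient_s)
    stop("duration_s must exceed transient_s", call. = FALSE)
  dt <- p$dt_s
  steps_per_tr <- round(p$tr_s / dt)
  transient_steps <- round(p$transient_s / dt)
  n_keep <- floor((duration_s - p$transient_s) / p$tr_s)
  n_steps <- transient_steps + n_keep * steps_per_tr
  gC <- p$G * C
  g_deg <- p$G * rowSums(C)
  noise_sd <- p$beta * sqrt(dt)
  a <- p$a; omega <- p$omega
  out <- matrix(0, n, n_keep)

  drift <- function(x, y) {
    r2 <- x * x + y * y
    list(dx = (a - r2) * x - omega * y + drop(gC %*% x) - g_deg * x,
         dy = (a - r2) * y + omega * x + drop(gC %*% y) - g_deg * y)
  }
  with_seed(seed, {
    x <- stats::rnorm(n, sd = 0.1)
    y <- stats::rnorm(n, sd = 0.1)
    kept <- 0L
    for (s in seq_len(n_steps)) {
      d1 <- drift(x, y)
      d2 <- drift(x + dt * d1$dx, y + dt * d1$dy)
      x <- x + dt * (d1$dx + d2$dx) / 2
      y <- y + dt * (d1$dy + d2$dy) / 2
      if (noise_sd > 0) {
        x <- x + noise_sd * stats::rnorm(n)
        y <- y + noise_sd * stats::rnorm(n)
      }
      if (!all(is.finite(x)) || max(abs(x)) > 1e6)
        stop(sprintf(
          "integration diverged at step %d (t = %.1f s); try a smaller dt_s",
          s, s * dt), call. = FALSE)
      if (s > transient_steps && (s - transient_steps) %% steps_per_tr == 0L) {
        kept <- kept + 1L
        out[, kept] <- x
      }
    }
  })
  id <- if (inherits(conn, "connectome")) "connectome" else "matrix"
  structure(list(series = regional_ts(out, p$tr_s, condition = "simulated"),
                 seed = as.integer(seed), params_snapshot = p,
                 connectome_id = id),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> seed %d: ", x$seed))
  print(x$series)
  invisible(x)
}

#' Estimate node intrinsic frequencies from data
#'
#' For each region, the peak of the subject-averaged power spectrum within
#' `band` (default 0.04-0.07 Hz, the narrowband range of slow hemodynamic
#' oscillations), returned as angular frequency `omega = 2*pi*f`. The search
#' is restricted to the band, so broadband input yields estimates clamped
#' inside it.
#'
#' @param dataset a [regional_ts] or list of them (same N and TR).
#' @param band frequency band in Hz, within Nyquist.
#' @return List with `omega` (rad/s), `f_hz`, and the frequency resolution
#'   `df_hz`.
#' @export
estimate_intrinsic_frequencies <- function(dataset, band = c(0.04, 0.07)) {
  if (inherits(dataset, "regional_ts")) dataset <- list(dataset)
  tr <- dataset[[1L]]$tr_s
  n <- nrow(dataset[[1L]]$values)
  if (band[1L] >= band[2L] || band[2L] > 1 / (2 * tr))
    stop("band must be increasing and within Nyquist", call. = FALSE)
  n_t <- min(vapply(dataset, function(d) ncol(d$values), 0L))
  freqs <- seq(0, floor(n_t / 2)) / (n_t * tr)
  in_band <- which(freqs >= band[1L] & freqs <= band[2L])
  if (length(in_band) == 0L)
    stop(sprintf(
      "band [%g, %g] Hz contains no frequency bin at resolution %g Hz",
      band[1L], band[2L], 1 / (n_t * tr)), call. = FALSE)
  pow <- matrix(0, n, length(freqs))
  for (d in dataset) {
    x <- d$values[, seq_len(n_t), drop = FALSE]
    x <- x - rowMeans(x)
    sp <- Mod(t(apply(x, 1L, stats::fft)))^2
    pow <- pow + sp[, seq_along(freqs), drop = FALSE]
  }
  f_hz <- freqs[in_band[apply(pow[, in_band, drop = FALSE], 1L, which.max)]]
  list(omega = 2 * pi * f_hz, f_hz = f_hz, df_hz = 1 / (n_t * tr))
}
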