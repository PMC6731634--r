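# Scoring simulated dynamics against empirical targets and fitting the
# model: static FC correlation, FCD/KS distance, symmetrized KL on substate
# probabilities, Markov entropy-rate distance, the G sweep, and the
# gradient-descent optimization of effective connectivity.

#' Static functional connectivity and its fit
#'
#' `static_fc` is the Pearson correlation matrix of the regional series;
#' `fc_fit` is the Pearson correlation between the strictly upper-triangular
#' entries of two such matrices - the standard scalar summary of how well a
#' simulated grand-average FC matches an empirical one.
#'
#' @param ts a [regional_ts].
#' @return `static_fc`: N x N correlation matrix.
#' @export
static_fc <- function(ts) {
  stopifnot(inherits(ts, "regional_ts"))
  sds <- apply(ts$values, 1L, stats::sd)
  if (any(sds == 0))
    stop(sprintf("region %d is constant; its correlations are undefined",
                 which(sds == 0)[1L]), call. = FALSE)
  stats::cor(t(ts$values))
}

#' @rdname static_fc
#' @param emp,sim same-size square matrices.
#' @return `fc_fit`: Pearson r over upper-triangular entries.
#' @export
fc_fit <- function(emp, sim) {
  if (!identical(dim(emp), dim(sim)))
    stop("FC matrices must have identical dimensions", call. = FALSE)
  stats::cor(upper_tri_vec(emp), upper_tri_vec(sim))
}

#' Grand-average phase-coherence matrix
#'
#' The time average of the instantaneous phase-coherence matrix:
#' `FC[i,j] = <cos(phi_j(t) - phi_i(t))>` over the valid samples. Symmetric
#' with unit diagonal. This is the matrix the effective-connectivity update
#' descends on.
#'
#' @param phases a `phase_repr`.
#' @return N x N matrix.
#' @export
grand_average_phase_fc <- function(phases) {
  stopifnot(inherits(phases, "phase_repr"))
  idx <- phases$valid_range
  if (length(idx) == 0L) stop("no valid samples", call. = FALSE)
  z <- exp(1i * phases$phases[, idx, drop = FALSE])
  fc <- Re(z %*% Conj(t(z))) / length(idx)
  diag(fc) <- 1
  fc
}

#' Functional connectivity dynamics (FCD) matrix and KS distance
#'
#' `fcd_matrix`: the T' x T' matrix of cosine similarities between the
#' upper-triangular parts of the phase-coherence matrices at every pair of
#' time points; blocks of high similarity mark epochs of stable
#' connectivity. `fcd_ks`: the two-sample Kolmogorov-Smirnov statistic
#' between the pooled upper-triangular FCD entries of two sets of sessions,
#' the scalar used to compare empirical and simulated dynamics.
#'
#' @param tensor a `coherence_tensor` with at least 2 time points.
#' @return `fcd_matrix`: symmetric matrix with unit diagonal.
#' @export
fcd_matrix <- function(tensor) {
  stopifnot(inherits(tensor, "coherence_tensor"))
  d <- dim(tensor$values)
  if (d[3L] < 2L) stop("need at least 2 time points", call. = FALSE)
  ut <- apply(tensor$values, 3L, upper_tri_vec)     # P x T'
  norms <- sqrt(colSums(ut^2))
  if (any(norms == 0))
    stop("a coherence slice has an all-zero upper triangle", call. = FALSE)
  ut <- sweep(ut, 2L, norms, "/")
  fcd <- crossprod(ut)
  diag(fcd) <- 1
  fcd
}

#' @rdname fcd_matrix
#' @param emp_tensors,sim_tensors lists of `coherence_tensor` objects.
#' @return `fcd_ks`: KS statistic in the unit interval.
#' @export
fcd_ks <- function(emp_tensors, sim_tensors) {
  pool <- function(tensors) {
    if (inherits(tensors, "coherence_tensor")) tensors <- list(tensors)
    unlist(lapply(tensors, function(t) upper_tri_vec(fcd_matrix(t))))
  }
  e <- pool(emp_tensors); s <- pool(sim_tensors)
  unname(suppressWarnings(stats::ks.test(e, s)$statistic))
}

#' Symmetrized Kullback-Leibler distance between substate probabilities
#'
#' `0.5 * (sum p ln(p/q) + sum q ln(q/p))` with natural logarithms.
#' Probabilities are floored at `floor` and renormalized first, so empty
#' substates cannot produce infinities. Non-negative, zero iff the clamped
#' distributions are equal, and symmetric in its arguments.
#'
#' @param p_emp,p_sim probability vectors of equal length.
#' @param floor lower clamp applied before the logs (default 1e-6).
#' @return Non-negative scalar.
#' @export
pms_kl <- function(p_emp, p_sim, floor = 1e-6) {
  if (length(p_emp) != length(p_sim))
    stop("probability vectors must have equal length", call. = FALSE)
  clamp <- function(p) { p <- pmax(p, floor); p / sum(p) }
  p <- clamp(p_emp); q <- clamp(p_sim)
  0.5 * (sum(p * log(p / q)) + sum(q * log(q / p)))
}

#' Stationary distribution of a Markov chain
#'
#' The probability vector `p` solving `t(P) p = p`: the eigenvector of the
#' transposed transition matrix for eigenvalue 1. Requires an irreducible
#' chain; unreachable states are reported by name. Falls back to power
#' iteration if the eigensolver residual exceeds `1e-8`.
#'
#' @param tpm row-stochastic k x k matrix.
#' @return Length-k probability vector.
#' @export
stationary_distribution <- function(tpm) {
  tpm <- as.matrix(tpm)
  k <- nrow(tpm)
  if (anyNA(tpm) || any(tpm < 0) || any(abs(rowSums(tpm) - 1) > 1e-9))
    stop("tpm rows must be probability vectors summing to 1", call. = FALSE)
  if (k == 1L) return(1)
  # irreducibility: all states mutually reachable through positive entries
  reach <- (tpm > 0) | diag(k)
  for (i in seq_len(ceiling(log2(k)) + 1L))
    reach <- (reach %*% reach) > 0
  if (!all(reach)) {
    bad <- which(!apply(reach, 2L, all))
    stop(sprintf("chain is reducible; state(s) %s unreachable from some state",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  e <- eigen(t(tpm))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  if (sum(v) < 0) v <- -v
  p <- v / sum(v)
  if (abs(Re(e$values[i]) - 1) > 1e-8 || any(p < -1e-10) ||
      max(abs(drop(t(tpm) %*% p) - p)) > 1e-8) {
    p <- rep(1 / k, k)
    for (it in seq_len(10000L)) {
      p_new <- drop(t(tpm) %*% p)
      if (max(abs(p_new - p)) < 1e-14) break
      p <- p_new
    }
  }
  pmax(p, 0) / sum(pmax(p, 0))
}

#' Markov entropy rate and entropy distance between transition matrices
#'
#' `markov_entropy_rate`: `S = -sum_i p(i) sum_j P(i,j) ln P(i,j)` with `p`
#' the stationary distribution and the convention `0 ln 0 = 0`. A chain that
#' switches a lot has high entropy rate; a chain that barely switches, low.
#' `entropy_distance` is the absolute difference of two entropy rates - the
#' scalar used to compare empirical and simulated switching matrices.
#'
#' @param tpm row-stochastic matrix of an irreducible chain.
#' @return `markov_entropy_rate`: non-negative scalar (nats).
#' @export
markov_entropy_rate <- function(tpm) {
  tpm <- as.matrix(tpm)
  p <- stationary_distribution(tpm)
  plogp <- ifelse(tpm > 0, tpm * log(tpm), 0)
  -sum(p * rowSums(plogp))
}

#' @rdname markov_entropy_rate
#' @param tpm_a,tpm_b two transition matrices.
#' @return `entropy_distance`: `|S_a - S_b|`.
#' @export
entropy_distance <- function(tpm_a, tpm_b) {
  abs(markov_entropy_rate(tpm_a) - markov_entropy_rate(tpm_b))
}

#' Score simulated runs against an empirical PMS model
#'
#' Runs the LEiDA chain on each simulated series, assigns the resulting
#' leading eigenvectors to the *empirical* centroids (so the probabilistic
#' measurements refer to the same substates), pools occupancy and switching
#' statistics over runs, and computes the symmetrized KL distance to the
#' empirical occupancies plus, when the empirical TPM is available and both
#' chains are irreducible, the Markov entropy distance. If reference
#' empirical series are supplied, the static-FC correlation and the FCD/KS
#' distance are computed as well.
#'
#' @param sim_results list of `simulation_result` (or [regional_ts]).
#' @param empirical_model a [pms_model] defining centroids, occupancies and
#'   (optionally) the TPM of the target state.
#' @param band,trim LEiDA settings, which must match those used for the
#'   empirical model.
#' @param emp_series optional list of empirical [regional_ts] for FC/FCD
#'   comparison.
#' @return Object of class `fit_result` with `kl_pms`, `ks_fcd`, `fc_corr`,
#'   `entropy_distance`, `sim_probabilities`, `sim_tpm`, `n_runs`, `seeds`.
#' @export
evaluate_model <- function(sim_results, empirical_model, band = c(0.02, 0.1),
                           trim = 3L, emp_series = NULL) {
  stopifnot(inherits(empirical_model, "pms_model"))
  if (!is.list(sim_results) || inherits(sim_results, "regional_ts"))
    sim_results <- list(sim_results)
  series <- lapply(sim_results, function(r)
    if (inherits(r, "simulation_result")) r$series else r)
  seeds <- vapply(sim_results, function(r)
    if (inherits(r, "simulation_result")) r$seed else NA_integer_, 0L)
  k <- empirical_model$k

  tensors <- lapply(series, function(ts)
    phase_coherence_tensor(compute_phases(bandpass_filter(ts, band[1L],
                                                          band[2L]), trim)))
  eigs <- lapply(tensors, leading_eigenvectors)
  labels <- lapply(eigs, assign_to_centroids,
                   centroids = empirical_model$centroids)
  p_sim <- occupancy_probabilities(labels, k)
  tpm_sim <- switching_matrix(labels, k)
  kl <- pms_kl(empirical_model$probabilities, p_sim)

  ent <- NA_real_
  if (!is.null(empirical_model$tpm) && !anyNA(tpm_sim) &&
      !anyNA(empirical_model$tpm)) {
    ent <- tryCatch(entropy_distance(empirical_model$tpm, tpm_sim),
                    error = function(e) NA_real_)
  }
  fc_r <- NA_real_; ks <- NA_real_
  if (!is.null(emp_series)) {
    if (inherits(emp_series, "regional_ts")) emp_series <- list(emp_series)
    fc_mean <- function(lst) Reduce(`+`, lapply(lst, static_fc)) / length(lst)
    fc_r <- fc_fit(fc_mean(emp_series), fc_mean(series))
    emp_tensors <- lapply(emp_series, function(ts)
      phase_coherence_tensor(compute_phases(bandpass_filter(ts, band[1L],
                                                            band[2L]), trim)))
    ks <- fcd_ks(emp_tensors, tensors)
  }
  structure(list(kl_pms = kl, ks_fcd = ks, fc_corr = fc_r,
                 entropy_distance = ent, sim_probabilities = p_sim,
                 sim_tpm = tpm_sim, n_runs = length(series), seeds = seeds),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> KL(PMS) = %.4g | KS(FCD) = %s | FC r = %s | dS = %s (%d runs)\n",
    x$kl_pms,
    ifelse(is.na(x$ks_fcd), "-", sprintf("%.3g", x$ks_fcd)),
    ifelse(is.na(x$fc_corr), "-", sprintf("%.3g", x$fc_corr)),
    ifelse(is.na(x$entropy_distance), "-", sprintf("%.3g", x$entropy_distance)),
    x$n_runs))
  invisible(x)
}

#' Sweep the global coupling G against an empirical PMS model
#'
#' Simulates the model at every value of `g_grid` (`n_runs` independent
#' runs each, averaged by pooling), scores each against the empirical PMS
#' model, and reports the optimum separately for the PMS criterion
#' (argmin of the symmetrized KL) and - when empirical series are supplied -
#' the FCD criterion (argmin of the KS distance); the two need not agree.
#'
#' @param conn connectome or coupling matrix.
#' @param params_template [hopf_params]; its `G` is overwritten per grid
#'   point.
#' @param g_grid ascending vector of coupling values.
#' @param empirical_model target [pms_model].
#' @param n_runs simulations per grid point (default 3).
#' @param duration_s duration of each simulated run.
#' @param seed integer seed; each (grid point, run) gets a derived seed.
#' @param band,trim,emp_series passed to [evaluate_model()].
#' @return List with `table` (data.frame of G and fit measures),
#'   `g_star_pms`, `g_star_fcd` (NA when FCD not computed), `fits`.
#' @export
sweep_coupling <- function(conn, params_template, g_grid, empirical_model,
                           n_runs = 3L, duration_s = 300, seed = 1L,
                           band = c(0.02, 0.1), trim = 3L, emp_series = NULL) {
  if (length(g_grid) == 0L || is.unsorted(g_grid))
    stop("g_grid must be non-empty and ascending", call. = FALSE)
  run_seeds <- matrix(spawn_seeds(seed, length(g_grid) * n_runs),
                      nrow = length(g_grid))
  fits <- vector("list", length(g_grid))
  for (i in seq_along(g_grid)) {
    params <- params_template
    params$G <- g_grid[i]
    sims <- lapply(seq_len(n_runs), function(r)
      simulate_hopf(conn, params, duration_s, seed = run_seeds[i, r]))
    fits[[i]] <- evaluate_model(sims, empirical_model, band, trim, emp_series)
  }
  tab <- data.frame(
    G = g_grid,
    kl_pms = vapply(fits, `[[`, 0, "kl_pms"),
    ks_fcd = vapply(fits, `[[`, 0, "ks_fcd"),
    fc_corr = vapply(fits, `[[`, 0, "fc_corr"),
    entropy_distance = vapply(fits, `[[`, 0, "entropy_distance"))
  g_fcd <- if (all(is.na(tab$ks_fcd))) NA_real_
           else g_grid[which.min(tab$ks_fcd)]
  list(table = tab, g_star_pms = g_grid[which.min(tab$kl_pms)],
       g_star_fcd = g_fcd, fits = fits)
}

#' Optimize effective connectivity by gradient descent on phase FC
#'
#' Starting from the structural connectome, repeatedly simulates the model,
#' computes its grand-average phase-coherence matrix, and updates every
#' off-diagonal connection by
#' `C[i,j] <- C[i,j] + epsilon * (FC_emp[i,j] - FC_mod[i,j])`,
#' clamped at zero and kept symmetric. The objective is the Frobenius
#' distance between the empirical and model phase-FC matrices, evaluated on
#' stochastic simulations, so it fluctuates around its descent path;
#' iteration stops when the best objective seen has not improved by more
#' than `tol` for `patience` consecutive iterations, or at `max_iter`. The
#' returned weights are the final iterate.
#'
#' @param conn connectome or coupling matrix (the initial EC).
#' @param params [hopf_params] (its `G` is used as-is).
#' @param empirical_phase_fc target N x N grand-average phase-coherence
#'   matrix.
#' @param epsilon learning rate (default 0.01).
#' @param max_iter maximum update iterations.
#' @param tol minimal objective improvement counted as progress.
#' @param patience consecutive no-progress iterations tolerated before
#'   stopping (default 10; the Monte-Carlo noise of the objective makes
#'   short patience trigger spuriously).
#' @param n_runs simulations averaged per iteration.
#' @param duration_s duration of each simulated run.
#' @param seed integer seed.
#' @param band,trim LEiDA settings for the model phase FC.
#' @return Object of class `ec_state`: `weights`, `iteration`,
#'   `fit_history` (data.frame iteration/objective), `epsilon`.
#' @export
optimize_ec <- function(conn, params, empirical_phase_fc, epsilon = 0.01,
                        max_iter = 100L, tol = 1e-3, n_runs = 1L,
                        duration_s = 300, seed = 1L, band = c(0.02, 0.1),
                        trim = 3L, patience = 10L) {
  C <- if (inherits(conn, "connectome")) conn$weights else as.matrix(conn)
  check_symmetric(empirical_phase_fc, tol = 1e-9, name = "empirical_phase_fc")
  stop_if_not_scalar(epsilon, "epsilon", positive = TRUE)
  n <- nrow(C)
  off <- row(C) != col(C)
  iter_seeds <- matrix(spawn_seeds(seed, max_iter * n_runs), nrow = max_iter)
  history <- numeric(0)
  best_obj <- Inf; stall <- 0L
  for (it in seq_len(max_iter)) {
    fc_runs <- lapply(seq_len(n_runs), function(r) {
      sim <- simulate_hopf(C, params, duration_s, seed = iter_seeds[it, r])
      grand_average_phase_fc(compute_phases(
        bandpass_filter(sim$series, band[1L], band[2L]), trim))
    })
    fc_mod <- Reduce(`+`, fc_runs) / n_runs
    resid <- empirical_phase_fc - fc_mod
    obj <- sqrt(sum(resid[off]^2))
    history <- c(history, obj)
    if (obj < best_obj - tol) {
      best_obj <- min(best_obj, obj); stall <- 0L
    } else {
      best_obj <- min(best_obj, obj)
      stall <- stall + 1L
    }
    # divergence = smoothed objective doubling from its smoothed minimum;
    # smoothing (5-iteration running mean) keeps single-run Monte-Carlo
    # spikes from triggering it
    if (it >= 10L) {
      sm <- stats::filter(history, rep(1 / 5, 5), sides = 1L)
      sm <- sm[!is.na(sm)]
      if (sm[length(sm)] > 2 * min(sm))
        stop(sprintf(
          "EC objective diverged (smoothed %.3g vs best %.3g); try a smaller epsilon",
          sm[length(sm)], min(sm)), call. = FALSE)
    }
    if (stall >= patience) break
    C[off] <- pmax(C[off] + epsilon * resid[off], 0)
    C <- (C + t(C)) / 2
    diag(C) <- 0
  }
  structure(list(weights = C, iteration = length(history),
                 fit_history = data.frame(iteration = seq_along(history),
                                          objective = history),
                 epsilon = epsilon),
            class = "ec_state")
}

#' @export
print.ec_state <- function(x, ...) {
  cat(sprintf("<ec_state> %d iterations, objective %.4g -> %.4g (eps = %g)\n",
              x$iteration, x$fit_history$objective[1L],
              min(x$fit_history$objective), x$epsilon))
  invisible(x)
}
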