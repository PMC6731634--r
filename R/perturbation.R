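# In-silico stimulation: shift the local bifurcation parameter of homotopic
# region pairs of a fitted source model, score the perturbed dynamics
# against a target PMS model, and search sites/intensities that force a
# state transition.

#' Specify a bilateral stimulation protocol
#'
#' A stimulation is a shift `delta_a` of the local bifurcation parameter of
#' every region in the selected homotopic pairs. The synchronization
#' protocol uses positive shifts (forcing local oscillation and promoting
#' whole-brain synchrony); the noise protocol uses negative shifts (pushing
#' regions to a noisy fixed point).
#'
#' @param protocol `"synchronization"` or `"noise"`.
#' @param pairs integer indices into the connectome's homotopic-pair table.
#' @param delta_a bifurcation-parameter shift; its sign must match the
#'   protocol (>= 0 for synchronization, <= 0 for noise).
#' @return Object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(protocol = c("synchronization", "noise"),
                              pairs, delta_a) {
  protocol <- match.arg(protocol)
  if (length(pairs) == 0L) stop("select at least one pair", call. = FALSE)
  stop_if_not_scalar(delta_a, "delta_a")
  if (protocol == "synchronization" && delta_a < 0)
    stop("synchronization protocol requires delta_a >= 0", call. = FALSE)
  if (protocol == "noise" && delta_a > 0)
    stop("noise protocol requires delta_a <= 0", call. = FALSE)
  structure(list(protocol = protocol, pairs = as.integer(pairs),
                 delta_a = delta_a),
            class = "perturbation_spec")
}

#' Apply a bilateral perturbation to model parameters
#'
#' Adds `delta_a` to the bifurcation parameter of both members of each
#' selected homotopic pair; every other node is untouched. The perturbation
#' is tonic: it holds for the whole simulation.
#'
#' @param params a [hopf_params].
#' @param spec a [perturbation_spec].
#' @param pair_table integer matrix of homotopic pairs (two columns), e.g.
#'   `connectome$homotopic_pairs`.
#' @return A modified [hopf_params].
#' @export
apply_perturbation <- function(params, spec, pair_table) {
  stopifnot(inherits(spec, "perturbation_spec"))
  pair_table <- matrix(as.integer(pair_table), ncol = 2L)
  if (any(spec$pairs < 1L) || any(spec$pairs > nrow(pair_table)))
    stop(sprintf("pair index out of range 1..%d", nrow(pair_table)),
         call. = FALSE)
  n <- 2L * nrow(pair_table)
  p <- expand_params(params, n)
  nodes <- as.vector(pair_table[spec$pairs, , drop = FALSE])
  p$a[nodes] <- p$a[nodes] + spec$delta_a
  p
}

# Shared evaluation: simulate the (possibly perturbed) system over fixed
# run seeds and score against a PMS model. Fixed seeds mean every candidate
# perturbation is compared on common noise.
eval_perturbed <- function(conn, params, target_model, duration_s, run_seeds,
                           band, trim) {
  sims <- lapply(run_seeds, function(s)
    simulate_hopf(conn, params, duration_s, seed = s))
  evaluate_model(sims, target_model, band, trim)
}

#' Exhaustive single-site stimulation scan
#'
#' For every homotopic pair and every intensity in `intensity_grid`, applies
#' the perturbation to the source system, simulates it, and records the
#' symmetrized KL distance between the perturbed model's substate
#' probabilities and the target PMS model. Low KL marks site/intensity
#' combinations that push the source state toward the target state. The
#' unperturbed baseline is evaluated with the same run seeds and budget, so
#' comparisons are like-for-like.
#'
#' @param conn source-system [connectome] (its homotopic-pair table defines
#'   the stimulation sites) with weights from the fitted SC or EC.
#' @param params source-system [hopf_params] (fitted working point).
#' @param target_model target-state [pms_model].
#' @param protocol `"synchronization"` or `"noise"`.
#' @param intensity_grid vector of `delta_a` values, sign-compatible with
#'   the protocol. Defaults: 0 to 0.2 by 0.02 (synchronization), 0 to -0.6
#'   by -0.05 (noise).
#' @param n_runs simulations per cell.
#' @param duration_s duration of each run.
#' @param seed integer seed.
#' @param band,trim LEiDA settings matching the target model.
#' @return Object of class `transition_map`: `kl_values` (pairs x
#'   intensities), `intensity_grid`, `baseline_kl`, `protocol`,
#'   `pair_table`.
#' @export
transition_scan <- function(conn, params, target_model,
                            protocol = c("synchronization", "noise"),
                            intensity_grid = NULL, n_runs = 3L,
                            duration_s = 300, seed = 1L,
                            band = c(0.02, 0.1), trim = 3L) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(conn, "connectome"))
  if (is.null(conn$homotopic_pairs))
    stop("connectome has no homotopic-pair table; bilateral stimulation needs one",
         call. = FALSE)
  if (is.null(intensity_grid))
    intensity_grid <- if (protocol == "synchronization") seq(0, 0.2, 0.02)
                      else seq(0, -0.6, -0.05)
  ok_sign <- if (protocol == "synchronization") all(intensity_grid >= 0)
             else all(intensity_grid <= 0)
  if (!ok_sign)
    stop(sprintf("intensity grid sign incompatible with %s protocol", protocol),
         call. = FALSE)
  pair_table <- conn$homotopic_pairs
  n_pairs <- nrow(pair_table)
  run_seeds <- spawn_seeds(seed, n_runs)
  baseline <- eval_perturbed(conn, params, target_model, duration_s,
                             run_seeds, band, trim)
  kl <- matrix(NA_real_, n_pairs, length(intensity_grid),
               dimnames = list(pair = NULL, delta_a = intensity_grid))
  for (p in seq_len(n_pairs)) {
    for (m in seq_along(intensity_grid)) {
      if (intensity_grid[m] == 0) { kl[p, m] <- baseline$kl_pms; next }
      spec <- perturbation_spec(protocol, p, intensity_grid[m])
      pp <- apply_perturbation(params, spec, pair_table)
      kl[p, m] <- eval_perturbed(conn, pp, target_model, duration_s,
                                 run_seeds, band, trim)$kl_pms
    }
  }
  structure(list(kl_values = kl, intensity_grid = intensity_grid,
                 baseline_kl = baseline$kl_pms, protocol = protocol,
                 pair_table = pair_table),
            class = "transition_map")
}

#' @export
print.transition_map <- function(x, ...) {
  best <- arrayInd(which.min(x$kl_values), dim(x$kl_values))
  cat(sprintf(
    "<transition_map> %s protocol, %d pairs x %d intensities; baseline KL %.4g, best KL %.4g (pair %d, delta_a %g)\n",
    x$protocol, nrow(x$kl_values), ncol(x$kl_values), x$baseline_kl,
    min(x$kl_values), best[1L], x$intensity_grid[best[2L]]))
  invisible(x)
}

#' Greedy multisite stimulation search
#'
#' Builds a set of stimulated homotopic pairs one at a time: at each step,
#' every not-yet-chosen pair is tried in addition to the current set (all at
#' the same, typically weak, `delta_a`), and the pair giving the lowest KL
#' distance to the target PMS model is kept stimulated. The trace records,
#' for step 0 (unperturbed) through `max_steps`, the KL to the target, the
#' KL to the source model, and the substate probabilities; the target-KL
#' curve typically falls to a minimum at the optimal number of sites and
#' rises again as further stimulation overshoots the target state, while
#' the source-KL rises monotonically. Candidates within a step share run
#' seeds, so they are compared on common noise; ties go to the lowest pair
#' index.
#'
#' @inheritParams transition_scan
#' @param source_model source-state [pms_model] (for the source-KL curve).
#' @param delta_a per-site intensity (sign selects the protocol).
#' @param max_steps number of pairs to add (<= number of pairs).
#' @return Object of class `greedy_trace`: `chosen_pairs`, `kl_to_target`,
#'   `kl_to_source`, `substate_probabilities` (rows = steps), `best_step`
#'   (step index minimizing target KL; 0 = unperturbed).
#' @export
greedy_multisite <- function(conn, params, target_model, source_model,
                             delta_a, max_steps, n_runs = 3L,
                             duration_s = 300, seed = 1L,
                             band = c(0.02, 0.1), trim = 3L) {
  stopifnot(inherits(conn, "connectome"))
  if (is.null(conn$homotopic_pairs))
    stop("connectome has no homotopic-pair table", call. = FALSE)
  pair_table <- conn$homotopic_pairs
  n_pairs <- nrow(pair_table)
  if (max_steps > n_pairs)
    stop("max_steps cannot exceed the number of homotopic pairs", call. = FALSE)
  protocol <- if (delta_a >= 0) "synchronization" else "noise"
  step_seeds <- matrix(spawn_seeds(seed, (max_steps + 1L) * n_runs),
                       nrow = max_steps + 1L)
  score <- function(pairs, run_seeds) {
    p <- if (length(pairs) == 0L) expand_params(params, 2L * n_pairs)
         else apply_perturbation(params,
                                 perturbation_spec(protocol, pairs, delta_a),
                                 pair_table)
    fit <- eval_perturbed(conn, p, target_model, duration_s, run_seeds,
                          band, trim)
    list(target = fit$kl_pms,
         source = pms_kl(source_model$probabilities, fit$sim_probabilities),
         probs = fit$sim_probabilities)
  }
  base <- score(integer(0), step_seeds[1L, ])
  chosen <- integer(0)
  kl_t <- base$target; kl_s <- base$source
  probs <- matrix(base$probs, nrow = 1L)
  for (s in seq_len(max_steps)) {
    candidates <- setdiff(seq_len(n_pairs), chosen)
    scores <- lapply(candidates, function(cand)
      score(c(chosen, cand), step_seeds[s + 1L, ]))
    kl_cand <- vapply(scores, `[[`, 0, "target")
    best <- which.min(kl_cand)          # which.min takes the first == lowest index on ties
    chosen <- c(chosen, candidates[best])
    kl_t <- c(kl_t, kl_cand[best])
    kl_s <- c(kl_s, scores[[best]]$source)
    probs <- rbind(probs, scores[[best]]$probs)
  }
  structure(list(chosen_pairs = chosen, kl_to_target = kl_t,
                 kl_to_source = kl_s, substate_probabilities = probs,
                 best_step = which.min(kl_t) - 1L, delta_a = delta_a,
                 protocol = protocol),
            class = "greedy_trace")
}

#' @export
print.greedy_trace <- function(x, ...) {
  cat(sprintf(
    "<greedy_trace> %s protocol at delta_a = %g: pairs [%s]; target KL %s; best at step %d\n",
    x$protocol, x$delta_a, paste(x$chosen_pairs, collapse = ", "),
    paste(sprintf("%.3g", x$kl_to_target), collapse = " -> "), x$best_step))
  invisible(x)
}
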