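#' Generate a synthetic modular connectome with homotopic pairs
#'
#' Builds a symmetric, non-negative, zero-diagonal weight matrix with a
#' modular block structure and explicit homotopic (left/right counterpart)
#' edges, then rescales it so the mean off-diagonal weight equals
#' `mean_weight`. Regions `1..N/2` are the "left" hemisphere and region
#' `i` is paired with region `i + N/2`; homotopic pairs always share a
#' module, as bilateral networks do.
#'
#' @param n_regions even number of regions, >= 4.
#' @param n_modules number of modules (>= 1); within-module connections are
#'   drawn stronger than between-module ones.
#' @param homotopic_strength extra weight (before normalization) added to
#'   each left/right pair edge; 0 disables.
#' @param seed integer seed; all randomness in the call derives from it.
#' @param mean_weight target mean of off-diagonal entries after
#'   normalization. Default 0.2, the scale at which the coupled-oscillator
#'   model is operated.
#' @return A [connectome] with `n_regions/2` homotopic pairs.
#' @export
generate_connectome <- function(n_regions, n_modules = 2L,
                                homotopic_strength = 1, seed = 1L,
                                mean_weight = 0.2) {
  stop_if_not_scalar(n_regions, "n_regions")
  if (n_regions < 4L) stop("need at least 4 regions", call. = FALSE)
  if (n_regions %% 2L != 0L)
    stop(paste("`n_regions` must be even: every region needs a homotopic",
               "(bilateral) partner for pair-wise stimulation"), call. = FALSE)
  if (n_modules < 1L) stop("`n_modules` must be >= 1", call. = FALSE)
  if (homotopic_strength < 0) stop("`homotopic_strength` must be >= 0",
                                   call. = FALSE)
  n <- as.integer(n_regions)
  n_pairs <- n %/% 2L
  pairs <- cbind(left = seq_len(n_pairs), right = seq_len(n_pairs) + n_pairs)
  # assign whole pairs to modules so homotopic partners share a module
  pair_module <- rep_len(seq_len(n_modules), n_pairs)
  module <- integer(n)
  module[pairs[, 1L]] <- pair_module
  module[pairs[, 2L]] <- pair_module

  w <- with_seed(seed, {
    base <- matrix(abs(stats::rnorm(n * n)), n, n)
    same <- outer(module, module, "==")
    # weak between-module background: network-wide synchronization then
    # builds gradually over the usual explored coupling range instead of
    # saturating at small G
    w <- base * ifelse(same, 1, 0.05)
    w <- (w + t(w)) / 2
    w[cbind(pairs[, 1L], pairs[, 2L])] <-
      w[cbind(pairs[, 1L], pairs[, 2L])] + homotopic_strength
    w[cbind(pairs[, 2L], pairs[, 1L])] <- w[cbind(pairs[, 1L], pairs[, 2L])]
    diag(w) <- 0
    w
  })
  off <- row(w) != col(w)
  w <- w * (mean_weight / mean(w[off]))
  names <- sprintf("%s%02d", rep(c("L", "R"), each = n_pairs),
                   rep(seq_len(n_pairs), 2L))
  connectome(w, region_names = names, homotopic_pairs = pairs)
}

#' Generate a multi-subject dataset from the whole-brain Hopf model
#'
#' Simulates `n_subjects` independent sessions of the coupled
#' Stuart-Landau system on the given connectome, each with its own noise
#' stream derived from `seed`. The generating parameters are returned as a
#' ground-truth record so parameter-recovery experiments never have to
#' re-derive them.
#'
#' @param conn a [connectome] (or plain coupling matrix).
#' @param params a [hopf_params] record; `tr_s` is taken from the `tr_s`
#'   argument here.
#' @param n_subjects number of independent sessions.
#' @param duration_s simulated duration per subject in seconds (including
#'   the transient that will be discarded).
#' @param tr_s output sampling period in seconds.
#' @param seed integer seed.
#' @param condition label attached to every generated series.
#' @return A list with `series` (list of [regional_ts]) and `ground_truth`
#'   (generating `G`, `a`, `omega`, `beta`, `seed`, per-subject seeds).
#' @export
generate_state_dataset <- function(conn, params, n_subjects, duration_s,
                                   tr_s = 2, seed = 1L, condition = "synthetic") {
  stop_if_not_scalar(duration_s, "duration_s", positive = TRUE)
  stop_if_not_scalar(n_subjects, "n_subjects", positive = TRUE)
  params$tr_s <- tr_s
  n_keep <- floor((duration_s - params$transient_s) / tr_s)
  if (n_keep < 50)
    stop(sprintf(
      "duration leaves only %d samples after the %gs transient; need >= 50",
      n_keep, params$transient_s), call. = FALSE)
  subject_seeds <- spawn_seeds(seed, n_subjects)
  series <- lapply(seq_len(n_subjects), function(i) {
    sim <- simulate_hopf(conn, params, duration_s, seed = subject_seeds[i])
    ts <- sim$series
    ts$subject_id <- sprintf("sub%02d", i)
    ts$condition <- condition
    ts
  })
  n <- nrow(series[[1L]]$values)
  p <- expand_params(params, n)
  list(series = series,
       ground_truth = list(G = p$G, a = p$a, omega = p$omega, beta = p$beta,
                           seed = seed, subject_seeds = subject_seeds,
                           duration_s = duration_s, tr_s = tr_s))
}

#' Generate labeled unit-vector clusters for testing eigenvector clustering
#'
#' Draws `n_samples` unit-norm vectors around `k` mutually orthogonal
#' directions, with isotropic Gaussian scatter of unit variance added to
#' each direction scaled by `separation` before renormalization. Large
#' `separation` gives tight, well-separated clusters; `separation = 0`
#' gives uniformly random directions.
#'
#' @param k number of clusters.
#' @param n_regions vector dimension (>= k).
#' @param n_samples total number of vectors, spread evenly over clusters.
#' @param separation signal-to-scatter ratio (>= 0).
#' @param seed integer seed.
#' @return List with `vectors` (`n_samples` x `n_regions`, unit rows),
#'   `labels` (integers in `1..k`) and `centers` (k x `n_regions`).
#' @export
generate_eigenvector_clusters <- function(k, n_regions, n_samples,
                                          separation = 10, seed = 1L) {
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (n_regions < k)
    stop("`n_regions` must be >= k for orthogonal cluster directions",
         call. = FALSE)
  if (separation < 0) stop("`separation` must be >= 0", call. = FALSE)
  with_seed(seed, {
    centers <- qr.Q(qr(matrix(stats::rnorm(n_regions * k), n_regions, k)))
    centers <- t(centers)                       # k x N, orthonormal rows
    labels <- rep_len(seq_len(k), n_samples)
    v <- centers[labels, , drop = FALSE] * separation +
      matrix(stats::rnorm(n_samples * n_regions), n_samples, n_regions)
    v <- v / sqrt(rowSums(v^2))
    list(vectors = v, labels = labels, centers = centers)
  })
}

#' Pair-tagged intrinsic frequency layout
#'
#' Assigns one intrinsic frequency per homotopic pair (both members share
#' it), for planted-perturbation experiments: the `tagged` pairs all receive
#' the common frequency `f_tagged` in the middle of the band, while the
#' remaining pairs are spread over the low and high edges of `f_range`,
#' well away from `f_tagged`. Oscillation evoked at a tagged site is then
#' mutually coherent with the other tagged sites and distinguishable from
#' oscillation evoked anywhere else, so a probabilistic-substate analysis
#' can identify which sites were stimulated.
#'
#' @param n_pairs number of homotopic pairs.
#' @param tagged indices of pairs sharing `f_tagged` (may be empty).
#' @param f_tagged common frequency of tagged pairs, Hz.
#' @param f_range band edges for the untagged background pairs, Hz.
#' @return List with `pair_f` (length `n_pairs`, Hz) and `omega` (length
#'   `2 * n_pairs`, rad/s, node order: all left members then all right).
#' @export
generate_pair_frequencies <- function(n_pairs, tagged = integer(0),
                                      f_tagged = 0.055,
                                      f_range = c(0.036, 0.07)) {
  tagged <- as.integer(tagged)
  if (any(tagged < 1L) || any(tagged > n_pairs))
    stop("tagged pair index out of range", call. = FALSE)
  pair_f <- numeric(n_pairs)
  pair_f[tagged] <- f_tagged
  n_bg <- n_pairs - length(tagged)
  if (n_bg > 0L) {
    n_low <- ceiling(0.6 * n_bg)
    low <- seq(0.042, by = -0.002, length.out = n_low)
    high <- seq(0.068, by = 0.002, length.out = n_bg - n_low)
    bg <- pmin(pmax(c(low, high), f_range[1L]), f_range[2L])
    pair_f[setdiff(seq_len(n_pairs), tagged)] <- sort(bg)
  }
  list(pair_f = pair_f, omega = 2 * pi * pair_f[c(seq_len(n_pairs),
                                                  seq_len(n_pairs))])
}

#' Sample a label sequence from a Markov chain
#'
#' Starts from the stationary distribution of the transition probability
#' matrix and samples `length` steps. Used as an exactly-known fixture for
#' occupancy, switching-matrix and entropy-rate checks.
#'
#' @param tpm row-stochastic k x k matrix.
#' @param length sequence length.
#' @param seed integer seed.
#' @return Integer vector of labels in `1..k`.
#' @export
generate_markov_labels <- function(tpm, length, seed = 1L) {
  tpm <- as.matrix(tpm)
  if (!is_square(tpm)) stop("`tpm` must be square", call. = FALSE)
  if (any(tpm < 0) || any(abs(rowSums(tpm) - 1) > 1e-9))
    stop("`tpm` rows must be probability vectors summing to 1", call. = FALSE)
  stop_if_not_scalar(length, "length", positive = TRUE)
  k <- nrow(tpm)
  # reducible chains (e.g. the identity) have no unique stationary
  # distribution; start uniformly in that case
  p0 <- tryCatch(stationary_distribution(tpm),
                 error = function(e) rep(1 / k, k))
  with_seed(seed, {
    out <- integer(length)
    out[1L] <- sample.int(k, 1L, prob = p0)
    if (length > 1L)
      for (t in 2L:length)
        out[t] <- sample.int(k, 1L, prob = tpm[out[t - 1L], ])
    out
  })
}
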