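# Leading eigenvector dynamics analysis (LEiDA): regional signals ->
# Hilbert phases -> instantaneous phase-coherence matrices -> leading
# eigenvectors -> k-means substates -> occupancy / switching statistics.

#' Zero-phase band-pass filter of regional time series
#'
#' Removes the per-region mean, then applies a second-order Butterworth
#' band-pass forward and backward (zero phase distortion). The default band
#' 0.02-0.1 Hz isolates slow hemodynamic fluctuations before phase
#' extraction.
#'
#' @param ts a [regional_ts].
#' @param f_low,f_high band edges in Hz; must satisfy
#'   `0 < f_low < f_high < 1/(2*tr_s)`.
#' @param order Butterworth order (default 2).
#' @return A filtered [regional_ts].
#' @export
bandpass_filter <- function(ts, f_low = 0.02, f_high = 0.1, order = 2L) {
  stopifnot(inherits(ts, "regional_ts"))
  nyq <- 1 / (2 * ts$tr_s)
  if (!(f_low > 0 && f_low < f_high))
    stop("need 0 < f_low < f_high", call. = FALSE)
  if (f_high >= nyq)
    stop(sprintf(
      "f_high = %g Hz is at or above Nyquist; with TR = %g s the achievable band is (0, %g) Hz",
      f_high, ts$tr_s, nyq), call. = FALSE)
  bf <- signal::butter(order, c(f_low, f_high) / nyq, type = "pass")
  x <- ts$values - rowMeans(ts$values)
  filt <- t(apply(x, 1L, function(row) signal::filtfilt(bf, row)))
  out <- ts
  out$values <- filt
  out
}

# Analytic signal of a real vector via the frequency-domain construction:
# null negative frequencies, double positive ones.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase and amplitude via the Hilbert transform
#'
#' Computes the analytic signal of each (already filtered) regional series
#' and returns its phase and amplitude. The first and last `trim` samples
#' are excluded from `valid_range` because the transform is unreliable at
#' the series edges.
#'
#' @param ts a filtered [regional_ts].
#' @param trim samples to drop at each end (default 3).
#' @return An object of class `phase_repr`: `phases` and `amplitudes`
#'   (N x T), `valid_range` (indices), `tr_s`, and the input labels.
#' @export
compute_phases <- function(ts, trim = 3L) {
  stopifnot(inherits(ts, "regional_ts"))
  n_t <- ncol(ts$values)
  if (n_t <= 2L * trim)
    stop(sprintf("T = %d leaves no valid samples after trimming %d per end",
                 n_t, trim), call. = FALSE)
  z <- t(apply(ts$values, 1L, analytic_signal))
  structure(list(phases = Arg(z), amplitudes = Mod(z),
                 valid_range = (trim + 1L):(n_t - trim), tr_s = ts$tr_s,
                 subject_id = ts$subject_id, condition = ts$condition),
            class = "phase_repr")
}

#' Phase-coherence tensor dFC(n, p, t)
#'
#' For every valid time point, the N x N matrix of cosines of pairwise phase
#' differences: 1 for regions oscillating in phase, 0 at 90 degrees, -1 in
#' anti-phase. Each slice is symmetric with unit diagonal.
#'
#' @param phases a `phase_repr` from [compute_phases()].
#' @return Object of class `coherence_tensor`: `values` (N x N x T' array)
#'   and `t_index` (original sample indices of the slices).
#' @export
phase_coherence_tensor <- function(phases) {
  stopifnot(inherits(phases, "phase_repr"))
  idx <- phases$valid_range
  if (length(idx) == 0L) stop("no valid samples", call. = FALSE)
  th <- phases$phases[, idx, drop = FALSE]
  n <- nrow(th)
  vals <- vapply(seq_along(idx), function(t) {
    d <- outer(th[, t], th[, t], "-")
    cos(d)
  }, matrix(0, n, n))
  structure(list(values = vals, t_index = idx, tr_s = phases$tr_s,
                 subject_id = phases$subject_id, condition = phases$condition),
            class = "coherence_tensor")
}

# Sign convention for leading eigenvectors: flip so most elements are
# negative; on a tie, flip so the largest-magnitude element is negative.
# A fixed convention is required because eigenvectors are defined up to sign
# and clustering must see a consistent orientation.
orient_eigenvector <- function(v) {
  n_pos <- sum(v > 0)
  n_neg <- sum(v < 0)
  flip <- if (n_pos != n_neg) n_pos > n_neg else v[which.max(abs(v))] > 0
  if (flip) -v else v
}

#' Leading eigenvector of each phase-coherence slice
#'
#' Reduces each N x N coherence matrix to the unit eigenvector of its
#' largest-magnitude eigenvalue - the dominant instantaneous connectivity
#' pattern, whose outer product is the best rank-1 approximation of the
#' slice. Vectors are sign-normalized so that the majority of elements are
#' negative.
#'
#' @param tensor a `coherence_tensor`.
#' @param sym_tol maximum allowed asymmetry of a slice.
#' @return Object of class `eigenvector_series`: `vectors` (T' x N, unit
#'   rows), `sign_convention`, `t_index`.
#' @export
leading_eigenvectors <- function(tensor, sym_tol = 1e-8) {
  stopifnot(inherits(tensor, "coherence_tensor"))
  dims <- dim(tensor$values)
  vecs <- t(vapply(seq_len(dims[3L]), function(t) {
    s <- tensor$values[, , t]
    check_symmetric(s, tol = sym_tol, name = sprintf("slice %d", t))
    e <- eigen(s, symmetric = TRUE)
    i <- which.max(abs(e$values))
    orient_eigenvector(e$vectors[, i])
  }, numeric(dims[1L])))
  structure(list(vectors = vecs, sign_convention = "majority_negative",
                 t_index = tensor$t_index, subject_id = tensor$subject_id,
                 condition = tensor$condition),
            class = "eigenvector_series")
}

# Pool one or more eigenvector_series (or bare matrices) into one matrix,
# remembering per-series lengths so transition counting can respect
# session boundaries.
pool_eigenvectors <- function(eigs) {
  if (inherits(eigs, "eigenvector_series")) eigs <- list(eigs)
  if (is.matrix(eigs)) return(list(x = eigs, sizes = nrow(eigs)))
  mats <- lapply(eigs, function(e)
    if (inherits(e, "eigenvector_series")) e$vectors else as.matrix(e))
  list(x = do.call(rbind, mats), sizes = vapply(mats, nrow, 0L))
}

relist_labels <- function(labels, sizes) {
  split(labels, rep(seq_along(sizes), sizes))
}

#' Cluster leading eigenvectors into metastable substates
#'
#' Pools the eigenvectors of all provided series (all subjects and
#' conditions) and runs k-means with Euclidean distance, keeping the best of
#' `n_restarts` random starts. The result is returned both as raw clustering
#' output (centroids, per-series labels, within-cluster sum of squares) and
#' as a [pms_model] whose occupancy and switching matrix are computed from
#' the labels with session boundaries respected.
#'
#' @param eigs an `eigenvector_series`, a list of them, or a samples x N
#'   matrix.
#' @param k number of substates.
#' @param n_restarts k-means restarts (default 20).
#' @param seed integer seed.
#' @return Object of class `pms_clustering`: `centroids` (k x N), `labels`
#'   (list of integer vectors, one per input series), `wcss`, `k`, `model`
#'   (a [pms_model]).
#' @export
cluster_states <- function(eigs, k, n_restarts = 20L, seed = 1L) {
  pooled <- pool_eigenvectors(eigs)
  x <- pooled$x
  if (k > nrow(x))
    stop(sprintf("k = %d exceeds the %d pooled samples", k, nrow(x)),
         call. = FALSE)
  km <- with_seed(seed, stats::kmeans(x, centers = k, nstart = n_restarts,
                                      iter.max = 100L))
  # relabel clusters by decreasing size so labels are stable across reruns
  ord <- order(tabulate(km$cluster, k), decreasing = TRUE)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- relabel[km$cluster]
  centroids <- km$centers[ord, , drop = FALSE]
  labels_by_series <- relist_labels(labels, pooled$sizes)
  model <- pms_model(centroids,
                     occupancy_probabilities(labels_by_series, k),
                     switching_matrix(labels_by_series, k))
  structure(list(centroids = centroids, labels = labels_by_series,
                 wcss = km$tot.withinss, k = k, model = model),
            class = "pms_clustering")
}

#' Silhouette-based selection of the number of substates
#'
#' Clusters the pooled eigenvectors for each `k` in `k_range` and reports
#' the mean silhouette width; the recommended `k` is the argmax.
#'
#' @inheritParams cluster_states
#' @param k_range integer vector of candidate cluster counts (each >= 2).
#' @return A data.frame with columns `k` and `silhouette`; the recommended
#'   `k` in attribute `"best_k"`.
#' @export
select_k <- function(eigs, k_range = 2:8, n_restarts = 20L, seed = 1L) {
  pooled <- pool_eigenvectors(eigs)
  if (any(k_range < 2L) || any(k_range > nrow(pooled$x) - 1L))
    stop("k_range must lie within [2, samples - 1]", call. = FALSE)
  d <- stats::dist(pooled$x)
  seeds <- spawn_seeds(seed, length(k_range))
  sil <- vapply(seq_along(k_range), function(i) {
    cl <- cluster_states(pooled$x, k_range[i], n_restarts, seeds[i])
    mean(cluster::silhouette(unlist(cl$labels), d)[, "sil_width"])
  }, 0)
  out <- data.frame(k = as.integer(k_range), silhouette = sil)
  attr(out, "best_k") <- out$k[which.max(out$silhouette)]
  out
}

#' Fractional occupancy of each substate
#'
#' The fraction of time points assigned to each substate, pooled over all
#' provided label sequences. Sums to exactly 1.
#'
#' @param labels integer vector or list of integer vectors with values in
#'   `1..k`.
#' @param k number of substates.
#' @return Numeric length-k probability vector.
#' @export
occupancy_probabilities <- function(labels, k) {
  lab <- unlist(labels, use.names = FALSE)
  if (length(lab) == 0L) stop("no labels provided", call. = FALSE)
  if (any(lab < 1L) || any(lab > k))
    stop("labels must lie in 1..k", call. = FALSE)
  tabulate(lab, k) / length(lab)
}

#' Substate switching (transition probability) matrix
#'
#' Row-normalized counts of consecutive label pairs. When `labels` is a
#' list, transitions are counted within each sequence only - concatenation
#' boundaries between subjects or sessions contribute no transition. Rows
#' of substates that are never visited are returned as `NA` and listed in
#' the `"unvisited"` attribute rather than silently uniform.
#'
#' @inheritParams occupancy_probabilities
#' @return k x k matrix, rows = current substate, columns = next substate.
#' @export
switching_matrix <- function(labels, k) {
  if (!is.list(labels)) labels <- list(labels)
  if (sum(lengths(labels)) < 2L)
    stop("need at least 2 labels to count a transition", call. = FALSE)
  counts <- matrix(0, k, k)
  for (seq_i in labels) {
    if (any(seq_i < 1L) || any(seq_i > k))
      stop("labels must lie in 1..k", call. = FALSE)
    if (length(seq_i) >= 2L) {
      from <- seq_i[-length(seq_i)]
      to <- seq_i[-1L]
      for (t in seq_along(from))
        counts[from[t], to[t]] <- counts[from[t], to[t]] + 1
    }
  }
  visits <- rowSums(counts)
  tpm <- counts / ifelse(visits > 0, visits, NA_real_)
  attr(tpm, "unvisited") <- which(visits == 0)
  tpm
}

#' Assign eigenvectors to fixed substate centroids
#'
#' Nearest-centroid assignment under Euclidean distance - the distance used
#' by the clustering - so that simulated data can be scored against the
#' substates extracted from empirical data. Exact ties go to the lowest
#' centroid index.
#'
#' @param eigs an `eigenvector_series`, list of them, or samples x N matrix.
#' @param centroids k x N centroid matrix (e.g. `pms_model$centroids`).
#' @return Integer label vector, or list of vectors when `eigs` is a list.
#' @export
assign_to_centroids <- function(eigs, centroids) {
  pooled <- pool_eigenvectors(eigs)
  centroids <- as.matrix(centroids)
  if (ncol(pooled$x) != ncol(centroids))
    stop(sprintf("eigenvectors have %d regions but centroids have %d",
                 ncol(pooled$x), ncol(centroids)), call. = FALSE)
  # squared distances ||x||^2 - 2 x.c + ||c||^2; ||x||^2 constant per row
  cross <- pooled$x %*% t(centroids)
  d2 <- sweep(-2 * cross, 2L, rowSums(centroids^2), "+")
  labels <- max.col(-d2, ties.method = "first")
  if (length(pooled$sizes) == 1L) labels
  else relist_labels(labels, pooled$sizes)
}

#' Permutation-based paired t test
#'
#' Two-sided paired test of per-subject values between conditions. The
#' statistic is the paired t statistic of the within-subject differences;
#' the null distribution is built by independently flipping the sign of
#' each pair's difference (the permutation of condition labels within a
#' pair), `n_perm` times.
#'
#' @param a,b equal-length numeric vectors, paired by subject.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param alpha significance level reported alongside (default 0.05).
#' @return List with `p_value`, `statistic`, `n_perm`, `alpha`,
#'   `significant`.
#' @export
permutation_paired_test <- function(a, b, n_perm = 1000L, seed = 1L,
                                    alpha = 0.05) {
  if (length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  t_stat <- function(x) {
    s <- stats::sd(x)
    m <- mean(x)
    if (s == 0) {                 # constant differences: degenerate t
      if (m == 0) 0 else sign(m) * Inf
    } else m / (s / sqrt(length(x)))
  }
  t_obs <- t_stat(d)
  t_null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    t_stat(d * sample(c(-1, 1), n, replace = TRUE))
  }, 0))
  p <- (1 + sum(abs(t_null) >= abs(t_obs))) / (n_perm + 1)
  list(p_value = p, statistic = t_obs, n_perm = n_perm, alpha = alpha,
       significant = p <= alpha)
}

#' Run the full LEiDA chain on a set of regional time series
#'
#' Convenience wrapper: band-pass filter, Hilbert phases, phase-coherence
#' tensor and leading eigenvectors per series, then pooled clustering into
#' `k` substates.
#'
#' @param ts_list a [regional_ts] or list of them.
#' @param k number of substates.
#' @param band band-pass edges in Hz.
#' @param trim Hilbert edge-trim samples.
#' @param n_restarts,seed passed to [cluster_states()].
#' @return List with `eigs` (list of `eigenvector_series`) and `clustering`
#'   (a `pms_clustering`).
#' @export
run_leida <- function(ts_list, k = 3L, band = c(0.02, 0.1), trim = 3L,
                      n_restarts = 20L, seed = 1L) {
  if (inherits(ts_list, "regional_ts")) ts_list <- list(ts_list)
  eigs <- lapply(ts_list, function(ts) {
    leading_eigenvectors(phase_coherence_tensor(
      compute_phases(bandpass_filter(ts, band[1L], band[2L]), trim)))
  })
  list(eigs = eigs, clustering = cluster_states(eigs, k, n_restarts, seed))
}
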