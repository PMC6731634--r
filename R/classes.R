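#' Regional time-series container
#'
#' Bundles an N x T matrix of regional signals with its sampling period and
#' labels. This is the object every analysis stage consumes: raw or filtered
#' BOLD-like signals in the rows (one row per region), samples in the columns.
#'
#' @param values numeric N x T matrix, regions in rows.
#' @param tr_s sampling period in seconds (the repetition time, TR).
#' @param subject_id,condition optional labels carried through the pipeline.
#' @return An object of class `regional_ts`.
#' @export
regional_ts <- function(values, tr_s, subject_id = "s1", condition = "none") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (regions x samples)", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at region %d, sample %d", bad[1L], bad[2L]),
         call. = FALSE)
  }
  if (nrow(values) < 1L) stop("need at least 1 region", call. = FALSE)
  stop_if_not_scalar(tr_s, "tr_s", positive = TRUE)
  structure(list(values = values, tr_s = tr_s,
                 subject_id = as.character(subject_id),
                 condition = as.character(condition)),
            class = "regional_ts")
}

#' @export
print.regional_ts <- function(x, ...) {
  cat(sprintf("<regional_ts> %d regions x %d samples, TR = %g s (%s, %s)\n",
              nrow(x$values), ncol(x$values), x$tr_s, x$subject_id,
              x$condition))
  invisible(x)
}

#' Structural connectome container
#'
#' An undirected weighted network over N brain regions: a symmetric,
#' zero-diagonal, non-negative weight matrix plus the table of homotopic
#' (left/right counterpart) region pairs needed for bilateral stimulation.
#' On construction the matrix is checked, never rescaled; use
#' [generate_connectome()] to build normalized synthetic connectomes.
#'
#' @param weights symmetric non-negative N x N matrix with zero diagonal.
#' @param region_names character vector of N labels.
#' @param homotopic_pairs integer matrix with two columns (left, right index),
#'   each region appearing in exactly one pair, or `NULL` when unknown.
#' @return An object of class `connectome`.
#' @export
connectome <- function(weights, region_names = NULL, homotopic_pairs = NULL) {
  check_symmetric(weights, tol = 1e-9, name = "weights")
  if (any(weights < 0)) stop("connectome weights must be >= 0", call. = FALSE)
  if (any(diag(weights) != 0)) stop("connectome diagonal must be 0", call. = FALSE)
  n <- nrow(weights)
  if (is.null(region_names)) region_names <- sprintf("R%02d", seq_len(n))
  if (length(region_names) != n) stop("need one name per region", call. = FALSE)
  if (!is.null(homotopic_pairs)) {
    homotopic_pairs <- matrix(as.integer(homotopic_pairs), ncol = 2L)
    idx <- as.vector(homotopic_pairs)
    if (anyDuplicated(idx) || any(idx < 1L) || any(idx > n))
      stop("homotopic pairs must partition regions, one pair per region",
           call. = FALSE)
  }
  dimnames(weights) <- list(region_names, region_names)
  structure(list(weights = weights, region_names = region_names,
                 homotopic_pairs = homotopic_pairs),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$weights)
  off <- x$weights[row(x$weights) != col(x$weights)]
  cat(sprintf("<connectome> %d regions, mean off-diagonal weight %.4g%s\n",
              n, mean(off),
              if (is.null(x$homotopic_pairs)) ""
              else sprintf(", %d homotopic pairs", nrow(x$homotopic_pairs))))
  invisible(x)
}

#' Parameters of the coupled Stuart-Landau (Hopf) whole-brain model
#'
#' Local node `n` obeys the normal form of a supercritical Hopf bifurcation:
#' for bifurcation parameter `a[n] > 0` it holds a stable limit cycle of
#' radius `sqrt(a[n])` at frequency `omega[n]/2/pi` Hz; for `a[n] < 0` it
#' relaxes to a noisy low-activity fixed point. Nodes are coupled by
#' difference coupling through the connectome, scaled by the global coupling
#' `G`, and driven by additive Gaussian noise of standard deviation `beta`.
#'
#' @param a numeric vector (or scalar, recycled) of bifurcation parameters.
#'   Default 0: nodes sit at the bifurcation edge, where the model expresses
#'   the transition between noisy and oscillatory dynamics.
#' @param omega angular frequencies in rad/s (scalar recycled).
#' @param G global coupling weight, >= 0.
#' @param beta noise standard deviation, >= 0 (default 0.02).
#' @param dt_s Euler-Maruyama integration step in seconds.
#' @param tr_s output sampling period in seconds.
#' @param transient_s initial duration to discard, seconds.
#' @return An object of class `hopf_params`.
#' @export
hopf_params <- function(a = 0, omega = 2 * pi * 0.05, G = 0, beta = 0.02,
                        dt_s = 0.1, tr_s = 2, transient_s = 60) {
  stopifnot(is.numeric(a), is.numeric(omega), all(is.finite(a)),
            all(is.finite(omega)))
  stop_if_not_scalar(G, "G"); stop_if_not_scalar(beta, "beta")
  stop_if_not_scalar(dt_s, "dt_s", positive = TRUE)
  stop_if_not_scalar(tr_s, "tr_s", positive = TRUE)
  stop_if_not_scalar(transient_s, "transient_s")
  if (G < 0 || beta < 0) stop("G and beta must be >= 0", call. = FALSE)
  if (dt_s > tr_s) stop("dt_s must not exceed tr_s", call. = FALSE)
  structure(list(a = a, omega = omega, G = G, beta = beta, dt_s = dt_s,
                 tr_s = tr_s, transient_s = transient_s),
            class = "hopf_params")
}

#' @export
print.hopf_params <- function(x, ...) {
  cat(sprintf(
    "<hopf_params> a in [%g, %g], f in [%.3g, %.3g] Hz, G = %g, beta = %g\n",
    min(x$a), max(x$a), min(x$omega) / (2 * pi), max(x$omega) / (2 * pi),
    x$G, x$beta))
  invisible(x)
}

# Expand scalar a/omega to length n, checking consistency.
expand_params <- function(params, n) {
  for (f in c("a", "omega")) {
    v <- params[[f]]
    if (length(v) == 1L) params[[f]] <- rep(v, n)
    else if (length(v) != n)
      stop(sprintf("`%s` has length %d but the network has %d nodes",
                   f, length(v), n), call. = FALSE)
  }
  params
}

#' Probabilistic metastable substate (PMS) model
#'
#' The operational description of a brain state: `k` recurrent phase-coherence
#' patterns (cluster centroids over leading eigenvectors), the fractional
#' occupancy of each, and the row-stochastic switching (transition
#' probability) matrix between them.
#'
#' @param centroids k x N matrix of substate centroid eigenvectors.
#' @param probabilities length-k occupancy vector (non-negative, sums to 1).
#' @param tpm k x k transition probability matrix (rows may be `NA` for
#'   substates never visited).
#' @param silhouette optional mean silhouette width of the clustering.
#' @return An object of class `pms_model`.
#' @export
pms_model <- function(centroids, probabilities, tpm = NULL, silhouette = NULL) {
  centroids <- as.matrix(centroids)
  k <- nrow(centroids)
  if (length(probabilities) != k)
    stop("probabilities length must equal the number of centroids", call. = FALSE)
  if (any(probabilities < -1e-12) || abs(sum(probabilities) - 1) > 1e-9)
    stop("probabilities must be a simplex vector (>= 0, sum 1)", call. = FALSE)
  if (!is.null(tpm)) {
    tpm <- as.matrix(tpm)
    if (!identical(dim(tpm), c(k, k)))
      stop("tpm must be k x k", call. = FALSE)
    ok <- !apply(tpm, 1L, anyNA)
    if (any(tpm[ok, ] < -1e-12) ||
        any(abs(rowSums(tpm)[ok] - 1) > 1e-9))
      stop("tpm rows must sum to 1 (NA rows mark unvisited substates)",
           call. = FALSE)
  }
  structure(list(centroids = centroids, probabilities = as.numeric(probabilities),
                 tpm = tpm, k = k, silhouette = silhouette),
            class = "pms_model")
}

#' @export
print.pms_model <- function(x, ...) {
  cat(sprintf("<pms_model> k = %d substates over %d regions\n", x$k,
              ncol(x$centroids)))
  cat("  occupancy:", paste(sprintf("%.3f", x$probabilities), collapse = " "),
      "\n")
  if (!is.null(x$silhouette))
    cat(sprintf("  mean silhouette: %.3f\n", x$silhouette))
  invisible(x)
}
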