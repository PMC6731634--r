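# On-disk formats: TSV for matrices and time series (human-diffable), JSON
# sidecars/models. Every writer/reader pair is a lossless round trip for
# finite inputs, and every file carries a schema version.

SCHEMA_VERSION <- 1L

sidecar_path <- function(path) paste0(path, ".json")

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
}

read_json_file <- function(path, what) {
  if (!file.exists(path)) stop(sprintf("missing %s file: %s", what, path),
                               call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version))
    stop(sprintf("%s lacks a schema_version field; not a recognized %s file",
                 path, what), call. = FALSE)
  obj
}

write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
}

read_matrix_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' Read and write regional time series
#'
#' Time series are stored as a TSV matrix (regions in rows, samples in
#' columns) plus a JSON sidecar (`<path>.json`) holding the sampling period
#' and labels; the sampling period is always read from the sidecar, never
#' guessed.
#'
#' @param ts a [regional_ts].
#' @param path TSV file path.
#' @return `read_timeseries`: a [regional_ts].
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "regional_ts"))
  write_matrix_tsv(ts$values, path)
  write_json_file(list(schema_version = SCHEMA_VERSION, tr_s = ts$tr_s,
                       subject_id = ts$subject_id, condition = ts$condition),
                  sidecar_path(path))
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  m <- read_matrix_tsv(path)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("NaN/missing value in %s at row %d, column %d",
                 path, bad[1L], bad[2L]), call. = FALSE)
  }
  meta <- read_json_file(sidecar_path(path), "time-series sidecar")
  if (is.null(meta$tr_s))
    stop(sprintf("sidecar %s does not state tr_s", sidecar_path(path)),
         call. = FALSE)
  regional_ts(m, meta$tr_s, meta$subject_id %||% "s1",
              meta$condition %||% "none")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write connectomes
#'
#' The weight matrix goes to TSV; region names, homotopic pairs and the mean
#' off-diagonal weight go to the JSON sidecar. Reading validates symmetry
#' (to 1e-9) and non-negativity.
#'
#' @param conn a [connectome].
#' @param path TSV file path.
#' @return `read_connectome`: a [connectome].
#' @export
write_connectome <- function(conn, path) {
  stopifnot(inherits(conn, "connectome"))
  write_matrix_tsv(conn$weights, path)
  off <- row(conn$weights) != col(conn$weights)
  write_json_file(list(schema_version = SCHEMA_VERSION,
                       region_names = conn$region_names,
                       homotopic_pairs = conn$homotopic_pairs,
                       mean_weight = mean(conn$weights[off])),
                  sidecar_path(path))
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  w <- read_matrix_tsv(path)
  meta <- read_json_file(sidecar_path(path), "connectome sidecar")
  pairs <- meta$homotopic_pairs
  if (!is.null(pairs)) pairs <- matrix(as.integer(as.matrix(pairs)), ncol = 2L)
  connectome(w, meta$region_names, pairs)
}

#' Read and write PMS models
#'
#' Serialized as JSON: centroids, occupancy probabilities, transition
#' matrix, `k`, and the sign convention. Reading enforces the simplex and
#' row-stochasticity invariants, so a corrupted or hand-edited model is
#' rejected rather than silently accepted.
#'
#' @param model a [pms_model].
#' @param path JSON file path.
#' @return `read_pms_model`: a [pms_model].
#' @export
write_pms_model <- function(model, path) {
  stopifnot(inherits(model, "pms_model"))
  write_json_file(list(schema_version = SCHEMA_VERSION, k = model$k,
                       centroids = model$centroids,
                       probabilities = model$probabilities,
                       tpm = model$tpm,
                       sign_convention = "majority_negative",
                       silhouette = model$silhouette),
                  path)
  invisible(path)
}

#' @rdname write_pms_model
#' @export
read_pms_model <- function(path) {
  obj <- read_json_file(path, "PMS model")
  tpm <- if (is.null(obj$tpm)) NULL else as.matrix(obj$tpm)
  pms_model(as.matrix(obj$centroids), obj$probabilities, tpm,
            obj$silhouette)
}

#' Read and write EC matrices, transition maps and greedy traces
#'
#' The effective-connectivity matrix goes to TSV; a transition map goes to
#' TSV (rows = homotopic pairs, columns = intensities) with a JSON sidecar
#' (grid, baseline KL, protocol); a greedy trace is a single JSON file.
#'
#' @param ec an `ec_state`; `map` a `transition_map`; `trace` a
#'   `greedy_trace`.
#' @param path output path.
#' @return Readers return the corresponding object.
#' @export
write_ec <- function(ec, path) {
  stopifnot(inherits(ec, "ec_state"))
  write_matrix_tsv(ec$weights, path)
  write_json_file(list(schema_version = SCHEMA_VERSION, epsilon = ec$epsilon,
                       iteration = ec$iteration,
                       objective = ec$fit_history$objective),
                  sidecar_path(path))
  invisible(path)
}

#' @rdname write_ec
#' @export
read_ec <- function(path) {
  w <- read_matrix_tsv(path)
  meta <- read_json_file(sidecar_path(path), "EC sidecar")
  structure(list(weights = w, iteration = meta$iteration,
                 fit_history = data.frame(
                   iteration = seq_along(meta$objective),
                   objective = meta$objective),
                 epsilon = meta$epsilon),
            class = "ec_state")
}

#' @rdname write_ec
#' @export
write_transition_map <- function(map, path) {
  stopifnot(inherits(map, "transition_map"))
  write_matrix_tsv(map$kl_values, path)
  write_json_file(list(schema_version = SCHEMA_VERSION,
                       intensity_grid = map$intensity_grid,
                       baseline_kl = map$baseline_kl,
                       protocol = map$protocol,
                       pair_table = map$pair_table),
                  sidecar_path(path))
  invisible(path)
}

#' @rdname write_ec
#' @export
read_transition_map <- function(path) {
  kl <- read_matrix_tsv(path)
  meta <- read_json_file(sidecar_path(path), "transition-map sidecar")
  structure(list(kl_values = kl, intensity_grid = meta$intensity_grid,
                 baseline_kl = meta$baseline_kl, protocol = meta$protocol,
                 pair_table = matrix(as.integer(as.matrix(meta$pair_table)),
                                     ncol = 2L)),
            class = "transition_map")
}

#' @rdname write_ec
#' @export
write_greedy_trace <- function(trace, path) {
  stopifnot(inherits(trace, "greedy_trace"))
  write_json_file(list(schema_version = SCHEMA_VERSION,
                       chosen_pairs = trace$chosen_pairs,
                       kl_to_target = trace$kl_to_target,
                       kl_to_source = trace$kl_to_source,
                       substate_probabilities = trace$substate_probabilities,
                       best_step = trace$best_step, delta_a = trace$delta_a,
                       protocol = trace$protocol),
                  path)
  invisible(path)
}

#' @rdname write_ec
#' @export
read_greedy_trace <- function(path) {
  obj <- read_json_file(path, "greedy trace")
  structure(list(chosen_pairs = as.integer(obj$chosen_pairs),
                 kl_to_target = obj$kl_to_target,
                 kl_to_source = obj$kl_to_source,
                 substate_probabilities = as.matrix(obj$substate_probabilities),
                 best_step = as.integer(obj$best_step),
                 delta_a = obj$delta_a, protocol = obj$protocol),
            class = "greedy_trace")
}

# Provenance record written next to every CLI output artifact.
write_provenance <- function(out_path, command, config, seed, inputs = character(0)) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else NULL
  write_json_file(list(schema_version = SCHEMA_VERSION, command = command,
                       config = config, seed = seed,
                       package_version = as.character(
                         utils::packageVersion("pmstates")),
                       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                       input_digests = digests),
                  paste0(out_path, ".prov.json"))
  invisible(NULL)
}
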