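# Text serialization: spike rasters, parameter snapshots, metric logs.

#' Read and write spike trains as event lists
#'
#' The event-list format is a two-column CSV (`time_step`, `neuron_index`,
#' both 0-based) holding one row per spike; [write_spike_matrix()] dumps the
#' dense binary matrix instead.
#'
#' @param spikes binary matrix `[time, n_neurons]`.
#' @param path file path.
#' @param n_steps,n_neurons dimensions for reconstruction.
#' @export
write_spike_events <- function(spikes, path) {
  spikes <- as.matrix(spikes)
  assert_binary(spikes, "spike matrix")
  idx <- which(spikes == 1, arr.ind = TRUE)
  df <- data.frame(time_step = idx[, 1L] - 1L, neuron_index = idx[, 2L] - 1L)
  df <- df[order(df$time_step, df$neuron_index), , drop = FALSE]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_events
#' @export
read_spike_events <- function(path, n_steps, n_neurons) {
  df <- read.csv(path)
  out <- matrix(0, n_steps, n_neurons)
  if (nrow(df) > 0L) out[cbind(df$time_step + 1L, df$neuron_index + 1L)] <- 1
  out
}

#' @rdname write_spike_events
#' @export
write_spike_matrix <- function(spikes, path) {
  utils::write.table(as.matrix(spikes), path, row.names = FALSE,
                     col.names = FALSE, sep = ",")
  invisible(path)
}

#' Save and load a parameter snapshot
#'
#' Parameters (weights, plasticity coefficients and rule parameters) are
#' stored as a flat JSON object mapping each parameter name to its
#' dimensions and values, so snapshots are portable text.
#'
#' @param params named list of numeric arrays.
#' @param path file path.
#' @export
save_params <- function(params, path) {
  enc <- lapply(params, function(p) {
    list(dim = if (is.matrix(p)) dim(p) else length(p), data = as.vector(p))
  })
  jsonlite::write_json(enc, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname save_params
#' @export
load_params <- function(path) {
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(enc, function(e) {
    d <- e$dim
    if (length(d) == 2L) matrix(e$data, d[1L], d[2L]) else as.numeric(e$data)
  })
  names(out) <- names(enc)
  out
}

# Small polynomial content hash over the serialized object, for run
# manifests (identity/change detection, not cryptographic).
content_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
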