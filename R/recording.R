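# Recording container: time-sampled membrane-potential movie plus per-node
# activation metadata; the substrate of all analysis stages.

#' Construct a recording object
#'
#' @param frames Numeric matrix, nodes x frames (node index runs
#'   column-major over the `nx` x `ny` grid).
#' @param times Frame times (ms), equally spaced at `sample_dt`.
#' @param sample_dt Frame interval (ms).
#' @param mesh The `cw_mesh` the movie lives on.
#' @param activation Data frame with columns `node`, `t` (upstroke times,
#'   ms), or NULL.
#' @param metadata List of provenance: configuration, seeds, stimulus log.
#' @return A `cw_recording`.
#' @export
new_recording <- function(frames, times, sample_dt, mesh, activation = NULL,
                          metadata = list()) {
  stopifnot(ncol(frames) == length(times))
  if (length(times) > 1) {
    stopifnot(abs(diff(range(diff(times))) ) < 1e-6,
              abs(diff(times)[1] - sample_dt) < 1e-6)
  }
  if (is.null(activation)) {
    activation <- data.frame(node = integer(0), t = numeric(0))
  }
  structure(list(frames = frames, times = times, sample_dt = sample_dt,
                 mesh = mesh, activation = activation, metadata = metadata),
            class = "cw_recording")
}

#' @export
print.cw_recording <- function(x, ...) {
  cat("<cw_recording> ", x$mesh$nx, " x ", x$mesh$ny, " nodes, ",
      ncol(x$frames), " frames at ", x$sample_dt, " ms (t = ",
      min(x$times), "..", max(x$times), " ms), ",
      nrow(x$activation), " upstrokes\n", sep = "")
  invisible(x)
}

#' Extract one frame as an nx x ny matrix
#'
#' @param recording A `cw_recording`.
#' @param index Frame index (1-based).
#' @return Numeric `nx` x `ny` matrix of membrane potential (mV).
#' @export
frame_matrix <- function(recording, index) {
  matrix(recording$frames[, index], recording$mesh$nx, recording$mesh$ny)
}

#' Per-node activation times as a list
#' @param recording A `cw_recording`.
#' @return List (length `n_nodes`) of increasing upstroke times.
#' @export
activation_list <- function(recording) {
  out <- vector("list", recording$mesh$n_nodes)
  if (nrow(recording$activation)) {
    sp <- split(recording$activation$t, recording$activation$node)
    out[as.integer(names(sp))] <- lapply(sp, sort)
  }
  out
}

#' Membrane-potential trace at one node
#' @param recording A `cw_recording`.
#' @param node Node index, or `c(i, j)` grid coordinates.
#' @return Data frame with `t` and `vm`.
#' @export
node_trace <- function(recording, node) {
  if (length(node) == 2) {
    node <- (node[2] - 1L) * recording$mesh$nx + node[1]
  }
  data.frame(t = recording$times, vm = recording$frames[node, ])
}

#' Export a recording's tabular summaries to CSV
#'
#' Writes `<stem>_activation.csv` (node, i, j, x_cm, y_cm, upstroke times)
#' and `<stem>_meta.json` (resolved metadata).
#'
#' @param recording A `cw_recording`.
#' @param stem Output path stem.
#' @return Invisibly, the paths written.
#' @export
write_recording_summary <- function(recording, stem) {
  act <- recording$activation
  nx <- recording$mesh$nx
  i <- (act$node - 1L) %% nx + 1L
  j <- (act$node - 1L) %/% nx + 1L
  df <- data.frame(node = act$node, i = i, j = j,
                   x_cm = (i - 1) * recording$mesh$dx,
                   y_cm = (j - 1) * recording$mesh$dx,
                   t_ms = act$t)
  p1 <- paste0(stem, "_activation.csv")
  write.csv(df, p1, row.names = FALSE)
  p2 <- paste0(stem, "_meta.json")
  jsonlite::write_json(recording$metadata, p2, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(c(p1, p2))
}
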