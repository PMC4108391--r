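# Monodomain reaction-diffusion stepping: per-node ionic reaction +
# flux-conservative anisotropic diffusion over the element-wise field,
# no-flux boundaries, Lie operator splitting.

#' Explicit anisotropic diffusion step(s)
#'
#' Flux-conservative finite differences on the regular grid: the flux
#' through each node-to-node edge uses the average of the diffusion
#' coefficients of the (at most two) elements adjacent to that edge, so no
#' net charge enters or leaves through the boundary.
#'
#' @param vm Membrane potential, an `nx` x `ny` matrix (or vector of length
#'   `nx*ny` with `nx`, `ny` supplied).
#' @param diffusion A `cw_diffusion` whose element grid matches `vm`.
#' @param dx Node spacing (cm).
#' @param dt Time step (ms); must satisfy `dt < dx^2 / (2 max(d_long))`.
#' @param n_steps Number of steps.
#' @param nx,ny Grid shape when `vm` is a bare vector.
#' @return Updated `vm` in the same shape as supplied.
#' @export
diffusion_step <- function(vm, diffusion, dx, dt, n_steps = 1,
                           nx = NULL, ny = NULL) {
  was_matrix <- is.matrix(vm)
  if (was_matrix) { nx <- nrow(vm); ny <- ncol(vm) }
  stopifnot(!is.null(nx), !is.null(ny))
  out <- cw_diffusion_steps(as.numeric(vm), nx, ny, diffusion$d_long,
                            diffusion$d_trans, dx, dt, as.integer(n_steps))
  if (was_matrix) matrix(out, nx, ny) else out
}

#' Diffusion stability limit
#' @param diffusion A `cw_diffusion`.
#' @param dx Node spacing (cm).
#' @return Maximal stable `dt` (ms) for the explicit scheme.
#' @export
stability_limit <- function(diffusion, dx) dx^2 / (2 * max(diffusion$d_long))

#' Advance a tissue and record a membrane-potential movie
#'
#' Lie splitting per time step: every node takes one ionic reaction step
#' (with any active stimulus current injected into myocyte nodes), then the
#' membrane potential diffuses over the heterogeneous element field.
#' Upstrokes are detected online (threshold crossing with a minimum rate of
#' rise and a refractory lockout). Spontaneous activations arising from
#' fibroblast-myocyte interaction at high fibrotic content are legitimate
#' dynamics and are recorded like any other upstroke.
#'
#' @param tissue A `cw_tissue` (its `state` holds the starting point).
#' @param stimuli List of stimulus specifications from [make_stimulus()].
#' @param duration Simulated time (ms).
#' @param dt Reaction/diffusion step (ms); default 0.002.
#' @param sample_dt Frame sampling interval (ms); default 1.
#' @param record_frames Keep the frame movie (set FALSE to save memory when
#'   only activation times are needed).
#' @param act_thresh,act_dvdt,act_lockout Upstroke detector: threshold
#'   (mV), minimum dV/dt (mV/ms), per-node lockout (ms).
#' @param metadata Extra provenance merged into the recording metadata.
#' @return List with `tissue` (advanced state) and `recording`
#'   (a `cw_recording`; frames empty when `record_frames = FALSE`).
#' @export
run_tissue <- function(tissue, stimuli = list(), duration, dt = 0.002,
                       sample_dt = 1, record_frames = TRUE,
                       act_thresh = -20, act_dvdt = 5, act_lockout = 100,
                       metadata = list()) {
  stopifnot(inherits(tissue, "cw_tissue"), duration >= 0)
  mesh <- tissue$node_map$mesh
  if (sample_dt > 0 && abs(sample_dt / dt - round(sample_dt / dt)) > 1e-6) {
    stop("sample_dt must be an integer multiple of dt")
  }
  st <- tissue$state
  act_last <- st$act_last
  if (is.null(act_last)) act_last <- rep(-1e18, mesh$n_nodes)

  stim_nodes <- lapply(stimuli, function(s) as.integer(s$nodes))
  stim_tda <- do.call(rbind, lapply(stimuli, function(s) {
    cbind(s$onsets, s$duration, s$amplitude)
  }))
  if (is.null(stim_tda)) stim_tda <- matrix(0, 0, 3)

  out <- cw_tissue_run(st$vm, st$myo_y, st$fib_y,
                       as.integer(tissue$node_map$kind), mesh$nx, mesh$ny,
                       tissue$diffusion$d_long, tissue$diffusion$d_trans,
                       mesh$dx, dt, duration, st$t,
                       stim_nodes, stim_tda,
                       unname(tissue$params$endo$scale),
                       unname(tissue$params$fib$scale),
                       sample_dt, record_frames,
                       act_thresh, act_dvdt, act_lockout, act_last)

  tissue$state <- list(vm = out$vm, myo_y = out$myo_y, fib_y = out$fib_y,
                       t = out$t_end, act_last = out$act_last)

  meta <- c(list(
    condition = tissue$condition,
    p_f = tissue$node_map$p_f,
    fibrosis_seed = tissue$node_map$seed,
    overrides = as.list(tissue$params$endo$scale[tissue$params$endo$scale != 1]),
    d_myo = tissue$diffusion$d_myo,
    anisotropy_ratio = tissue$diffusion$anisotropy_ratio,
    fib_factor = tissue$diffusion$fib_factor,
    dt = dt, sample_dt = sample_dt, duration = duration,
    stimulus_log = lapply(stimuli, function(s) {
      s[c("label", "onsets", "duration", "amplitude")]
    }),
    package_version = as.character(utils::packageVersion("cardiowave"))
  ), metadata)

  rec <- new_recording(out$frames, out$frame_times, sample_dt, mesh,
                       activation = data.frame(node = out$act_node,
                                               t = out$act_time),
                       metadata = meta)
  list(tissue = tissue, recording = rec)
}

#' Single operator-splitting step
#'
#' Convenience wrapper advancing the tissue by exactly one `dt` (reaction
#' then diffusion). `dt = 0` returns the tissue unchanged.
#'
#' @inheritParams run_tissue
#' @param dt Time step (ms).
#' @return The advanced `cw_tissue`.
#' @export
tissue_step <- function(tissue, stimuli = list(), dt = 0.002) {
  if (dt == 0) return(tissue)
  run_tissue(tissue, stimuli, duration = dt, dt = dt, sample_dt = 0,
             record_frames = FALSE)$tissue
}
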