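# Analytic inputs with known ground truth: plane-wave and rotating-spiral
# membrane-potential movies, AP trains, vortex phase fields, and the four
# named fibrosis presets. These let every analysis stage be tested without
# PDE runs; the stylized AP waveform is deliberately independent of the
# ionic models under test.

#' Stylized action-potential pulse
#'
#' Piecewise waveform: 1 ms linear upstroke from rest to peak, plateau,
#' cosine repolarization back to rest, used by the analytic fixtures.
#'
#' @param s Time since activation (ms); values outside the pulse give rest.
#' @param apd Nominal duration of the repolarization envelope (ms).
#' @param rest,peak Resting and peak potentials (mV).
#' @return Membrane potential (mV).
#' @export
ap_pulse <- function(s, apd = 200, rest = -80, peak = 20) {
  v <- rep(rest, length(s))
  up <- s >= 0 & s < 1
  v[up] <- rest + (peak - rest) * s[up]
  rep_phase <- (s - 1) / apd
  on <- s >= 1 & rep_phase < 1
  v[on] <- rest + (peak - rest) * (1 + cos(pi * rep_phase[on]^2)) / 2
  v
}

#' Analytic plane-wave recording
#'
#' `Vm(x, t) = pulse(t - t_start - x / speed)`: a single planar wave
#' travelling in +x at the programmed speed.
#'
#' @param mesh A `cw_mesh`.
#' @param speed Wave speed (cm/s).
#' @param sample_dt Frame interval (ms).
#' @param duration Movie length (ms); default long enough for the wave to
#'   cross the sheet plus one APD.
#' @param t_start Activation time at x = 0 (ms).
#' @param apd,rest,peak Passed to [ap_pulse()].
#' @return List with `recording` (a `cw_recording`) and `truth`
#'   (`speed`, `t_start`).
#' @export
make_plane_wave <- function(mesh, speed, sample_dt = 1, duration = NULL,
                            t_start = 5, apd = 200, rest = -80, peak = 20) {
  stopifnot(speed > 0)
  v_ms <- speed / 1000  # cm/ms
  if (is.null(duration)) duration <- t_start + mesh$lx / v_ms + apd + 20
  times <- seq(0, duration, by = sample_dt)
  xy <- node_xy(mesh)
  frames <- vapply(times, function(t) {
    ap_pulse(t - t_start - xy$x / v_ms, apd = apd, rest = rest, peak = peak)
  }, numeric(mesh$n_nodes))
  rec <- new_recording(frames, times, sample_dt, mesh,
                       metadata = list(fixture = "plane_wave", speed = speed))
  list(recording = rec, truth = list(speed = speed, t_start = t_start))
}

#' Analytic rotating-spiral recording
#'
#' Builds an Archimedean-spiral phase field rotating with the programmed
#' period around a (possibly moving) core and maps it through the stylized
#' AP waveform.
#'
#' @param mesh A `cw_mesh`.
#' @param period Rotation period (ms).
#' @param core `c(x, y)` (cm) for a stationary core, or a function of time
#'   (ms) returning `c(x, y)`.
#' @param sample_dt Frame interval (ms).
#' @param duration Movie length (ms).
#' @param wavelength Spiral arm spacing (cm).
#' @param charge +1 (counter-clockwise) or -1.
#' @param apd Plateau+repolarization envelope (ms); capped at 0.9 period.
#' @return List with `recording` and `truth` (`period`, `core_path` data
#'   frame, `charge`, `rotations`).
#' @export
make_spiral <- function(mesh, period, core = c(mesh$lx / 2, mesh$ly / 2),
                        sample_dt = 1, duration = 4 * period,
                        wavelength = 0.8 * min(mesh$lx, mesh$ly),
                        charge = 1, apd = NULL) {
  stopifnot(period > 0, charge %in% c(-1, 1))
  if (is.null(apd)) apd <- 0.6 * period
  apd <- min(apd, 0.9 * period)
  core_fun <- if (is.function(core)) core else function(t) core
  times <- seq(0, duration, by = sample_dt)
  xy <- node_xy(mesh)
  frames <- vapply(times, function(t) {
    cc <- core_fun(t)
    theta <- atan2(xy$y - cc[2], xy$x - cc[1])
    r <- sqrt((xy$x - cc[1])^2 + (xy$y - cc[2])^2)
    # time within the local cycle: advances with t, delayed outward along
    # the Archimedean arm, once around the core per rotation
    s_cyc <- ((t / period - r / wavelength - charge * theta / (2 * pi)) %% 1) *
      period
    ap_pulse(s_cyc, apd = apd)
  }, numeric(mesh$n_nodes))
  core_path <- t(vapply(times, core_fun, numeric(2)))
  rec <- new_recording(frames, times, sample_dt, mesh,
                       metadata = list(fixture = "spiral", period = period,
                                       charge = charge))
  list(recording = rec,
       truth = list(period = period,
                    core_path = data.frame(t = times, x = core_path[, 1],
                                           y = core_path[, 2]),
                    charge = charge, rotations = duration / period))
}

#' Analytic multi-vortex phase field
#'
#' `phi(x, y) = wrap(sum_k q_k atan2(y - y_k, x - x_k))`.
#'
#' @param mesh A `cw_mesh`.
#' @param charges Data frame or matrix with columns `x`, `y`, `charge`
#'   (pairwise at least `4 dx` apart), possibly empty.
#' @return `nx` x `ny` phase matrix in (-pi, pi].
#' @export
make_vortex_phase_field <- function(mesh, charges) {
  charges <- as.data.frame(charges)
  if (nrow(charges) > 1) {
    d <- as.matrix(stats::dist(charges[, c("x", "y")]))
    diag(d) <- Inf
    stopifnot(min(d) >= 4 * mesh$dx)
  }
  xy <- node_xy(mesh)
  phi <- numeric(mesh$n_nodes)
  # nudge charges off the node lattice so the winding center lies strictly
  # inside one element (the angle at a core sitting exactly on a node is
  # undefined and would smear the singularity over adjacent elements)
  nudge <- mesh$dx / 200
  for (k in seq_len(nrow(charges))) {
    phi <- phi + charges$charge[k] *
      atan2(xy$y - charges$y[k] - nudge, xy$x - charges$x[k] - nudge)
  }
  matrix(wrap_phase(phi), mesh$nx, mesh$ny)
}

#' Analytic paced AP-train trace
#'
#' @param bcl Basic cycle length (ms).
#' @param n_beats Number of beats.
#' @param sample_dt Sampling interval (ms).
#' @param apd Passed to [ap_pulse()].
#' @return Data frame with `t`, `vm`.
#' @export
make_ap_train <- function(bcl = 1000, n_beats = 4, sample_dt = 1, apd = 250) {
  t <- seq(0, n_beats * bcl, by = sample_dt)
  s <- t %% bcl
  s[t >= n_beats * bcl] <- -1
  data.frame(t = t, vm = ap_pulse(s, apd = apd))
}

#' Named fibrosis presets
#'
#' The four tissue configurations studied at full scale: "minimal"
#' (P_f = 4%), "mild1" (14.5%), "mild2" (28%) and "high" (40%), on the
#' 5 x 5 cm sheet (or a scaled-down version), with the myocyte diffusion
#' coefficient, anisotropy ratio 4 and the three-fold fibrotic reduction.
#'
#' @param name One of `"minimal"`, `"mild1"`, `"mild2"`, `"high"`.
#' @param seed Fibroblast-placement seed.
#' @param condition `"NC"` or `"HF"` myocyte remodeling (the full-scale
#'   fibrosis study uses HF).
#' @param scale Geometry scale factor (1 = 5 x 5 cm).
#' @param dx Node spacing (cm).
#' @param d_multiplier Intercellular-uncoupling multiplier on the myocyte
#'   diffusion coefficient (1, 0.5, 0.1, 0.01 in the uncoupling study).
#' @param d_myo Normal myocyte diffusion coefficient (cm^2/ms).
#' @return A ready `cw_tissue`.
#' @export
preset <- function(name = c("minimal", "mild1", "mild2", "high"), seed,
                   condition = "HF", scale = 1, dx = 0.01, d_multiplier = 1,
                   d_myo = 0.0013) {
  name <- match.arg(name)
  p_f <- c(minimal = 0.04, mild1 = 0.145, mild2 = 0.28, high = 0.40)[[name]]
  mesh <- build_mesh(5 * scale, 5 * scale, dx)
  nm <- assign_node_types(mesh, p_f, seed)
  df <- build_diffusion(nm, d_myo = d_myo * d_multiplier)
  make_tissue(nm, df, condition = condition)
}
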