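# Post-hoc analysis of recordings: Hilbert instantaneous phase, ring-sum
# phase-singularity detection, tip tracking, rotation counting, dominant
# cycle-length histograms, conduction velocity and APD measurement.

#' Detect upstrokes in a recorded movie
#'
#' Offline counterpart of the solver's online detector, for recordings that
#' were built analytically (fixtures) or loaded without activation
#' metadata: threshold crossing with a minimum rate of rise and a per-node
#' refractory lockout.
#'
#' @param recording A `cw_recording` with frames.
#' @param thresh Crossing threshold (mV).
#' @param dvdt Minimum rate of rise at the crossing (mV/ms).
#' @param lockout Per-node refractory lockout (ms).
#' @return Data frame with `node`, `t`.
#' @export
detect_upstrokes <- function(recording, thresh = -20, dvdt = 5, lockout = 100) {
  fr <- recording$frames
  tt <- recording$times
  dt <- recording$sample_dt
  n <- nrow(fr); T <- ncol(fr)
  out_node <- integer(0); out_t <- numeric(0)
  if (T < 2) return(data.frame(node = out_node, t = out_t))
  cross <- fr[, -1, drop = FALSE] >= thresh & fr[, -T, drop = FALSE] < thresh &
    (fr[, -1, drop = FALSE] - fr[, -T, drop = FALSE]) / dt > dvdt
  idx <- which(cross, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(node = out_node, t = out_t))
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  node <- idx[, 1]
  v0 <- fr[cbind(node, idx[, 2])]
  v1 <- fr[cbind(node, idx[, 2] + 1L)]
  # sub-sample crossing time by linear interpolation
  tcross <- tt[idx[, 2]] + (thresh - v0) / (v1 - v0) * dt
  keep <- logical(length(node))
  last_node <- -1L; last_t <- -Inf
  for (k in seq_along(node)) {
    if (node[k] != last_node || tcross[k] - last_t > lockout) {
      keep[k] <- TRUE
      last_node <- node[k]; last_t <- tcross[k]
    }
  }
  data.frame(node = node[keep], t = tcross[keep])
}

upstrokes_of <- function(recording, ...) {
  if (nrow(recording$activation)) recording$activation
  else detect_upstrokes(recording, ...)
}

#' Instantaneous phase of a membrane-potential movie
#'
#' Per node: subtract the temporal mean, form the analytic signal (FFT
#' method), and take the four-quadrant arctangent of (Hilbert component,
#' signal), yielding phase in (-pi, pi]. Constant-signal nodes get phase 0
#' and are flagged.
#'
#' @param recording A `cw_recording` (at least two dominant cycles long for
#'   a meaningful phase).
#' @return A `cw_phase_movie`: list with `phases` (nodes x frames matrix),
#'   `times`, `sample_dt`, `mesh`, `flat_nodes`.
#' @export
instantaneous_phase <- function(recording) {
  fr <- recording$frames
  n <- nrow(fr); T <- ncol(fr)
  stopifnot(T >= 4)
  h <- numeric(T)
  h[1] <- 1
  if (T %% 2 == 0) {
    h[T / 2 + 1] <- 1
    if (T > 2) h[2:(T / 2)] <- 2
  } else {
    h[2:((T + 1) / 2)] <- 2
  }
  phases <- matrix(0, n, T)
  flat <- logical(n)
  block <- 4000L
  for (lo in seq(1L, n, by = block)) {
    hi <- min(lo + block - 1L, n)
    x <- t(fr[lo:hi, , drop = FALSE])
    x <- sweep(x, 2, colMeans(x))
    flat_b <- apply(abs(x) < 1e-12, 2, all)
    z <- mvfft(mvfft(x) * h, inverse = TRUE) / T
    ph <- atan2(Im(z), Re(z))
    ph[, flat_b] <- 0
    phases[lo:hi, ] <- t(ph)
    flat[lo:hi] <- flat_b
  }
  structure(list(phases = phases, times = recording$times,
                 sample_dt = recording$sample_dt, mesh = recording$mesh,
                 flat_nodes = which(flat)),
            class = "cw_phase_movie")
}

#' @export
print.cw_phase_movie <- function(x, ...) {
  cat("<cw_phase_movie> ", x$mesh$nx, " x ", x$mesh$ny, " nodes, ",
      ncol(x$phases), " frames\n", sep = "")
  invisible(x)
}

# wrap to (-pi, pi]
wrap_phase <- function(x) x - 2 * pi * ceiling((x - pi) / (2 * pi))

#' Detect phase singularities in one phase frame
#'
#' For every interior element (2x2 node ring A, B, C, D traversed
#' counter-clockwise), the four phase differences wrapped to (-pi, pi] are
#' summed; a sum of +2pi marks a +1 singularity, -2pi a -1 singularity.
#' The tolerance absorbs floating-point noise only. Elements touching the
#' tissue boundary are excluded (phase beyond the sheet is undefined).
#'
#' @param phase_frame `nx` x `ny` matrix of phases in (-pi, pi].
#' @param mesh The `cw_mesh` (for dx and coordinates).
#' @param tol Detection tolerance on |sum -+ 2 pi|.
#' @return Data frame with element indices `i`, `j`, element-center
#'   coordinates `x`, `y` (cm) and `charge`.
#' @export
detect_phase_singularities <- function(phase_frame, mesh, tol = 1e-6) {
  nx <- mesh$nx; ny <- mesh$ny
  stopifnot(nrow(phase_frame) == nx, ncol(phase_frame) == ny, ny >= 2)
  A <- phase_frame[-nx, -ny, drop = FALSE]
  B <- phase_frame[-1, -ny, drop = FALSE]
  C <- phase_frame[-1, -1, drop = FALSE]
  D <- phase_frame[-nx, -1, drop = FALSE]
  s <- wrap_phase(B - A) + wrap_phase(C - B) + wrap_phase(D - C) + wrap_phase(A - D)
  pos <- abs(s - 2 * pi) < tol
  neg <- abs(s + 2 * pi) < tol
  # exclude boundary-touching elements
  interior <- matrix(TRUE, nx - 1, ny - 1)
  interior[c(1, nx - 1), ] <- FALSE
  interior[, c(1, ny - 1)] <- FALSE
  idx <- which((pos | neg) & interior, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(i = integer(0), j = integer(0), x = numeric(0),
                      y = numeric(0), charge = integer(0)))
  }
  data.frame(i = idx[, 1], j = idx[, 2],
             x = (idx[, 1] - 0.5) * mesh$dx,
             y = (idx[, 2] - 0.5) * mesh$dx,
             charge = ifelse(pos[idx], 1L, -1L))
}

#' Phase singularities over a whole phase movie
#'
#' @param phase_movie A `cw_phase_movie`.
#' @param frames Frame indices to scan (default all).
#' @return Data frame with `frame`, `t`, `i`, `j`, `x`, `y`, `charge`.
#' @export
ps_events <- function(phase_movie, frames = seq_along(phase_movie$times)) {
  mesh <- phase_movie$mesh
  out <- lapply(frames, function(f) {
    pf <- matrix(phase_movie$phases[, f], mesh$nx, mesh$ny)
    ps <- detect_phase_singularities(pf, mesh)
    if (nrow(ps)) cbind(frame = f, t = phase_movie$times[f], ps) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(frame = integer(0), t = numeric(0), i = integer(0),
                      j = integer(0), x = numeric(0), y = numeric(0),
                      charge = integer(0))
  }
  out
}

#' Link phase singularities into tip trajectories
#'
#' Greedy nearest-neighbor linking of same-charge singularities across
#' consecutive frames within `max_jump`; unmatched singularities start or
#' terminate trajectories.
#'
#' @param ps Data frame from [ps_events()] (time-ordered frames).
#' @param max_jump Maximal per-frame tip displacement (cm).
#' @return List of trajectories, each a data frame (`frame`, `t`, `x`,
#'   `y`, `charge`) with attribute `id`; ordered by decreasing length.
#' @export
track_tips <- function(ps, max_jump = 0.3) {
  if (!nrow(ps)) return(list())
  ps$traj <- NA_integer_
  next_id <- 1L
  frames <- sort(unique(ps$frame))
  prev_rows <- which(ps$frame == frames[1])
  ps$traj[prev_rows] <- seq_len(length(prev_rows))
  next_id <- length(prev_rows) + 1L
  for (fi in seq_along(frames)[-1]) {
    cur_rows <- which(ps$frame == frames[fi])
    if (frames[fi] - frames[fi - 1] == 1 && length(prev_rows)) {
      # candidate links ordered by distance
      cand <- expand.grid(a = prev_rows, b = cur_rows)
      cand <- cand[ps$charge[cand$a] == ps$charge[cand$b], , drop = FALSE]
      if (nrow(cand)) {
        cand$d <- sqrt((ps$x[cand$a] - ps$x[cand$b])^2 +
                         (ps$y[cand$a] - ps$y[cand$b])^2)
        cand <- cand[cand$d <= max_jump, , drop = FALSE]
        cand <- cand[order(cand$d), , drop = FALSE]
        used_a <- used_b <- integer(0)
        for (k in seq_len(nrow(cand))) {
          a <- cand$a[k]; b <- cand$b[k]
          if (a %in% used_a || b %in% used_b) next
          ps$traj[b] <- ps$traj[a]
          used_a <- c(used_a, a); used_b <- c(used_b, b)
        }
      }
    }
    new <- cur_rows[is.na(ps$traj[cur_rows])]
    if (length(new)) {
      ps$traj[new] <- seq(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
    prev_rows <- cur_rows
  }
  split_df <- split(ps[c("frame", "t", "x", "y", "charge")], ps$traj)
  out <- lapply(names(split_df), function(id) {
    df <- split_df[[id]]
    attr(df, "id") <- as.integer(id)
    df
  })
  out[order(vapply(out, nrow, 1L), decreasing = TRUE)]
}

# accumulated rotation (in units of full turns) seen by a probe node next
# to a tip trajectory
trajectory_rotations <- function(traj, phase_movie) {
  mesh <- phase_movie$mesh
  # probe at the trajectory's median tip element corner
  i <- round(stats::median(traj$x / mesh$dx + 0.5))
  j <- round(stats::median(traj$y / mesh$dx + 0.5))
  i <- min(max(i, 1), mesh$nx); j <- min(max(j, 1), mesh$ny)
  node <- (j - 1) * mesh$nx + i
  f0 <- min(traj$frame); f1 <- max(traj$frame)
  if (f1 - f0 < 1) return(0)
  ph <- phase_movie$phases[node, f0:f1]
  sum(abs(wrap_phase(diff(ph)))) / (2 * pi)
}

#' Count spiral-wave rotations in a window
#'
#' Primary route: track phase-singularity trajectories and return the
#' maximal accumulated tip rotation (in full turns). When no trajectory
#' survives the window, falls back to probe-upstroke counting: the maximal
#' number of full-amplitude upstrokes (peak above `min_peak`) at any node
#' inside the window, minus one (the wave that launched the episode).
#'
#' @param recording A `cw_recording`.
#' @param window `c(t0, t1)` ms; default the whole recording.
#' @param phase_movie Optional precomputed [instantaneous_phase()] result.
#' @param min_peak Minimum peak Vm (mV) for an upstroke to count as a true
#'   activation rather than an electrotonic deflection.
#' @param max_jump Tip-linking jump limit (cm).
#' @return Maximal rotation count (numeric; may be fractional).
#' @export
count_rotations <- function(recording, window = NULL, phase_movie = NULL,
                            min_peak = 0, max_jump = 0.3) {
  if (is.null(window)) window <- range(recording$times)
  sel <- recording$times >= window[1] & recording$times <= window[2]
  if (!any(sel)) return(0)
  if (is.null(phase_movie)) {
    sub <- new_recording(recording$frames[, sel, drop = FALSE],
                         recording$times[sel], recording$sample_dt,
                         recording$mesh, recording$activation,
                         recording$metadata)
    if (sum(sel) >= 8 && recording$mesh$ny >= 3) {
      phase_movie <- instantaneous_phase(sub)
    }
  }
  rot_traj <- 0
  if (!is.null(phase_movie)) {
    ps <- ps_events(phase_movie)
    trajs <- track_tips(ps, max_jump = max_jump)
    trajs <- trajs[vapply(trajs, nrow, 1L) >= 3]
    if (length(trajs)) {
      rot_traj <- max(vapply(trajs, trajectory_rotations, 1,
                             phase_movie = phase_movie))
    }
  }
  rot_probe <- probe_rotations(recording, window, min_peak)
  max(rot_traj, rot_probe)
}

# upstroke-count fallback: max over nodes of full-amplitude upstrokes in
# the window, minus one
probe_rotations <- function(recording, window, min_peak = 0) {
  act <- upstrokes_of(recording)
  act <- act[act$t > window[1] & act$t <= window[2], , drop = FALSE]
  if (!nrow(act)) return(0)
  if (ncol(recording$frames)) {
    # keep only upstrokes whose following 80 ms reach min_peak
    keep <- vapply(seq_len(nrow(act)), function(k) {
      sel <- recording$times >= act$t[k] &
        recording$times <= act$t[k] + 80
      any(recording$frames[act$node[k], sel] > min_peak)
    }, TRUE)
    act <- act[keep, , drop = FALSE]
    if (!nrow(act)) return(0)
  }
  max(tabulate(act$node)) - 1
}

#' Cycle-length histogram and dominant period
#'
#' Pools all inter-upstroke intervals from all nodes, rounded to the
#' nearest 1 ms, and returns the histogram together with the modal bin
#' (ties broken toward the longer period, since harmonics of the true
#' period land at shorter intervals).
#'
#' @param recording A `cw_recording`.
#' @param window Optional `c(t0, t1)` restriction (ms).
#' @param bin_width Bin width (ms); 1 by convention.
#' @return A `cw_cycle_histogram`: list with `counts` (named vector),
#'   `bin_width`, `dominant_period` (ms).
#' @export
dominant_period <- function(recording, window = NULL, bin_width = 1) {
  act <- upstrokes_of(recording)
  if (!is.null(window)) {
    act <- act[act$t >= window[1] & act$t <= window[2], , drop = FALSE]
  }
  if (!nrow(act)) stop("insufficient activity: no upstrokes recorded")
  ivals <- unlist(lapply(split(act$t, act$node), function(tt) {
    if (length(tt) >= 2) diff(sort(tt)) else numeric(0)
  }), use.names = FALSE)
  if (!length(ivals)) stop("insufficient activity: no node with >= 2 upstrokes")
  bins <- round(ivals / bin_width) * bin_width
  counts <- table(bins)
  best <- max(counts)
  modal <- as.numeric(names(counts)[counts == best])
  structure(list(counts = counts, bin_width = bin_width,
                 dominant_period = max(modal)),
            class = "cw_cycle_histogram")
}

#' @export
print.cw_cycle_histogram <- function(x, ...) {
  cat("<cw_cycle_histogram> dominant period ", x$dominant_period,
      " ms (", sum(x$counts), " intervals in ", length(x$counts),
      " bins of ", x$bin_width, " ms)\n", sep = "")
  invisible(x)
}

#' Conduction velocity between two points
#'
#' Distance between the two points divided by the difference of their
#' (unique) upstroke times.
#'
#' @param recording A `cw_recording`.
#' @param point_a,point_b Points `c(x, y)` in cm (y defaults to 0 for 1D
#'   cables when a single coordinate is given).
#' @param window Optional `c(t0, t1)` activation window (ms).
#' @return Conduction velocity (cm/s).
#' @export
measure_cv <- function(recording, point_a, point_b, window = NULL) {
  mesh <- recording$mesh
  locate <- function(p, label) {
    if (length(p) == 1) p <- c(p, 0)
    i <- round(p[1] / mesh$dx) + 1
    j <- round(p[2] / mesh$dx) + 1
    stopifnot(i >= 1, i <= mesh$nx, j >= 1, j <= mesh$ny)
    node <- (j - 1) * mesh$nx + i
    act <- upstrokes_of(recording)
    tt <- act$t[act$node == node]
    if (!is.null(window)) tt <- tt[tt >= window[1] & tt <= window[2]]
    if (length(tt) == 0) {
      stop("no activation at point ", label, " (", p[1], ", ", p[2], ") cm")
    }
    if (length(tt) > 1) {
      stop("point ", label, " activates ", length(tt),
           " times in the window; narrow the window")
    }
    list(node = node, t = tt, xy = c((i - 1) * mesh$dx, (j - 1) * mesh$dx))
  }
  a <- locate(point_a, "A")
  b <- locate(point_b, "B")
  dist <- sqrt(sum((a$xy - b$xy)^2))
  dt_ms <- abs(b$t - a$t)
  if (dt_ms == 0) stop("identical activation times; points too close")
  dist / dt_ms * 1000
}

#' Action potential duration of a voltage trace
#'
#' APD at repolarization `level` (e.g. 90): time between the upward and
#' downward crossings of `peak - level/100 * (peak - diastolic)` for the
#' last complete action potential, with linear interpolation between
#' samples.
#'
#' @param vm_trace Numeric vector of membrane potential, or data frame with
#'   columns `t`, `vm`.
#' @param level Repolarization level in percent.
#' @param dt Sample interval (ms) when `vm_trace` is a bare vector.
#' @return APD (ms).
#' @export
measure_apd <- function(vm_trace, level = 90, dt = NULL) {
  if (is.data.frame(vm_trace)) {
    tt <- vm_trace$t; vm <- vm_trace$vm
  } else {
    stopifnot(!is.null(dt))
    vm <- as.numeric(vm_trace); tt <- (seq_along(vm) - 1) * dt
  }
  dia <- min(vm); pk <- max(vm)
  if (pk - dia < 1) stop("no action potential in trace (amplitude < 1 mV)")
  vlev <- pk - level / 100 * (pk - dia)
  above <- vm > vlev
  up <- which(!above[-length(above)] & above[-1])
  down <- which(above[-length(above)] & !above[-1])
  if (!length(up)) stop("no complete action potential (no upstroke)")
  cross_t <- function(k) {
    # linear interpolation of the crossing between samples k and k+1
    tt[k] + (vlev - vm[k]) / (vm[k + 1] - vm[k]) * (tt[k + 1] - tt[k])
  }
  down <- down[down > min(up)]
  if (!length(down)) stop("no complete action potential (no repolarization)")
  d_last <- max(down)
  u_last <- max(up[up < d_last])
  cross_t(d_last) - cross_t(u_last)
}
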