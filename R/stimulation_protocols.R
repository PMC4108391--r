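# Threshold calibration, steady-state S1 pacing, the cross-field S1-S2
# reentry-induction protocol, episode classification, and the
# vulnerable-window scan.

#' Rasterize a rectangular stimulus region
#'
#' @param mesh A `cw_mesh`.
#' @param rect `c(x0, x1, y0, y1)` in cm (inclusive).
#' @return Integer node indices.
#' @export
region_nodes <- function(mesh, rect) {
  stopifnot(length(rect) == 4)
  xs <- (seq_len(mesh$nx) - 1) * mesh$dx
  ys <- (seq_len(mesh$ny) - 1) * mesh$dx
  eps <- 1e-9
  ii <- which(xs >= rect[1] - eps & xs <= rect[2] + eps)
  jj <- which(ys >= rect[3] - eps & ys <= rect[4] + eps)
  if (!length(ii) || !length(jj)) stop("stimulus region is empty after rasterization")
  as.integer(outer(ii, (jj - 1) * mesh$nx, `+`))
}

#' Edge-strip region (S1 electrode at the endocardial end)
#'
#' @param mesh A `cw_mesh`.
#' @param width_nodes Strip width in nodes (default 2, the minimal robust
#'   electrode).
#' @param side `"left"` (endocardial end for the default transmural axis).
#' @return `c(x0, x1, y0, y1)` rectangle in cm.
#' @export
edge_strip_region <- function(mesh, width_nodes = 2, side = c("left", "bottom")) {
  side <- match.arg(side)
  w <- (width_nodes - 1) * mesh$dx
  if (side == "left") c(0, w, 0, mesh$ly) else c(0, mesh$lx, 0, w)
}

#' Cross-field S2 region (endocardial bottom-left corner)
#'
#' The premature stimulus covers the bottom-left corner: 1.25 cm wide by
#' 2.5 cm high at full scale, scaled proportionally for smaller sheets.
#'
#' @param mesh A `cw_mesh`.
#' @return `c(x0, x1, y0, y1)` rectangle in cm.
#' @export
s2_corner_region <- function(mesh) {
  c(0, mesh$lx * 1.25 / 5, 0, mesh$ly * 2.5 / 5)
}

#' Build a stimulus specification
#'
#' @param mesh A `cw_mesh`.
#' @param region `c(x0, x1, y0, y1)` rectangle (cm) or an integer node set.
#' @param amplitude Current density (A/F).
#' @param duration Pulse duration (ms).
#' @param onsets Onset times (ms).
#' @param label Free-text tag kept in the provenance log.
#' @return A `cw_stimulus` specification.
#' @export
make_stimulus <- function(mesh, region, amplitude, duration = 2, onsets = 0,
                          label = "stim") {
  stopifnot(duration > 0, amplitude > 0)
  nodes <- if (is.numeric(region) && length(region) == 4 && !is.integer(region)) {
    region_nodes(mesh, region)
  } else {
    as.integer(region)
  }
  structure(list(nodes = nodes, amplitude = amplitude, duration = duration,
                 onsets = onsets, label = label),
            class = "cw_stimulus")
}

#' Diastolic excitation threshold of a tissue region
#'
#' Bisection (to within 5%) on the minimal current density applied over
#' `region` for `duration` ms that elicits a propagated response at least
#' `min_distance` cm away from the region.
#'
#' @param tissue A resting `cw_tissue`.
#' @param region Stimulus rectangle (cm) or node set.
#' @param duration Pulse duration (ms).
#' @param min_distance Propagation distance defining capture (cm).
#' @param observe_ms Observation window per probe run (ms).
#' @param dt Integration step (ms).
#' @param upper Initial upper bracket (A/F).
#' @return Threshold amplitude (A/F).
#' @export
find_threshold <- function(tissue, region, duration = 2, min_distance = 1,
                           observe_ms = 80, dt = 0.002, upper = 20) {
  mesh <- tissue$node_map$mesh
  nodes <- if (length(region) == 4 && !is.integer(region)) {
    region_nodes(mesh, region)
  } else as.integer(region)
  # myocyte probe nodes at least min_distance from the region
  xy <- node_xy(mesh)
  rx <- range(xy$x[nodes]); ry <- range(xy$y[nodes])
  ddx <- pmax(rx[1] - xy$x, 0, xy$x - rx[2])
  ddy <- pmax(ry[1] - xy$y, 0, xy$y - ry[2])
  far <- which(sqrt(ddx^2 + ddy^2) >= min_distance &
                 as.integer(tissue$node_map$kind) != 2L)
  if (!length(far)) stop("no myocyte node at least ", min_distance,
                         " cm from the region")
  captures <- function(amp) {
    stim <- make_stimulus(mesh, nodes, amp, duration, onsets = tissue$state$t,
                          label = "probe")
    out <- run_tissue(tissue, list(stim), duration = observe_ms, dt = dt,
                      sample_dt = 0, record_frames = FALSE)
    any(out$tissue$state$act_last[far] > tissue$state$t)
  }
  hi <- upper
  while (!captures(hi)) {
    hi <- hi * 2
    if (hi > 64 * upper) {
      stop("inexcitable configuration: no propagated capture at ", hi / 2, " A/F")
    }
  }
  lo <- 0
  while ((hi - lo) / hi > 0.05) {
    mid <- (hi + lo) / 2
    if (captures(mid)) hi <- mid else lo <- mid
  }
  hi
}

node_xy <- function(mesh) {
  i <- rep(seq_len(mesh$nx), mesh$ny)
  j <- rep(seq_len(mesh$ny), each = mesh$nx)
  list(x = (i - 1) * mesh$dx, y = (j - 1) * mesh$dx)
}

#' Pace a tissue with S1 stimuli up to the onset of the last beat
#'
#' Applies `n_s1 - 1` full cycles so that the returned tissue sits exactly
#' at the onset time of the final S1 stimulus; [run_s1s2()] then applies
#' that last S1 and the premature S2. The returned checkpoint is reused
#' across a whole coupling-interval scan.
#'
#' @param tissue A `cw_tissue` at rest.
#' @param s1 A `cw_stimulus` for the S1 electrode (onsets ignored).
#' @param n_s1 Number of S1 beats in the full protocol.
#' @param bcl Basic cycle length (ms).
#' @param dt Integration step (ms).
#' @return The pre-paced `cw_tissue`.
#' @export
prepace_tissue <- function(tissue, s1, n_s1 = 5, bcl = 1000, dt = 0.002) {
  stopifnot(n_s1 >= 1)
  if (n_s1 == 1) return(tissue)
  t0 <- tissue$state$t
  s1run <- s1
  s1run$onsets <- t0 + (seq_len(n_s1 - 1) - 1) * bcl
  run_tissue(tissue, list(s1run), duration = (n_s1 - 1) * bcl, dt = dt,
             sample_dt = 0, record_frames = FALSE)$tissue
}

#' Run one cross-field S1-S2 episode
#'
#' From a pre-paced tissue (see [prepace_tissue()]), applies the final S1
#' at the current time and the premature S2 after the coupling interval,
#' then observes the sheet and classifies the outcome:
#' `no_capture` (S2 elicits no propagated activation),
#' `reentry` (at least two spiral-wave rotations),
#' `full_propagation` (the S2 wave activates most of the excitable sheet
#' and extinguishes), or `block_no_reentry` otherwise.
#'
#' @param tissue A pre-paced `cw_tissue`.
#' @param ci Coupling interval, onset of last S1 to onset of S2 (ms).
#' @param s1_spec,s2_spec `cw_stimulus` specifications (onsets ignored).
#' @param observe_ms Observation window after S2 (ms).
#' @param dt Integration step (ms).
#' @param sample_dt Frame interval for the analysis movie (ms).
#' @param full_prop_frac Fraction of non-S2 myocyte nodes that must
#'   activate after S2 for `full_propagation`.
#' @param min_peak Minimum peak Vm for an activation to count toward
#'   rotations (suppresses electrotonic deflections at high fibrosis).
#' @return List with `outcome` (a `cw_episode`: `ci`, `classification`,
#'   `n_rotations`, `notes`) and `recording`.
#' @export
run_s1s2 <- function(tissue, ci, s1_spec, s2_spec, observe_ms = 600,
                     dt = 0.002, sample_dt = 2, full_prop_frac = 0.75,
                     min_peak = 0) {
  t0 <- tissue$state$t
  s1 <- s1_spec; s1$onsets <- t0
  s2 <- s2_spec; s2$onsets <- t0 + ci
  out <- run_tissue(tissue, list(s1, s2), duration = ci + observe_ms,
                    dt = dt, sample_dt = sample_dt, record_frames = TRUE,
                    metadata = list(protocol = "S1S2 cross-field", ci = ci))
  rec <- out$recording
  t_s2 <- t0 + ci
  act <- rec$activation
  kind <- as.integer(tissue$node_map$kind)

  # capture: any new activation of an S2-region myocyte node shortly after S2
  s2_myo <- s2$nodes[kind[s2$nodes] != 2L]
  cap <- act$node %in% s2_myo & act$t >= t_s2 & act$t <= t_s2 + s2$duration + 30
  classification <- "no_capture"
  n_rot <- 0
  if (any(cap)) {
    n_rot <- count_rotations(rec, window = c(t_s2 + 1, t0 + ci + observe_ms),
                             min_peak = min_peak)
    if (n_rot >= 2) {
      classification <- "reentry"
    } else {
      myo_out <- setdiff(which(kind != 2L), s2$nodes)
      frac <- mean(myo_out %in% act$node[act$t > t_s2])
      classification <- if (frac >= full_prop_frac) "full_propagation"
                        else "block_no_reentry"
    }
  }
  outcome <- structure(list(ci = ci, classification = classification,
                            n_rotations = n_rot,
                            notes = sprintf("t_s2 = %g ms", t_s2)),
                       class = "cw_episode")
  list(outcome = outcome, recording = rec)
}

#' @export
print.cw_episode <- function(x, ...) {
  cat("<cw_episode> CI ", x$ci, " ms: ", x$classification,
      " (", signif(x$n_rotations, 3), " rotations)\n", sep = "")
  invisible(x)
}

#' Scan the vulnerable window for reentry
#'
#' Runs [run_s1s2()] for each coupling interval in
#' `seq(ci_min, ci_max, by = step)`, reusing one pre-paced S1 checkpoint,
#' and aggregates the outcomes. The vulnerable window is the span of
#' coupling intervals yielding reentry (at least two spiral-wave
#' rotations): width = last - first + step when any reentry occurs, else 0.
#'
#' @param tissue A `cw_tissue` at rest (it will be pre-paced once).
#' @param ci_min,ci_max Scanned coupling-interval range (ms).
#' @param step Scan step (ms); 1 ms at full scale.
#' @param s1_spec,s2_spec Stimulus specifications; defaults are the 2-node
#'   left edge strip and the bottom-left corner rectangle, at twice the
#'   tissue's diastolic threshold.
#' @param n_s1 Number of S1 beats.
#' @param bcl Basic cycle length (ms).
#' @param observe_ms Post-S2 observation (ms).
#' @param dt Integration step (ms).
#' @param sample_dt Analysis frame interval (ms).
#' @param min_peak Activation amplitude criterion, see [run_s1s2()].
#' @param keep_recordings Keep per-episode recordings (memory-heavy).
#' @param progress Print one line per episode.
#' @return A `cw_vw_result`: data frame `outcomes` plus `vw_width` (ms),
#'   `vw_limits` (first/last reentrant CI or NULL), `scan_step`.
#' @export
scan_vulnerable_window <- function(tissue, ci_min, ci_max, step,
                                   s1_spec = NULL, s2_spec = NULL,
                                   n_s1 = 5, bcl = 1000, observe_ms = 600,
                                   dt = 0.002, sample_dt = 2, min_peak = 0,
                                   keep_recordings = FALSE, progress = FALSE) {
  stopifnot(ci_min < ci_max, step > 0)
  mesh <- tissue$node_map$mesh
  if (is.null(s1_spec) || is.null(s2_spec)) {
    thr <- find_threshold(tissue, edge_strip_region(mesh), dt = dt)
    if (is.null(s1_spec)) {
      s1_spec <- make_stimulus(mesh, edge_strip_region(mesh), 2 * thr,
                               label = "S1 endocardial edge")
    }
    if (is.null(s2_spec)) {
      s2_spec <- make_stimulus(mesh, s2_corner_region(mesh), 2 * thr,
                               label = "S2 cross-field corner")
    }
  }
  pre <- prepace_tissue(tissue, s1_spec, n_s1 = n_s1, bcl = bcl, dt = dt)
  cis <- seq(ci_min, ci_max, by = step)
  rows <- vector("list", length(cis))
  recs <- if (keep_recordings) vector("list", length(cis)) else NULL
  for (k in seq_along(cis)) {
    ep <- run_s1s2(pre, cis[k], s1_spec, s2_spec, observe_ms = observe_ms,
                   dt = dt, sample_dt = sample_dt, min_peak = min_peak)
    rows[[k]] <- data.frame(ci = cis[k],
                            classification = ep$outcome$classification,
                            n_rotations = ep$outcome$n_rotations)
    if (keep_recordings) recs[[k]] <- ep$recording
    if (progress) {
      message(sprintf("CI %g ms: %s (%.2f rotations)", cis[k],
                      ep$outcome$classification, ep$outcome$n_rotations))
    }
  }
  outcomes <- do.call(rbind, rows)
  vw_from_outcomes(outcomes, step, recordings = recs)
}

vw_from_outcomes <- function(outcomes, step, recordings = NULL) {
  re <- outcomes$ci[outcomes$classification == "reentry"]
  if (length(re)) {
    limits <- c(min(re), max(re))
    width <- limits[2] - limits[1] + step
  } else {
    limits <- NULL
    width <- 0
  }
  structure(list(outcomes = outcomes, vw_width = width, vw_limits = limits,
                 scan_step = step, recordings = recordings),
            class = "cw_vw_result")
}

#' @export
print.cw_vw_result <- function(x, ...) {
  cat("<cw_vw_result> VW ", x$vw_width, " ms",
      if (!is.null(x$vw_limits)) paste0(" [", x$vw_limits[1], "; ",
                                        x$vw_limits[2], "]"),
      " over ", nrow(x$outcomes), " coupling intervals (step ",
      x$scan_step, " ms)\n", sep = "")
  invisible(x)
}

#' Write a vulnerable-window scan to CSV
#' @param vw A `cw_vw_result`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_vw_csv <- function(vw, path) {
  write.csv(vw$outcomes, path, row.names = FALSE)
  invisible(path)
}
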