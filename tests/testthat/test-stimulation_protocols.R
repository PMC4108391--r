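# Threshold calibration, S1-S2 episode classification, vulnerable-window
# aggregation.

test_that("threshold bisection brackets the excitation threshold", {
  tis <- tiny_cable(lx = 1.2, dx = 0.01)
  mesh <- tis$node_map$mesh
  region <- edge_strip_region(mesh)
  thr <- find_threshold(tis, region, dt = 0.005)
  expect_gt(thr, 0)

  run_amp <- function(amp) {
    s <- make_stimulus(mesh, region, amp, label = "probe")
    out <- run_tissue(tis, list(s), duration = 60, dt = 0.005, sample_dt = 0,
                      record_frames = FALSE)
    far <- which(cardiowave:::node_xy(mesh)$x >= 1)
    any(out$tissue$state$act_last[far] > 0)
  }
  expect_true(run_amp(2 * thr))    # doubling always captures
  expect_false(run_amp(0.5 * thr)) # halving never does
})

test_that("hundred-fold uncoupling blocks propagation in the fibrotic
           failing tissue regardless of amplitude", {
  # the mild-fibrosis-2 configuration of the uncoupling study: HF
  # remodeling, 28% fibroblasts, D reduced one-hundred-fold
  mesh <- build_mesh(1.2, 0.05, 0.01)
  nm <- assign_node_types(mesh, 0.28, seed = 7)
  df <- build_diffusion(nm, d_myo = 0.0013 * 0.5 * 0.01)
  tis <- make_tissue(nm, df, "HF")
  for (amp in c(60, 360)) {
    s <- make_stimulus(mesh, edge_strip_region(mesh), amp, label = "S")
    out <- run_tissue(tis, list(s), duration = 400, dt = 0.005,
                      sample_dt = 0, record_frames = FALSE)
    al <- matrix(out$tissue$state$act_last, mesh$nx, mesh$ny)
    reach <- max(c(0, which(apply(al > 0, 1, any)))) * mesh$dx
    expect_lt(reach, 0.5)
  }
})

test_that("vulnerable-window aggregation follows its invariants", {
  mk <- function(ci, cls) data.frame(ci = ci, classification = cls,
                                     n_rotations = ifelse(cls == "reentry", 3, 0))
  out <- rbind(mk(200, "block_no_reentry"), mk(205, "reentry"),
               mk(210, "reentry"), mk(215, "full_propagation"))
  vw <- cardiowave:::vw_from_outcomes(out, step = 5)
  expect_equal(vw$vw_width, 210 - 205 + 5)
  expect_equal(vw$vw_limits, c(205, 210))

  none <- cardiowave:::vw_from_outcomes(
    rbind(mk(200, "no_capture"), mk(210, "full_propagation")), step = 10)
  expect_equal(none$vw_width, 0)
  expect_null(none$vw_limits)
})

test_that("S1-S2 episodes classify refractory block vs late full propagation", {
  tis <- tiny_sheet(lx = 0.8, dx = 0.02)
  mesh <- tis$node_map$mesh
  thr <- find_threshold(tis, edge_strip_region(mesh), dt = 0.01,
                        min_distance = 0.5, observe_ms = 40)
  s1 <- make_stimulus(mesh, edge_strip_region(mesh), 2 * thr, label = "S1")
  s2 <- make_stimulus(mesh, s2_corner_region(mesh), 2 * thr, label = "S2")

  # S2 far beyond recovery: complete propagation, no reentry on this
  # non-fibrotic sheet
  late <- run_s1s2(tis, ci = 420, s1_spec = s1, s2_spec = s2,
                   observe_ms = 250, dt = 0.01, sample_dt = 5)
  expect_equal(late$outcome$classification, "full_propagation")
  expect_lt(late$outcome$n_rotations, 2)

  # S2 deep inside the refractory period: no capture
  early <- run_s1s2(tis, ci = 120, s1_spec = s1, s2_spec = s2,
                    observe_ms = 150, dt = 0.01, sample_dt = 5)
  expect_equal(early$outcome$classification, "no_capture")
  # the episode invariant: reentry iff >= 2 rotations
  for (ep in list(late$outcome, early$outcome)) {
    expect_identical(ep$classification == "reentry", ep$n_rotations >= 2)
  }
})

test_that("stimulus regions rasterize as specified", {
  mesh <- build_mesh(1, 1, 0.02)
  expect_equal(edge_strip_region(mesh, width_nodes = 2), c(0, 0.02, 0, 1))
  expect_equal(s2_corner_region(mesh), c(0, 0.25, 0, 0.5))
  nodes <- region_nodes(mesh, c(0, 0.02, 0, 1))
  expect_length(nodes, 2 * mesh$ny)
  expect_error(region_nodes(mesh, c(2, 3, 2, 3)), "empty")
  # stimuli only ever inject into myocyte nodes (fibroblasts are not paced)
  nm <- assign_node_types(mesh, 1, seed = 1)
  df <- build_diffusion(nm)
  tis_fib <- make_tissue(nm, df, "NC")
  s <- make_stimulus(mesh, c(0, 1, 0, 1), 50, onsets = 0)
  out <- run_tissue(tis_fib, list(s), duration = 10, dt = 0.01,
                    sample_dt = 0, record_frames = FALSE)
  expect_lt(max(out$tissue$state$vm), -30)  # fibroblasts never paced to an AP
})
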