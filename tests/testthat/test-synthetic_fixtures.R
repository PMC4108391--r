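# Fixture round trips: analysis(generate(truth)) recovers the programmed
# ground truth.

test_that("plane-wave fixtures round-trip their speed", {
  mesh <- build_mesh(3, 0.04, 0.02)
  for (speed in c(50, 18)) {
    pw <- make_plane_wave(mesh, speed = speed)
    cv <- measure_cv(pw$recording, c(1, 0), c(2, 0))
    expect_equal(cv, speed, tolerance = 0.5 / 50)
  }
})

test_that("spiral fixtures round-trip period, rotations and tip location", {
  mesh <- build_mesh(2, 2, 0.02)
  for (period in c(240, 250)) {
    sp <- make_spiral(mesh, period = period, duration = 4 * period,
                      sample_dt = 2)
    hist <- dominant_period(sp$recording)
    expect_equal(hist$dominant_period, period)
    rot <- count_rotations(sp$recording)
    expect_equal(rot, sp$truth$rotations, tolerance = 0.2 / 4)
  }

  sp <- make_spiral(mesh, period = 200, duration = 800, sample_dt = 2)
  pm <- instantaneous_phase(sp$recording)
  # drop the edge frames where the analytic signal is distorted
  fr <- seq(40, length(pm$times) - 40)
  trajs <- track_tips(ps_events(pm, frames = fr))
  expect_gt(length(trajs), 0)
  main <- trajs[[1]]
  err <- sqrt((main$x - 1)^2 + (main$y - 1)^2)
  expect_lt(sqrt(mean(err^2)), 2 * mesh$dx)
})

test_that("a translating spiral core is followed within tolerance", {
  mesh <- build_mesh(2, 2, 0.02)
  core <- function(t) c(1 + 0.2 * cos(2 * pi * t / 800),
                        1 + 0.2 * sin(2 * pi * t / 800))
  sp <- make_spiral(mesh, period = 200, core = core, duration = 800,
                    sample_dt = 2)
  pm <- instantaneous_phase(sp$recording)
  fr <- seq(40, length(pm$times) - 40)
  trajs <- track_tips(ps_events(pm, frames = fr), max_jump = 0.3)
  # the programmed core may drop out of detection for isolated frames,
  # splitting the track; the top two segments must cover most of the window
  lens <- vapply(trajs, nrow, 1L)
  expect_gt(lens[1], length(fr) * 0.4)
  expect_gt(sum(head(lens, 2)), length(fr) * 0.8)
  main <- trajs[[1]]
  truth <- t(vapply(main$t, core, numeric(2)))
  err <- sqrt((main$x - truth[, 1])^2 + (main$y - truth[, 2])^2)
  expect_lt(sqrt(mean(err^2)), 2 * mesh$dx)
})

test_that("vortex phase fields place exactly the programmed charges", {
  mesh <- build_mesh(5, 5, 0.05)
  pf <- make_vortex_phase_field(mesh, data.frame(x = 2.5, y = 2.5, charge = 1))
  ps <- detect_phase_singularities(pf, mesh)
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$charge, 1L)

  pf0 <- make_vortex_phase_field(mesh, data.frame(x = numeric(0),
                                                  y = numeric(0),
                                                  charge = numeric(0)))
  expect_equal(nrow(detect_phase_singularities(pf0, mesh)), 0L)

  pf2 <- make_vortex_phase_field(mesh, data.frame(x = c(1, 4), y = c(1, 4),
                                                  charge = c(1, -1)))
  ps2 <- detect_phase_singularities(pf2, mesh)
  expect_equal(nrow(ps2), 2L)
  expect_equal(sum(ps2$charge), 0L)
})

test_that("presets encode the four named fibrosis configurations", {
  t1 <- preset("mild1", seed = 42, scale = 0.2, dx = 0.02)
  expect_equal(t1$node_map$p_f, 0.145)
  expect_equal(t1$condition, "HF")
  t1b <- preset("mild1", seed = 42, scale = 0.2, dx = 0.02)
  expect_identical(t1$node_map$kind, t1b$node_map$kind)
  expect_equal(preset("minimal", seed = 1, scale = 0.2, dx = 0.02)$node_map$p_f,
               0.04)
  expect_equal(preset("high", seed = 1, scale = 0.2, dx = 0.02)$node_map$p_f,
               0.40)
  expect_equal(preset("mild2", seed = 1, scale = 0.2, dx = 0.02)$node_map$p_f,
               0.28)
  expect_error(preset("none", seed = 1), "arg")
})
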