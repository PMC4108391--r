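# Hilbert phase, ring-sum singularity detection, tip tracking, period
# histograms, conduction velocity and APD measures.

test_that("instantaneous phase of a sinusoid advances linearly and is
           amplitude/offset invariant", {
  mesh <- build_mesh(0.05, 0.01, 0.01)
  T_ms <- 100
  tt <- seq(0, 1000, by = 1)
  v <- sin(2 * pi * tt / T_ms)
  frames <- matrix(rep(v, each = mesh$n_nodes), mesh$n_nodes, length(tt))
  rec <- new_recording(frames, tt, 1, mesh)
  ph <- instantaneous_phase(rec)$phases[1, ]
  expect_true(all(ph > -pi & ph <= pi))
  # unwrapped phase advances 2*pi per period, linear away from the edges
  mid <- 150:850
  unwrapped <- cumsum(c(ph[mid[1]],
                        cardiowave:::wrap_phase(diff(ph))[mid[-1] - 1]))
  fit <- lm(unwrapped ~ tt[mid])
  expect_equal(unname(coef(fit)[2]), 2 * pi / T_ms, tolerance = 1e-3)
  expect_lt(max(abs(residuals(fit))), 1e-2)

  rec2 <- new_recording(5 * frames + 7, tt, 1, mesh)
  ph2 <- instantaneous_phase(rec2)$phases[1, ]
  expect_equal(ph2, ph, tolerance = 1e-9)

  # constant node: phase 0 and flagged
  frames3 <- frames; frames3[2, ] <- -80
  pm3 <- instantaneous_phase(new_recording(frames3, tt, 1, mesh))
  expect_true(all(pm3$phases[2, ] == 0))
  expect_true(2 %in% pm3$flat_nodes)
})

test_that("a synthetic AP train wraps once per paced cycle", {
  tr <- make_ap_train(bcl = 1000, n_beats = 4, sample_dt = 1)
  mesh <- build_mesh(0.05, 0.01, 0.01)
  frames <- matrix(rep(tr$vm, each = mesh$n_nodes), mesh$n_nodes, nrow(tr))
  rec <- new_recording(frames, tr$t, 1, mesh)
  ph <- instantaneous_phase(rec)$phases[1, ]
  # net descending -pi -> pi wraps = paced beats (edge artifacts at the
  # window boundary appear as cancelling wrap pairs)
  wraps <- sum(diff(ph) < -pi) - sum(diff(ph) > pi)
  expect_equal(wraps, 4)
})

test_that("ring-sum singularity detection matches the ideal vortex and the
           brute-force oracle", {
  mesh <- build_mesh(1, 1, 0.01)  # 101 x 101
  pf <- make_vortex_phase_field(mesh, data.frame(x = 0.5, y = 0.5, charge = 1))
  ps <- detect_phase_singularities(pf, mesh)
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$charge, 1L)
  expect_lt(max(abs(c(ps$x, ps$y) - 0.5)), 0.011)

  # uniform and plane-gradient fields: no singularity
  flat <- matrix(0.3, mesh$nx, mesh$ny)
  expect_equal(nrow(detect_phase_singularities(flat, mesh)), 0L)
  xy <- expand.grid(x = 0:(mesh$nx - 1), y = 0:(mesh$ny - 1))
  grad <- matrix(cardiowave:::wrap_phase(0.05 * xy$x + 0.03 * xy$y),
                 mesh$nx, mesh$ny)
  expect_equal(nrow(detect_phase_singularities(grad, mesh)), 0L)

  # opposite-charge pair recovered with net charge 0, matching brute force
  m2 <- build_mesh(0.5, 0.5, 0.01)  # 51 x 51
  pf2 <- make_vortex_phase_field(m2, data.frame(x = c(0.1, 0.4),
                                                y = c(0.1, 0.4),
                                                charge = c(1, -1)))
  ps2 <- detect_phase_singularities(pf2, m2)
  expect_equal(nrow(ps2), 2L)
  expect_equal(sum(ps2$charge), 0L)
  expect_lt(min(abs(ps2$x - 0.1) + abs(ps2$y - 0.1)), 0.025)
  expect_lt(min(abs(ps2$x - 0.4) + abs(ps2$y - 0.4)), 0.025)

  brute <- brute_ring_sums(pf2)
  hits <- which(abs(abs(brute) - 2 * pi) < 1e-6, arr.ind = TRUE)
  interior <- hits[hits[, 1] > 1 & hits[, 1] < m2$nx - 1 &
                     hits[, 2] > 1 & hits[, 2] < m2$ny - 1, , drop = FALSE]
  expect_equal(nrow(interior), nrow(ps2))
  expect_setequal(paste(interior[, 1], interior[, 2]), paste(ps2$i, ps2$j))
})

test_that("ring sums of random smooth fields agree with brute force", {
  m <- build_mesh(0.2, 0.2, 0.01)  # 21 x 21
  set.seed(42)
  for (rep in 1:5) {
    base <- matrix(rnorm(9), 3, 3)
    big <- matrix(0, m$nx, m$ny)
    xs <- seq(1, 3, length.out = m$nx)
    for (jj in seq_len(m$ny)) {
      yv <- seq(1, 3, length.out = m$ny)[jj]
      big[, jj] <- apply(cbind(xs), 1, function(xv) {
        i0 <- floor(xv); j0 <- floor(yv)
        i1 <- min(i0 + 1, 3); j1 <- min(j0 + 1, 3)
        fx <- xv - i0; fy <- yv - j0
        (1 - fx) * (1 - fy) * base[i0, j0] + fx * (1 - fy) * base[i1, j0] +
          (1 - fx) * fy * base[i0, j1] + fx * fy * base[i1, j1]
      })
    }
    pf <- cardiowave:::wrap_phase(3 * big)
    ps <- detect_phase_singularities(pf, m)
    brute <- brute_ring_sums(pf)
    hits <- which(abs(abs(brute) - 2 * pi) < 1e-6, arr.ind = TRUE)
    interior <- hits[hits[, 1] > 1 & hits[, 1] < m$nx - 1 &
                       hits[, 2] > 1 & hits[, 2] < m$ny - 1, , drop = FALSE]
    expect_equal(nrow(ps), nrow(interior))
  }
})

test_that("tip tracking links stationary, moving and transient singularities", {
  mesh <- build_mesh(1, 1, 0.02)
  mk_ps <- function(frame, x, y, charge = 1L) {
    data.frame(frame = frame, t = frame - 1, i = round(x / 0.02),
               j = round(y / 0.02), x = x, y = y, charge = charge)
  }
  stationary <- do.call(rbind, lapply(1:10, function(f) mk_ps(f, 0.5, 0.5)))
  tr <- track_tips(stationary)
  expect_length(tr, 1)
  expect_equal(nrow(tr[[1]]), 10L)

  moving <- do.call(rbind, lapply(1:10, function(f) {
    mk_ps(f, 0.3 + 0.02 * f, 0.5)
  }))
  tr2 <- track_tips(moving, max_jump = 0.1)
  expect_length(tr2, 1)

  transient <- rbind(stationary,
                     mk_ps(5, 0.1, 0.1, charge = 1L),
                     mk_ps(5, 0.9, 0.9, charge = -1L))
  tr3 <- track_tips(transient)
  expect_length(tr3, 3)
  expect_equal(sort(vapply(tr3, nrow, 1L)), c(1L, 1L, 10L))

  # opposite charges never link
  pair <- rbind(mk_ps(1, 0.5, 0.5, 1L), mk_ps(2, 0.5, 0.5, -1L))
  expect_length(track_tips(pair), 2)
})

test_that("dominant period pools inter-upstroke intervals with ties toward
           the longer period", {
  mesh <- build_mesh(0.05, 0.01, 0.01)
  act <- data.frame(node = rep(1:6, each = 5),
                    t = as.vector(sapply(1:6, function(n) (0:4) * 1000)))
  rec <- new_recording(matrix(-80, mesh$n_nodes, 2), c(0, 1), 1, mesh,
                       activation = act)
  hist <- dominant_period(rec)
  expect_equal(hist$dominant_period, 1000)

  # tie: equal counts at 200 and 300 ms -> 300 wins
  act2 <- data.frame(node = c(1, 1, 2, 2), t = c(0, 200, 0, 300))
  rec2 <- new_recording(matrix(-80, mesh$n_nodes, 2), c(0, 1), 1, mesh,
                        activation = act2)
  expect_equal(dominant_period(rec2)$dominant_period, 300)

  rec3 <- new_recording(matrix(-80, mesh$n_nodes, 2), c(0, 1), 1, mesh,
                        activation = data.frame(node = 1L, t = 5))
  expect_error(dominant_period(rec3), "insufficient activity")
})

test_that("conduction velocity is recovered from plane-wave fixtures", {
  mesh <- build_mesh(3, 0.02, 0.02)
  pw50 <- make_plane_wave(mesh, speed = 50)
  expect_equal(measure_cv(pw50$recording, c(1, 0), c(2, 0)), 50,
               tolerance = 0.01)
  pw18 <- make_plane_wave(mesh, speed = 18)
  expect_equal(measure_cv(pw18$recording, c(1, 0), c(2, 0)), 18,
               tolerance = 0.011)
  expect_error(measure_cv(pw50$recording, c(1, 0), c(2, 0),
                          window = c(0, 1)), "no activation")
})

test_that("APD measurement matches closed forms", {
  # square pulse of width w gives APD ~ w at any level
  dt <- 0.1
  tt <- seq(0, 100, by = dt)
  vm <- ifelse(tt >= 20 & tt < 60, 20, -80)
  for (lev in c(30, 50, 90)) {
    expect_equal(measure_apd(data.frame(t = tt, vm = vm), level = lev), 40,
                 tolerance = 2 * dt / 40)
  }
  # triangle AP: linear repolarization from peak 20 to rest -80 over 100 ms
  tt2 <- seq(0, 150, by = dt)
  vtri <- ifelse(tt2 < 10, -80, ifelse(tt2 < 11, -80 + 100 * (tt2 - 10),
                                       pmax(20 - (tt2 - 11), -80)))
  apd90 <- measure_apd(data.frame(t = tt2, vm = vtri), level = 90)
  # V90 = -70: upward crossing at 10.1 ms, downward at 101 ms
  expect_equal(apd90, 90.9, tolerance = 0.02)
  expect_error(measure_apd(data.frame(t = tt, vm = rep(-80, length(tt)))),
               "no action potential")
})

test_that("plane waves carry no rotation; offline upstroke detection matches
           the programmed wave", {
  mesh <- build_mesh(1, 0.4, 0.02)
  pw <- make_plane_wave(mesh, speed = 30)
  expect_equal(count_rotations(pw$recording), 0)
  ps <- ps_events(instantaneous_phase(pw$recording))
  expect_equal(nrow(ps), 0L)
  act <- detect_upstrokes(pw$recording)
  expect_equal(nrow(act), mesh$n_nodes)
})
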