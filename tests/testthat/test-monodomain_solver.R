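# Diffusion operator and coupled reaction-diffusion stepping.

test_that("diffusion leaves uniform fields unchanged and conserves charge", {
  tis <- tiny_sheet(lx = 0.4, dx = 0.02, p_f = 0.3, seed = 3)
  df <- tis$diffusion
  nx <- tis$node_map$mesh$nx
  vm <- matrix(-80, nx, nx)
  out <- diffusion_step(vm, df, 0.02, 0.01)
  expect_equal(out, vm, tolerance = 1e-14)

  set.seed(1)
  vm2 <- matrix(rnorm(nx * nx, -60, 30), nx, nx)
  out2 <- diffusion_step(vm2, df, 0.02, 0.01, n_steps = 50)
  expect_lt(abs(sum(out2) - sum(vm2)) / abs(sum(vm2)), 1e-10)
})

test_that("1D Gaussian profile follows the heat-kernel solution", {
  mesh <- build_mesh(3, 0.01, 0.01)
  nm <- assign_node_types(mesh, 0, 1)
  df <- build_diffusion(nm, d_myo = 0.0013, anisotropy_ratio = 1)
  x <- (0:(mesh$nx - 1)) * 0.01
  s0 <- 0.05; D <- 0.0013; Tt <- 100
  v0 <- exp(-(x - 1.5)^2 / (2 * s0^2))
  out <- diffusion_step(matrix(rep(v0, 2), mesh$nx, 2), df, 0.01, 0.01,
                        n_steps = Tt / 0.01)
  s2 <- s0^2 + 2 * D * Tt
  vref <- s0 / sqrt(s2) * exp(-(x - 1.5)^2 / (2 * s2))
  expect_lt(sqrt(mean((out[, 1] - vref)^2)) / max(vref), 0.01)
})

test_that("the stability precondition is enforced with a useful message", {
  tis <- tiny_sheet(lx = 0.4, dx = 0.02)
  vm <- matrix(-80, 21, 21)
  expect_error(diffusion_step(vm, tis$diffusion, 0.02, 0.2),
               "unstable.*dx\\^2")
  expect_equal(stability_limit(tis$diffusion, 0.01), 0.01^2 / (2 * 0.0013))
})

test_that("resting tissue stays quiescent and dt = 0 is the identity", {
  tis <- tiny_cable(lx = 0.5, dx = 0.01)
  vm0 <- tis$state$vm
  out <- run_tissue(tis, list(), duration = 100, dt = 0.005, sample_dt = 0,
                    record_frames = FALSE)
  expect_lt(max(abs(out$tissue$state$vm - vm0)), 0.5)
  expect_equal(nrow(out$recording$activation), 0L)

  tis2 <- tissue_step(tis, dt = 0)
  expect_identical(tis2$state$vm, tis$state$vm)
})

test_that("an S1 stimulus launches a single wavefront that activates every
           node exactly once", {
  tis <- tiny_cable(lx = 0.5, dx = 0.01)
  mesh <- tis$node_map$mesh
  s1 <- make_stimulus(mesh, edge_strip_region(mesh), 60, label = "S1")
  out <- run_tissue(tis, list(s1), duration = 40, dt = 0.002, sample_dt = 1)
  act <- out$recording$activation
  expect_equal(sort(unique(act$node)), seq_len(mesh$n_nodes))
  expect_equal(nrow(act), mesh$n_nodes)
  # activation times increase left to right along the cable
  first_row <- act[match(seq_len(mesh$nx), act$node), ]
  expect_true(all(diff(first_row$t[order(first_row$node)]) >= 0))
  # frames equally spaced, metadata carries provenance
  expect_equal(unique(round(diff(out$recording$times), 9)), 1)
  expect_equal(out$recording$metadata$d_myo, 0.0013)
  expect_length(out$recording$metadata$stimulus_log, 1)
})

test_that("tissue runs are deterministic", {
  tis <- tiny_cable(lx = 0.4, dx = 0.02)
  mesh <- tis$node_map$mesh
  s1 <- make_stimulus(mesh, edge_strip_region(mesh), 60, label = "S1")
  a <- run_tissue(tis, list(s1), duration = 20, dt = 0.005, sample_dt = 1)
  b <- run_tissue(tis, list(s1), duration = 20, dt = 0.005, sample_dt = 1)
  expect_identical(a$recording$frames, b$recording$frames)
  expect_identical(a$tissue$state$myo_y, b$tissue$state$myo_y)
})
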