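# Single-cell electrophysiology: parameter resolution, resting stability,
# action-potential properties, HF remodeling, numerical robustness.

test_that("make_params resolves kinds, layers and conditions", {
  p <- make_params("myocyte", "endo", "NC")
  expect_s3_class(p, "cw_params")
  expect_true(all(p$scale == 1))

  # endo and epi NC differ only through the transient-outward split flag,
  # not through the override vector
  pe <- make_params("myocyte", "epi", "NC")
  expect_identical(p$scale, pe$scale)
  expect_identical(pe$layer, "epi")

  hf <- make_params("myocyte", "endo", "HF")
  tab <- default_hf_table()
  for (key in names(tab)) expect_equal(hf$scale[[key]], tab[[key]])
  expect_true(all(hf$scale[setdiff(names(hf$scale), names(tab))] == 1))

  expect_error(make_params("myocyte", "endo", "HF",
                           override_table = list(nope = 2)),
               "unknown override key 'nope'")
  expect_error(make_params("myocyte", "endo", "HF",
                           override_table = list(GNa = -1)),
               "positive")
  expect_error(make_params("fibroblast", layer = "endo"), "layer")
})

test_that("myocyte and fibroblast rest at their quiescent potentials", {
  p <- make_params("myocyte", "endo", "NC")
  r <- relax_cell(p, duration = 10000, dt = 0.01)
  st0 <- initial_state(p)
  # 10 s of zero-input stepping moves Vm by well under 0.5 mV from the
  # shipped initial state and the residual drift is tiny
  expect_lt(abs(r$state[["vm"]] - st0[["vm"]]), 0.5)
  expect_lt(r$drift, 1e-3)

  # one more step from the relaxed state barely moves Vm
  st1 <- step_cell(r$state, p, dt = 0.002)
  expect_lt(abs(st1[["vm"]] - r$state[["vm"]]) / 0.002, 1e-4)

  # fibroblast: depolarized rest, well above myocyte rest but below -40 mV
  pf <- make_params("fibroblast", condition = "NC")
  rf <- relax_cell(pf, duration = 10000, dt = 0.01)
  expect_gt(rf$state[["vm"]], -60)
  expect_lt(rf$state[["vm"]], -40)
  stf <- step_cell(rf$state, pf, dt = 0.002)
  expect_lt(abs(stf[["vm"]] - rf$state[["vm"]]) / 0.002, 1e-4)
})

test_that("zero step and state-shape guards behave", {
  p <- make_params("myocyte", "endo", "NC")
  st <- initial_state(p)
  expect_identical(step_cell(st, p, dt = 0), st)
  pf <- make_params("fibroblast", condition = "NC")
  expect_error(step_cell(st, pf, dt = 0.002), "inconsistent")
})

test_that("paced endo NC cell fires a physiological action potential", {
  p <- make_params("myocyte", "endo", "NC")
  pc <- pace_single_cell(p, bcl = 1000, n_beats = 3, dt = 0.002)
  expect_true(pc$captured)
  expect_gt(max(pc$last_beat$vm), 0)           # overshoot above 0 mV
  apd <- measure_apd(pc$last_beat, level = 90)
  expect_gt(apd, 200)
  expect_lt(apd, 400)
  # gates stay in [0, 1], concentrations stay positive
  gates <- pc$state[c("m", "h", "j", "d", "f", "xtos", "ytos", "xtof",
                      "ytof", "xkr", "xks", "mL", "hL")]
  expect_true(all(gates >= 0 & gates <= 1))
  conc <- pc$state[c("Naj", "Nasl", "Nai", "Ki", "Caj", "Casl", "Cai", "Casr")]
  expect_true(all(conc > 0))
})

test_that("subthreshold stimulation is flagged, not an error", {
  p <- make_params("myocyte", "endo", "NC")
  thr <- find_cell_threshold(p)
  expect_warning(
    pc <- pace_single_cell(p, bcl = 500, n_beats = 1,
                           stim_amplitude = 0.5 * thr, dt = 0.002),
    "no action potential")
  expect_false(pc$captured)
  expect_lt(max(pc$last_beat$vm), 0)
})

test_that("HF overrides of 1 reproduce NC bit-for-bit; the default HF table
           prolongs the action potential", {
  nc <- make_params("myocyte", "endo", "NC")
  hf1 <- make_params("myocyte", "endo", "HF", override_table = list(GNaL = 1))
  st <- initial_state(nc)
  a <- step_cell(st, nc, dt = 0.002, n_steps = 500)
  b <- step_cell(st, hf1, dt = 0.002, n_steps = 500)
  expect_identical(unname(a), unname(b))

  hf <- make_params("myocyte", "endo", "HF")
  pc_nc <- pace_single_cell(nc, bcl = 1000, n_beats = 3, dt = 0.002)
  pc_hf <- pace_single_cell(hf, bcl = 1000, n_beats = 3, dt = 0.002)
  expect_gt(measure_apd(pc_hf$last_beat), measure_apd(pc_nc$last_beat))
})

test_that("halving the time step changes APD90 by less than 1 ms and the
           lookup tables agree with exact rate evaluation", {
  p <- make_params("myocyte", "endo", "NC")
  amp <- 2 * find_cell_threshold(p)
  pc1 <- pace_single_cell(p, bcl = 600, n_beats = 2, stim_amplitude = amp,
                          dt = 0.002, record_dt = 0.1)
  pc2 <- pace_single_cell(p, bcl = 600, n_beats = 2, stim_amplitude = amp,
                          dt = 0.001, record_dt = 0.1)
  expect_lt(abs(measure_apd(pc1$last_beat) - measure_apd(pc2$last_beat)), 1)

  # one table-driven step vs one closed-form step from a plateau state
  st <- initial_state(p)
  st[["vm"]] <- 10
  lut <- step_cell(st, p, dt = 0.002)
  exact <- step_cell(st, p, dt = 0.002, exact = TRUE)
  expect_lt(max(abs(lut - exact)), 1e-6)
})
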