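# Mesh arithmetic, random fibroblast placement, and the element-wise
# diffusion assignment rule.

test_that("mesh arithmetic matches hand counts and rejects bad extents", {
  m <- build_mesh(1, 1, 0.5)
  expect_equal(c(m$nx, m$ny), c(3L, 3L))
  expect_equal(m$n_nodes, 9L)
  expect_equal(m$n_elements, 4L)
  expect_error(build_mesh(5, 5, 0.03), "not an integer multiple")
})

test_that("node-type assignment honors p_f limits and the endo/epi split", {
  m <- build_mesh(1, 1, 0.02)  # 51 x 51
  nm0 <- assign_node_types(m, 0, seed = 7)
  expect_equal(sum(nm0$kind == 2L), 0L)
  # odd nx: extra column endocardial
  expect_equal(sum(nm0$kind == 0L), 26L * 51L)
  expect_equal(sum(nm0$kind == 1L), 25L * 51L)

  nm1 <- assign_node_types(m, 1, seed = 7)
  expect_true(all(nm1$kind == 2L))
  expect_equal(nm1$realized_fraction, 1)
})

test_that("fibroblast counts are binomial and reproducible", {
  m <- build_mesh(5, 5, 0.01)  # full-scale grid
  nm <- assign_node_types(m, 0.145, seed = 42)
  n <- m$n_nodes
  expect_equal(n, 251001L)
  mu <- n * 0.145
  sdev <- sqrt(n * 0.145 * 0.855)
  expect_lt(abs(sum(nm$kind == 2L) - mu), 4 * sdev)

  nm2 <- assign_node_types(m, 0.145, seed = 42)
  expect_identical(nm$kind, nm2$kind)

  # thinning: same seed, larger p gives a superset of fibroblast nodes
  m2 <- build_mesh(1, 1, 0.02)
  a <- assign_node_types(m2, 0.10, seed = 5)
  b <- assign_node_types(m2, 0.25, seed = 5)
  expect_true(all(b$kind[a$kind == 2L] == 2L))
})

test_that("diffusion assignment follows the any-fibroblast-corner rule", {
  m <- build_mesh(0.05, 0.05, 0.01)  # 6 x 6 nodes, 25 elements
  nm <- assign_node_types(m, 0, seed = 1)
  df <- build_diffusion(nm, d_myo = 0.0013, anisotropy_ratio = 4,
                        fib_factor = 1 / 3)
  expect_true(all(df$d_long == 0.0013))
  expect_true(all(df$d_trans == 0.0013 / 4))

  # one interior fibroblast node touches exactly 4 elements
  nm$kind[3, 3] <- 2L
  df1 <- build_diffusion(nm, d_myo = 0.0013, fib_factor = 1 / 3)
  expect_equal(sum(df1$d_long < 0.0013), 4L)
  expect_equal(unique(df1$d_long[df1$d_long < 0.0013]), 0.0013 / 3)
  # the four elements are those sharing node (3,3)
  expect_true(all(df1$d_long[2:3, 2:3] == 0.0013 / 3))

  # saturation
  nm$kind[] <- 2L
  dfa <- build_diffusion(nm, d_myo = 0.0013, fib_factor = 1 / 3)
  expect_true(all(dfa$d_long == 0.0013 / 3))
  expect_true(all(dfa$d_long >= dfa$d_trans) && all(dfa$d_trans > 0))
})

test_that("fibrotic element fraction matches 1-(1-p)^4 on interior elements", {
  m <- build_mesh(1, 1, 0.02)  # 51 x 51 nodes, 2500 elements
  p <- 0.08
  fr <- vapply(1:30, function(s) {
    nm <- assign_node_types(m, p, seed = s)
    mean(build_diffusion(nm)$d_long < 0.0013)
  }, numeric(1))
  expect_equal(mean(fr), 1 - (1 - p)^4, tolerance = 0.05)
})

test_that("fibrotic element count is monotone in p_f under thinning", {
  m <- build_mesh(1, 1, 0.02)
  counts <- sapply(c(0.02, 0.1, 0.25, 0.5), function(p) {
    build_diffusion(assign_node_types(m, p, seed = 11))$n_fibrotic
  })
  expect_true(all(diff(counts) >= 0))
})
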