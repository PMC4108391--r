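# shared builders for small test tissues

tiny_cable <- function(lx = 1.2, dx = 0.01, d_mult = 1, p_f = 0, seed = 1,
                       condition = "NC") {
  mesh <- build_mesh(lx, dx, dx)
  nm <- assign_node_types(mesh, p_f, seed)
  df <- build_diffusion(nm, d_myo = 0.0013 * d_mult)
  make_tissue(nm, df, condition)
}

tiny_sheet <- function(lx = 0.8, dx = 0.02, d_mult = 1, p_f = 0, seed = 1,
                       condition = "NC") {
  mesh <- build_mesh(lx, lx, dx)
  nm <- assign_node_types(mesh, p_f, seed)
  df <- build_diffusion(nm, d_myo = 0.0013 * d_mult)
  make_tissue(nm, df, condition)
}

# brute-force ring-sum oracle for phase-singularity detection
brute_ring_sums <- function(phase_frame) {
  nx <- nrow(phase_frame); ny <- ncol(phase_frame)
  wrap <- function(x) x - 2 * pi * ceiling((x - pi) / (2 * pi))
  out <- matrix(NA_real_, nx - 1, ny - 1)
  for (i in seq_len(nx - 1)) {
    for (j in seq_len(ny - 1)) {
      a <- phase_frame[i, j]; b <- phase_frame[i + 1, j]
      cc <- phase_frame[i + 1, j + 1]; d <- phase_frame[i, j + 1]
      out[i, j] <- wrap(b - a) + wrap(cc - b) + wrap(d - cc) + wrap(a - d)
    }
  }
  out
}
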