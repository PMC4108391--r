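# Discrete tissue construction: regular grid, endo/epi halves, random
# fibroblast placement, and the element-wise anisotropic diffusion field.

#' Build a regular 2D mesh
#'
#' Nodes sit at `(i*dx, j*dx)` (0-based, origin bottom-left); elements are
#' the squares between four neighboring nodes, indexed by their bottom-left
#' node.
#'
#' @param lx,ly Physical extents (cm); must be integer multiples of `dx`.
#'   `ly = 0` builds a one-dimensional cable (a single node row).
#' @param dx Node spacing (cm).
#' @return A `cw_mesh` with node counts `nx`, `ny`, spacing and extents.
#' @export
build_mesh <- function(lx, ly, dx) {
  stopifnot(dx > 0, lx > 0, ly >= 0)
  for (ext in c(x = lx, y = ly)) {
    k <- ext / dx
    if (abs(k - round(k)) > 1e-9 * k) {
      stop("extent ", ext, " cm is not an integer multiple of dx = ", dx,
           " cm (remainder ", signif((k - floor(k)) * dx, 6), " cm)")
    }
  }
  nx <- as.integer(round(lx / dx)) + 1L
  ny <- as.integer(round(ly / dx)) + 1L
  structure(list(nx = nx, ny = ny, dx = dx, lx = lx, ly = ly,
                 n_nodes = nx * ny,
                 n_elements = (nx - 1L) * max(ny - 1L, 1L)),
            class = "cw_mesh")
}

#' @export
print.cw_mesh <- function(x, ...) {
  cat("<cw_mesh> ", x$lx, " x ", x$ly, " cm, dx = ", x$dx, " cm: ",
      x$nx, " x ", x$ny, " nodes (", x$n_nodes, "), ",
      x$n_elements, " elements\n", sep = "")
  invisible(x)
}

#' Assign cell types to mesh nodes
#'
#' Each node is independently a fibroblast with probability `p_f`
#' (seeded Bernoulli draw); remaining myocyte nodes are split into
#' endocardial and epicardial halves along `transmural_axis` (first half
#' endo; with an odd node count the extra line is endocardial).
#'
#' @param mesh A `cw_mesh`.
#' @param p_f Fibroblast fraction in \[0, 1\].
#' @param seed RNG seed (integer).
#' @param transmural_axis `"x"` (default: the S1 wave travels endo->epi
#'   along the horizontal fiber axis) or `"y"`.
#' @return A `cw_node_map` with per-node labels (`"endo_myocyte"`,
#'   `"epi_myocyte"`, `"fibroblast"`) stored as an integer matrix
#'   `kind` (`nx` x `ny`; 0 endo, 1 epi, 2 fibroblast).
#' @export
assign_node_types <- function(mesh, p_f, seed, transmural_axis = c("x", "y")) {
  stopifnot(inherits(mesh, "cw_mesh"), p_f >= 0, p_f <= 1)
  transmural_axis <- match.arg(transmural_axis)
  fib <- with_seed(seed, {
    matrix(runif(mesh$nx * mesh$ny) < p_f, mesh$nx, mesh$ny)
  })
  kind <- matrix(0L, mesh$nx, mesh$ny)
  if (transmural_axis == "x") {
    kind[seq_len(mesh$nx) > ceiling(mesh$nx / 2), ] <- 1L
  } else {
    kind[, seq_len(mesh$ny) > ceiling(mesh$ny / 2)] <- 1L
  }
  kind[fib] <- 2L
  structure(list(mesh = mesh, kind = kind, p_f = p_f, seed = seed,
                 transmural_axis = transmural_axis,
                 realized_fraction = mean(kind == 2L)),
            class = "cw_node_map")
}

#' @export
print.cw_node_map <- function(x, ...) {
  cat("<cw_node_map> ", x$mesh$nx, " x ", x$mesh$ny,
      " nodes; requested P_f = ", x$p_f, ", realized ",
      signif(x$realized_fraction, 4), " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# run code under a local, restorable RNG state; the seed promise must be
# forced before the state snapshot or a seed drawn from the global RNG
# would be rewound on exit
with_seed <- function(seed, expr) {
  force(seed)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Build the element-wise anisotropic diffusion field
#'
#' Elements whose four corner nodes all run the myocyte model receive the
#' myocyte diffusion coefficient `d_myo` longitudinally and
#' `d_myo / anisotropy_ratio` transversally. An element with one or more
#' fibroblast corner nodes receives the fibrotic coefficient
#' `d_myo * fib_factor` (same anisotropy ratio). The fiber (longitudinal)
#' axis is horizontal.
#'
#' @param node_map A `cw_node_map`.
#' @param d_myo Myocyte diffusion coefficient (cm^2/ms); the normal value
#'   is 0.0013. Heart-failure intercellular uncoupling is expressed as an
#'   independent multiplier on `d_myo` before calling this (0.5 for the
#'   50% reduction between failing myocytes, 0.1 for the ten-fold case).
#' @param anisotropy_ratio Longitudinal-to-transverse conductance ratio
#'   (>= 1); default 4.
#' @param fib_factor Multiplier for fibrotic elements (default 1/3, the
#'   three-fold reduction between fibroblasts and for myocyte-fibroblast
#'   interaction). Applied to the possibly already-uncoupling-scaled
#'   `d_myo`.
#' @return A `cw_diffusion` with element matrices `d_long`, `d_trans`
#'   (`(nx-1)` x `(ny-1)`, or `(nx-1)` x 1 for a 1D cable).
#' @export
build_diffusion <- function(node_map, d_myo = 0.0013, anisotropy_ratio = 4,
                            fib_factor = 1 / 3) {
  stopifnot(inherits(node_map, "cw_node_map"), d_myo > 0,
            anisotropy_ratio >= 1, fib_factor > 0, fib_factor <= 1)
  mesh <- node_map$mesh
  ex <- mesh$nx - 1L
  ey <- max(mesh$ny - 1L, 1L)
  fib <- node_map$kind == 2L
  if (mesh$ny == 1L) {
    fib_elem <- fib[seq_len(ex), 1, drop = FALSE] | fib[seq_len(ex) + 1L, 1, drop = FALSE]
    fib_elem <- matrix(fib_elem, ex, 1)
  } else {
    i <- seq_len(ex); j <- seq_len(ey)
    fib_elem <- fib[i, j, drop = FALSE] | fib[i + 1L, j, drop = FALSE] |
      fib[i, j + 1L, drop = FALSE] | fib[i + 1L, j + 1L, drop = FALSE]
  }
  d_long <- matrix(d_myo, ex, ey)
  d_long[fib_elem] <- d_myo * fib_factor
  structure(list(d_long = d_long, d_trans = d_long / anisotropy_ratio,
                 fiber_axis = "horizontal", d_myo = d_myo,
                 anisotropy_ratio = anisotropy_ratio, fib_factor = fib_factor,
                 n_fibrotic = sum(fib_elem)),
            class = "cw_diffusion")
}

#' @export
print.cw_diffusion <- function(x, ...) {
  cat("<cw_diffusion> ", nrow(x$d_long), " x ", ncol(x$d_long),
      " elements; d_myo = ", x$d_myo, " cm^2/ms, ratio ",
      x$anisotropy_ratio, "; ", x$n_fibrotic, " fibrotic elements\n", sep = "")
  invisible(x)
}

#' Assemble a ready-to-simulate tissue bundle
#'
#' Combines the node map and diffusion field with resolved cell parameter
#' sets and initializes every node at its cell type's quiescent state.
#'
#' @param node_map A `cw_node_map`.
#' @param diffusion A `cw_diffusion` built from the same map.
#' @param condition `"NC"` or `"HF"` (myocyte ionic remodeling).
#' @param override_table Optional HF override table (default
#'   [default_hf_table()]).
#' @return A `cw_tissue`: node map, diffusion field, parameter sets and the
#'   per-node state (myocyte and fibroblast pools).
#' @export
make_tissue <- function(node_map, diffusion, condition = c("NC", "HF"),
                        override_table = NULL) {
  condition <- match.arg(condition)
  stopifnot(inherits(node_map, "cw_node_map"), inherits(diffusion, "cw_diffusion"))
  p_endo <- make_params("myocyte", "endo", condition, override_table)
  p_epi <- make_params("myocyte", "epi", condition, override_table)
  p_fib <- make_params("fibroblast", condition = "NC")
  kind <- as.integer(node_map$kind)
  n_myo <- sum(kind != 2L)
  n_fib <- sum(kind == 2L)

  rs_endo <- resting_state(p_endo)
  rs_epi <- resting_state(p_epi)
  rs_fib <- resting_state(p_fib)

  vm <- numeric(length(kind))
  myo_y <- matrix(0, n_myo, 40)
  fib_y <- matrix(0, n_fib, 2)
  myo_kind <- kind[kind != 2L]
  vm[kind != 2L] <- ifelse(myo_kind == 0L, rs_endo[[1]], rs_epi[[1]])
  vm[kind == 2L] <- rs_fib[[1]]
  if (n_myo) {
    myo_y[myo_kind == 0L, ] <- matrix(rs_endo[-1], sum(myo_kind == 0L), 40,
                                      byrow = TRUE)
    if (any(myo_kind == 1L)) {
      myo_y[myo_kind == 1L, ] <- matrix(rs_epi[-1], sum(myo_kind == 1L), 40,
                                        byrow = TRUE)
    }
  }
  if (n_fib) fib_y[] <- matrix(rs_fib[-1], n_fib, 2, byrow = TRUE)

  structure(list(node_map = node_map, diffusion = diffusion,
                 condition = condition,
                 params = list(endo = p_endo, epi = p_epi, fib = p_fib),
                 state = list(vm = vm, myo_y = myo_y, fib_y = fib_y, t = 0,
                              act_last = NULL)),
            class = "cw_tissue")
}

#' @export
print.cw_tissue <- function(x, ...) {
  cat("<cw_tissue> ", x$condition, " condition; ", sep = "")
  print(x$node_map)
  invisible(x)
}
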