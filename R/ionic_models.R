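# Single-cell electrophysiology: GPB human ventricular myocyte (endo/epi,
# with late sodium current) and MacCannell active fibroblast, exposed as
# fixed-step state-update operations.

#' Default heart-failure ionic remodeling table
#'
#' Multiplicative overrides applied to the normal (NC) myocyte model to
#' obtain the failing (HF) phenotype. The factors follow the heart-failure
#' remodeling used with this myocyte model in the failing-human-ventricle
#' simulation literature (upregulated late sodium current and Na/Ca
#' exchanger; downregulated transient outward current, inward rectifier,
#' Na/K pump and SERCA; increased SR calcium leak). The table is plain
#' configuration: pass a modified copy (or a YAML/JSON file via
#' [read_override_table()]) to [make_params()] to change the phenotype.
#'
#' @return Named list of multiplicative factors.
#' @export
default_hf_table <- function() {
  list(
    GNaL = 2.0,      # late Na+ current doubled
    Gto = 0.6,       # transient outward reduced 40%
    GK1 = 0.68,      # inward rectifier reduced 32%
    IbarNaK = 0.58,  # Na/K pump reduced 42%
    IbarNCX = 1.65,  # Na/Ca exchanger upregulated 65%
    Vmax_SERCA = 0.54,  # SR Ca uptake reduced 46%
    SR_leak = 2.0    # SR Ca leak doubled
  )
}

#' Read a parameter override table from YAML or JSON
#'
#' @param path File with a flat mapping `parameter_name: factor`.
#' @return Named list of factors.
#' @export
read_override_table <- function(path) {
  tab <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as.list(tab)
}

#' Known myocyte override parameter names
#' @return Character vector of valid override keys for myocyte parameters.
#' @export
override_names <- function() as.character(cw_ov_names())

fib_override_names <- c("GKv", "GK1_f", "GbNa", "INaKmax_f")

#' Build a resolved cell parameter set
#'
#' Resolves a cell kind, transmural layer and condition into the full
#' parameter set used by the steppers. `condition = "NC"` keeps the
#' published model values (all override factors 1); `condition = "HF"`
#' applies `override_table` (default [default_hf_table()]) on top.
#'
#' @param cell_kind `"myocyte"` or `"fibroblast"`.
#' @param layer `"endo"` or `"epi"`; myocytes only.
#' @param condition `"NC"` or `"HF"`.
#' @param override_table Named list of multiplicative factors; keys must be
#'   in [override_names()] (myocyte) or the fibroblast set. Only consulted
#'   for `condition = "HF"`.
#' @return An object of class `cw_params`.
#' @export
make_params <- function(cell_kind = c("myocyte", "fibroblast"),
                        layer = c("endo", "epi"),
                        condition = c("NC", "HF"),
                        override_table = NULL) {
  cell_kind <- match.arg(cell_kind)
  condition <- match.arg(condition)
  if (cell_kind == "myocyte") {
    layer <- match.arg(layer)
  } else {
    if (!missing(layer)) stop("'layer' is defined only for myocytes")
    layer <- NA_character_
  }
  if (condition == "HF" && is.null(override_table)) {
    override_table <- if (cell_kind == "myocyte") default_hf_table() else list()
  }
  if (condition == "NC" && length(override_table)) {
    stop("condition 'NC' implies all override factors 1; drop the table or use 'HF'")
  }

  known <- if (cell_kind == "myocyte") override_names() else fib_override_names
  scale <- stats::setNames(rep(1, length(known)), known)
  for (key in names(override_table)) {
    if (!key %in% known) stop("unknown override key '", key, "'")
    fac <- override_table[[key]]
    if (!is.numeric(fac) || length(fac) != 1 || !is.finite(fac) || fac <= 0) {
      stop("override factor for '", key, "' must be a positive number")
    }
    scale[[key]] <- fac
  }

  structure(
    list(
      cell_kind = cell_kind,
      layer = layer,
      condition = condition,
      scale = scale,
      override_table = override_table,
      # book-keeping only: the tissue solver works directly in diffusion-
      # coefficient form, these document the monodomain scaling constants
      membrane_capacitance = if (cell_kind == "myocyte") 138.1 else 6.3, # pF
      surface_to_volume = if (cell_kind == "myocyte") 0.2e6 else NA_real_ # 1/m
    ),
    class = "cw_params"
  )
}

#' @export
print.cw_params <- function(x, ...) {
  cat("<cw_params> ", x$cell_kind,
      if (!is.na(x$layer)) paste0(" (", x$layer, ")"), ", condition ",
      x$condition, "\n", sep = "")
  ov <- x$scale[x$scale != 1]
  if (length(ov)) {
    cat("  overrides:", paste(names(ov), signif(unlist(ov), 4), sep = " x ",
                              collapse = ", "), "\n")
  }
  invisible(x)
}

kind_code <- function(params) if (params$cell_kind == "myocyte") 0L else 1L
is_epi <- function(params) identical(params$layer, "epi")

#' Initial (resting) cell state
#'
#' Published resting state of the transcribed model; pass through
#' [relax_cell()] to land exactly on this implementation's quiescent point.
#'
#' @param params A `cw_params` object.
#' @return Numeric state vector; element 1 is the membrane potential (mV),
#'   the rest are gates (dimensionless) and concentrations (mM).
#' @export
initial_state <- function(params) {
  st <- cw_initial_state_cpp(kind_code(params))
  names(st) <- state_names(params)
  st
}

state_names <- function(params) {
  if (params$cell_kind == "myocyte") {
    c("vm", "m", "h", "j", "d", "f", "fcaBj", "fcaBsl",
      "xtos", "ytos", "xtof", "ytof", "xkr", "xks", "mL", "hL",
      "RyRr", "RyRo", "RyRi", "NaBj", "NaBsl",
      "TnCL", "TnCHc", "TnCHm", "CaM", "Myoc", "Myom", "SRB",
      "SLLj", "SLLsl", "SLHj", "SLHsl", "Csqnb",
      "Naj", "Nasl", "Nai", "Ki", "Caj", "Casl", "Cai", "Casr")
  } else {
    c("vm", "r", "s")
  }
}

#' Advance a single cell by one (or more) fixed time steps
#'
#' Voltage-dependent gates advance by Rush-Larsen (which keeps them in
#' \[0, 1\] by construction), linear buffer ODEs by exact exponential
#' updates, concentrations and membrane potential by forward Euler.
#'
#' @param state State vector as returned by [initial_state()].
#' @param params A `cw_params` object matching the state's cell kind.
#' @param dt Time step (ms); must be positive and at most 0.02 for the
#'   default scheme (`dt = 0` returns the state unchanged).
#' @param i_inject Injected stimulus current density (A/F), depolarizing
#'   when positive.
#' @param n_steps Number of steps to take.
#' @param exact Use closed-form rate evaluation instead of the lookup
#'   tables (slower; used for verification).
#' @return The advanced state vector.
#' @export
step_cell <- function(state, params, dt, i_inject = 0, n_steps = 1,
                      exact = FALSE) {
  if (dt == 0 || n_steps == 0) return(state)
  stopifnot(dt > 0)
  if (dt > 0.02) stop("dt must be <= 0.02 ms for the default explicit scheme")
  check_state(state, params)
  if (n_steps == 1) {
    out <- cw_cell_step_once(unname(state), kind_code(params), is_epi(params),
                             unname(params$scale), dt, i_inject, exact)
  } else {
    if (i_inject != 0) stop("use the pacing helpers for stimulated multi-step runs")
    out <- cw_cell_run(unname(state), kind_code(params), is_epi(params),
                       unname(params$scale), dt, dt * n_steps,
                       numeric(0), 0, 0, 0, exact, 0)$state
  }
  names(out) <- names(state)
  out
}

check_state <- function(state, params) {
  want <- if (params$cell_kind == "myocyte") 41L else 3L
  if (length(state) != want) {
    stop("state length ", length(state), " inconsistent with cell kind '",
         params$cell_kind, "' (expected ", want, ")")
  }
  invisible(TRUE)
}

#' Relax a cell to its quiescent steady state
#'
#' Integrates the unstimulated model for `duration` ms from `state`
#' (default: the shipped initial state).
#'
#' @inheritParams step_cell
#' @param duration Unstimulated integration time (ms).
#' @return List with `state` (the relaxed state) and `drift`
#'   (|dVm| over the final 1 ms, mV).
#' @export
relax_cell <- function(params, duration = 30000, dt = 0.01, state = NULL) {
  if (is.null(state)) state <- initial_state(params)
  out <- cw_cell_run(unname(state), kind_code(params), is_epi(params),
                     unname(params$scale), dt, duration,
                     numeric(0), 0, 0, min(1, duration), FALSE, 0)
  vm <- out$vm
  drift <- abs(diff(tail(vm, 2)))
  st <- out$state
  names(st) <- names(state)
  list(state = st, drift = drift)
}

# memoized relaxed states per (kind, layer, condition, overrides)
.cw_cache <- new.env(parent = emptyenv())

resting_state <- function(params, duration = 30000, dt = 0.01) {
  key <- paste0(params$cell_kind, "/", params$layer, "/", params$condition, "/",
                paste(signif(params$scale, 10), collapse = ","))
  if (!is.null(.cw_cache[[key]])) return(.cw_cache[[key]])
  st <- relax_cell(params, duration = duration, dt = dt)$state
  .cw_cache[[key]] <- st
  st
}

#' Diastolic excitation threshold of an isolated cell
#'
#' Minimal stimulus current density (A/F) of a pulse of the given duration
#' that elicits an action potential (peak above 0 mV), found by bisection
#' to within 5%.
#'
#' @param params A myocyte `cw_params`.
#' @param stim_duration Pulse duration (ms).
#' @param dt Integration step (ms).
#' @return Threshold amplitude (A/F).
#' @export
find_cell_threshold <- function(params, stim_duration = 2, dt = 0.002) {
  state <- resting_state(params)
  fires <- function(amp) {
    out <- cw_cell_run(unname(state), kind_code(params), is_epi(params),
                       unname(params$scale), dt, 30, 0, stim_duration, amp,
                       0.1, FALSE, 0)
    max(out$vm) > 0
  }
  hi <- 5
  while (!fires(hi)) {
    hi <- hi * 2
    if (hi > 640) stop("inexcitable configuration: no capture at ", hi / 2, " A/F")
  }
  lo <- 0
  while ((hi - lo) / hi > 0.05) {
    mid <- (hi + lo) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Pace an isolated cell to steady state
#'
#' Applies `n_beats` stimuli of `stim_duration` ms at the given basic cycle
#' length and returns the final state together with the sampled membrane
#' potential trace (electrophysiological properties are conventionally
#' measured on the last beat).
#'
#' @param params A `cw_params` object.
#' @param bcl Basic cycle length (ms).
#' @param n_beats Number of stimuli (>= 1).
#' @param stim_amplitude Stimulus amplitude (A/F); default twice the
#'   diastolic threshold of the cell.
#' @param stim_duration Stimulus duration (ms); must be below `bcl`.
#' @param dt Integration step (ms).
#' @param record_dt Trace sampling interval (ms).
#' @param from Optional starting state (default: relaxed resting state).
#' @return List with `state`, `t`, `vm` (full trace), `last_beat`
#'   (data.frame `t`, `vm` for the final cycle), `captured` (logical flag:
#'   FALSE when no AP was elicited) and `stim_amplitude`.
#' @export
pace_single_cell <- function(params, bcl = 1000, n_beats = 5,
                             stim_amplitude = NULL, stim_duration = 2,
                             dt = 0.002, record_dt = 0.5, from = NULL) {
  stopifnot(bcl > stim_duration, n_beats >= 1)
  if (is.null(stim_amplitude)) {
    stim_amplitude <- 2 * find_cell_threshold(params, stim_duration, dt = dt)
  }
  state <- if (is.null(from)) resting_state(params) else from
  onsets <- (seq_len(n_beats) - 1) * bcl
  out <- cw_cell_run(unname(state), kind_code(params), is_epi(params),
                     unname(params$scale), dt, n_beats * bcl,
                     onsets, stim_duration, stim_amplitude, record_dt, FALSE, 0)
  st <- out$state
  names(st) <- names(state)
  last <- out$t >= (n_beats - 1) * bcl
  last_beat <- data.frame(t = out$t[last] - (n_beats - 1) * bcl,
                          vm = out$vm[last])
  captured <- max(last_beat$vm) > 0
  if (!captured) {
    warning("no action potential elicited on the final beat (peak Vm ",
            signif(max(last_beat$vm), 3), " mV)")
  }
  list(state = st, t = out$t, vm = out$vm, last_beat = last_beat,
       captured = captured, stim_amplitude = stim_amplitude)
}
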