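---
title: "Modeling reentry vulnerability in fibrotic failing ventricular tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling reentry vulnerability in fibrotic failing ventricular tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Heart failure remodels ventricular tissue in three ways that matter for
arrhythmia: the ionic currents of the myocytes change (electrophysiological
remodeling), gap-junctional coupling between myocytes weakens (intercellular
uncoupling), and fibroblasts proliferate between myocytes (diffuse fibrosis).
`cardiowave` simulates a two-dimensional transmural sheet of human
ventricular tissue carrying all three ingredients and asks the classic
vulnerability question: over which range of coupling intervals does a
premature stimulus launch a sustained spiral wave (reentry)? The package
also provides the analysis toolkit used to characterize such episodes:
Hilbert-transform phase maps, ring-sum phase-singularity (PS) detection,
rotor-tip trajectories, and dominant-period histograms.

# Model

## Tissue equation

Membrane potential on the sheet obeys the monodomain reaction–diffusion
equation

$$\partial_t V_m \;=\; \nabla\!\cdot\!\big(\mathbf{D}\,\nabla V_m\big)\;-\;
I_{\mathrm{ion}}(V_m,\mathbf{y}) \;+\; I_{\mathrm{stim}},$$

with no-flux boundary conditions on all four edges. $\mathbf{D}$ is the
diagonal diffusion tensor (cm²/ms) with the fiber (longitudinal) axis
horizontal; $I_{\mathrm{ion}}$ is the total transmembrane current density
(A/F) of the local cell model and $\mathbf{y}$ its gating/concentration
state. The surface-to-volume ratio and membrane capacitance that appear in
conductivity-form monodomain formulations are absorbed into $\mathbf{D}$;
they are retained in `cw_params` for book-keeping only.

## Cell models

Myocyte nodes run the Grandi–Pasqualini–Bers (GPB) human ventricular model
(39 state variables per node as implemented: 15 gates, RyR triplet, Na⁺ and
Ca²⁺ buffers, internal Na⁺/Ca²⁺/SR pools), with endocardial and epicardial
variants differing in the transient-outward current split, plus a late
sodium current $I_{\mathrm{NaL}}$ (Luo–Rudy-style activation, 600-ms
inactivation) as used in failing-ventricle adaptations of the model.
Internal K⁺ is clamped at 120 mM, the model's convention at 1 Hz pacing.
Fibroblast nodes run the MacCannell *active* fibroblast model (time-dependent
K⁺ current with activation/inactivation, inward-rectifier K⁺ current, Na⁺/K⁺
pump, Na⁺ background; resting potential ≈ −49 mV). Both models work in
current densities (A/F), so the ~20-fold capacitance difference between a
fibroblast (6.3 pF) and a myocyte (138 pF) is carried by each model's own
current scaling and no extra geometric factor is applied.

Heart-failure ionic remodeling is expressed as a table of multiplicative
overrides on maximal conductances and fluxes (`default_hf_table()`):
$I_{\mathrm{NaL}}\times2$, $I_{\mathrm{to}}\times0.6$, $I_{K1}\times0.68$,
$I_{\mathrm{NaK}}\times0.58$, $I_{\mathrm{NCX}}\times1.65$,
SERCA $\times0.54$, SR leak $\times2$ — the consensus failing-phenotype
direction for this model family (reduced repolarization reserve, prolonged
APD). The table is configuration, not code: any YAML/JSON mapping of
parameter names to positive factors defines a phenotype, and every
simulation logs the resolved table into its provenance record.

## Fibrosis and the diffusion field

Fibroblast placement is node-wise i.i.d. Bernoulli at fraction `p_f`
(seeded, reproducible). The four named presets are `minimal` (4%), `mild1`
(14.5%), `mild2` (28%) and `high` (40%). Each square element (dx × dx, four
corner nodes) receives the myocyte coefficient `d_myo` longitudinally and
`d_myo / anisotropy_ratio` (default ratio 4) transversally; an element with
*any* fibroblast corner is fibrotic and its coefficients are multiplied by
`fib_factor` (default 1/3, the three-fold fibroblast-coupling reduction).
Intercellular uncoupling (0.5 between failing myocytes, 0.1 for the
ten-fold study, 0.01 for the block case) is an independent multiplier
applied to `d_myo` *before* the fibrotic factor, i.e. the multipliers
compose; this is a design choice (the alternative — fibrotic elements
always pinned to the normal D/3 — is not what the uncoupling study varies,
which scales "the diffusion coefficient" globally). The endo/epi halves
split along the horizontal fiber axis (the S1 wave travels endo→epi along
fibers; with an odd node count the extra column is endocardial); the axis
is configurable.

# Numerics

* **Operator splitting.** Lie splitting per time step: one ionic reaction
  step per node, then one diffusion step. Default `dt` = 0.002 ms
  (configurable; the explicit diffusion limit is `dx²/(2 max d_long)` ≈
  0.0385 ms at the default parameters, and the reaction stiffness allows up
  to ~0.01 ms).
* **Reaction integration.** Voltage-gated variables advance by Rush–Larsen
  (gate update toward its voltage-dependent steady state with factor
  $e^{-\Delta t/\tau}$, which keeps gates in [0, 1] by construction);
  buffer occupancies, whose ODEs are linear given the instantaneous free
  concentrations, advance by exact exponential updates (this removes the
  stiffest explicit mode, calsequestrin, from the stability budget);
  concentrations, RyR states and $V_m$ advance by forward Euler.
  Voltage-dependent rates come from lookup tables on a 0.02-mV grid with
  linear interpolation, built once per run; a closed-form path
  (`exact = TRUE`) is retained and agrees with the tables to <1e-6 per
  step, which the tests assert.
* **Diffusion.** Flux-conservative finite differences on the node grid:
  the flux through each node-to-node edge uses the mean of the diffusion
  coefficients of the (at most two) adjacent elements, so heterogeneous
  fields conserve total $V_m$ exactly and no-flux boundaries hold by
  construction. Axis-aligned anisotropy needs no cross-derivative terms.
  The operator is verified against the closed-form heat kernel.
* **Degenerate inputs.** `dt = 0` is the identity; constant-signal nodes
  get phase 0 and are flagged; a vortex core specified exactly on a node
  is nudged off-lattice by dx/200 in the fixture generator so its winding
  number is well defined.

# Stimulation protocols

Thresholds are measured, not assumed: bisection (to 5%) on the minimal
current density over the electrode region (2-ms pulses) that elicits a
response propagating ≥ 1 cm. S1 is a 2-node-wide strip on the endocardial
(left) edge at twice threshold; five S1 beats at BCL 1000 ms precede the
premature S2, a bottom-left corner rectangle (1.25 × 2.5 cm at full scale,
scaled proportionally). The coupling interval (CI) is measured onset of the
last S1 → onset of S2. Episodes classify as `no_capture`,
`full_propagation`, `block_no_reentry` or `reentry`; *reentry* requires at
least two spiral-wave rotations, operationalized as a tracked PS trajectory
accumulating > 4π of rotation, or ≥ 3 full-amplitude upstrokes (peak above
0 mV, which excludes the electrotonic deflections seen at 40% fibrosis) at
a probe node after S2. The vulnerable window is `last − first + step` over
the reentrant CIs. Stimuli inject only into myocyte nodes (pacing models
myocardial capture, and fibroblasts would otherwise act as spurious current
sources).

# Phase analysis

Per node the temporal mean is removed, the analytic signal is formed by the
FFT method, and instantaneous phase is `atan2(HT(v), v)` in (−π, π]. For
each interior element the four ring differences A→B→C→D (counter-clockwise)
are wrapped to (−π, π] and summed; the sum is exactly 0 or ±2π up to float
noise, so the 1e-6 tolerance is purely numerical. Elements touching the
tissue boundary are excluded (phase beyond the sheet is undefined).
Same-charge PSs in consecutive frames are linked greedily within 0.3 cm;
cycle-length histograms pool all inter-upstroke intervals rounded to 1 ms,
with modal ties broken toward the longer period because harmonics of the
true period land at shorter intervals.

# Synthetic fixtures

Every analysis stage is testable without PDE runs: plane waves with
programmed speed, Archimedean spirals with programmed period/core
path/charge, multi-vortex phase fields, and paced AP trains, all built from
a stylized AP pulse (1-ms linear upstroke, plateau, cosine repolarization)
that is deliberately independent of the ionic models under test. The module
contract is the round trip: `analysis(generate(truth)) ≈ truth`. What these
fixtures do *not* emulate: measurement noise, baseline drift, or the
amplitude heterogeneity of real optical-mapping data — passing fixture
tests demonstrates correctness of the analysis algebra, not robustness to
experimental artifacts.

# Problem sizes used by the test and acceptance runs

The full-scale study (5 × 5 cm, 251 001 nodes, five 1000-ms S1 cycles per
episode, 1-ms CI scans) is a cluster-sized computation; a single episode is
hours on one CPU. The shipped test suite and acceptance script therefore
work at desk scale, a deliberate package choice:

* conduction-velocity calibration on the 3-cm, 301-node cable exactly as
  specified (dt = 0.002 ms), including the D/2, D/4 and D/10 reductions;
* protocol and classification logic on sheets of 0.8–2 cm at dx = 0.02 cm
  with shortened pre-pacing (the S1 steady state of a small quiescent sheet
  is reached in 1–2 beats);
* phase/fixture analyses at full fidelity (they are cheap);
* the biphasic-substrate check as: monotone conduction slowing across
  fibrosis fractions on 1.2-cm failing strips; the hundred-fold-uncoupling
  propagation block on the 28%-fibrosis strip; and one full cross-field
  reentry induction on a 2 × 2 cm, 28%-fibrosis failing sheet at ten-fold
  uncoupling (dt = 0.01 ms, two pre-pacing beats at BCL 900 ms, a fixed
  strongly suprathreshold electrode, coupling interval 450 ms — a point
  inside that substrate's desk-scale vulnerable window, which is bracketed
  by full-propagation outcomes at CI 300 and 600 ms), asserting ≥ 2
  rotations, a rotor-scale dominant period and a tracked tip trajectory;
* the full vulnerable-window scans (2.5 × 2.5 cm, 3 seeds, all four
  fibrosis fractions and the uncoupling series) ship as
  `scripts/biphasic_study.R` (an overnight batch), and the full-scale
  protocol as `scripts/full_reproduction.R`. Two
  sub-claims are not demonstrable at desk scale in this implementation:
  the 40%-fibrosis electrotonic-propagation endpoint (with this scheme's
  higher conduction safety a 40% strip still conducts full-amplitude) and
  the vulnerable-window *width* orderings, which need the larger sheets.

# Known limitations and departures

* **Conduction velocity versus the reference implementation.** With the
  transcribed GPB membrane kinetics (single-cell dV/dt_max ≈ 386 V/s,
  APD90 ≈ 299 ms, both in the published range) and the flux-conservative
  scheme at dx = 0.01 cm, the calibration cable conducts at ≈ 77 cm/s for
  D = 0.0013 cm²/ms, converged to ~2% under dx and dt refinement.
  Published FEM simulations of this tissue model quote 50 cm/s for the
  same nominal coefficient; monodomain coefficients are only meaningful
  jointly with the solver and its discretization, and pseudo-adaptive time
  stepping is known to slow upstroke propagation. We therefore treat a quoted coefficient as
  solver-specific: `calibrate_conduction(50)` recovers the coefficient
  (≈ 5.7e-4 cm²/ms) that reproduces the physiological 50 cm/s in *this*
  scheme, and the acceptance checks report the faithful measurement at the
  printed coefficient rather than a value forced through calibration.
* **CV ∝ √D.** The continuum square-root law holds to a log–log slope of
  ≈ 0.55 over D…D/10 on the dx = 0.01 cm cable; the excess over 0.5 is
  discrete-lattice slowing of the thinning wavefront at low D (FEM
  simulations of the same reduction report the opposite deviation, a CV
  above the √D prediction). At D/100 with 28% fibrosis the lattice blocks
  propagation entirely, reproducing the uncoupling-block endpoint.
* **Desk-scale reentry.** The electrophysiological wavelength (CV × APD ≈
  15 cm normal, ≈ 6 cm at ten-fold uncoupling) exceeds any desk-scale
  sheet, so sustained rotors at the paper's full-scale conditions cannot
  form in the small test tissues; the suite asserts the induction
  machinery, classification boundaries, block endpoints and, where the
  wavelength permits (strong fibrosis plus uncoupling), rotation counting
  on true reentrant episodes.
* Fibrosis is diffuse (i.i.d. node replacement) only: no patchy textures,
  collagen strands, or spatially varying fiber angles. No bidomain, no 3D,
  no EAD/DAD trigger protocols, no drug block.
* The exact HF override factors are transcription targets taken from the
  companion failing-ventricle model family; they ship as data, and any
  alternative table can be supplied per run.
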