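Package: cardiowave
Title: Monodomain Simulation of Fibrotic Failing Ventricular Tissue and
    Spiral-Wave Vulnerability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates two-dimensional human transmural ventricular tissue
    as a monodomain reaction-diffusion system on a regular grid, coupling
    the Grandi-Pasqualini-Bers human ventricular myocyte model (with a late
    sodium current and optional heart-failure ionic remodeling) to the
    MacCannell active fibroblast model through a heterogeneous anisotropic
    diffusion field built from randomly placed fibroblasts (diffuse
    fibrosis). Provides cross-field S1-S2 stimulation protocols,
    vulnerable-window scans for spiral-wave reentry, and post-hoc analysis
    of membrane-potential movies: Hilbert-transform instantaneous phase,
    ring-sum phase-singularity detection, rotor-tip tracking, dominant
    cycle-length histograms, conduction velocity and action potential
    duration measurement. Includes analytic synthetic fixtures (plane
    waves, rotating spirals, vortex phase fields) with known ground truth
    for testing every analysis stage without PDE runs.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
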