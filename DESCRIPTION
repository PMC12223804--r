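Package: binlesswe
Title: Weighted-Ensemble Path Sampling with Binless and Adaptive Resampling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Weighted-ensemble (WE) path sampling for rare-event kinetics
    with a minimal adaptive binless (MABL) resampler that ranks walkers by a
    multiplicative progress score (per-coordinate normalized progress,
    tunable scaling factors, a soft weight-balance term, and region-based
    progress scaling), plus minimal adaptive binning (MAB), nested
    multi-MAB, and fixed-bin resamplers. Ships desk-scale toy systems with
    exact oracles (discrete Markov chains, a 1-D double-well Langevin
    system, and a 2-D surrogate ligand-unbinding landscape), statistically
    exact split/merge primitives, recycling boundary conditions, and
    analysis tools for weighted histograms, first-event aggregate times,
    flux-based rate estimates, and weight-profile diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
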