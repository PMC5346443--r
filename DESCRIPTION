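Package: nldfs
Title: Nonlinear Dynamic Force Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Theory and simulation toolkit for dynamic force spectroscopy of
    single receptor-ligand bonds under arbitrary monotonically increasing
    loads. Implements Bell-Evans force-dependent dissociation kinetics, the
    analytic survival and rupture-force density for any monotone loading
    protocol (constant-rate, power-law, worm-like chain, or tabulated
    force-distance curves), closed-form and implicit most-probable rupture
    force prediction, exact inverse-hazard Monte Carlo simulation of rupture
    forces, Gaussian kernel rupture-force spectra with peak identification,
    and recovery of the bond length and thermal off-rate from (pulling
    velocity, peak force) data by Nelder-Mead least squares, including a
    sample-size error study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
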