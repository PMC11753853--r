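Package: trabflow
Title: Interstitial Flow and Wall Shear Stress in Microcracked Trabecular Gaps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Steady incompressible laminar flow solver for simplified
    inter-trabecular gap geometries containing a rectangular microcrack
    groove. Builds parameterized channel-plus-groove domains, generates
    boundary-tagged tensor-product meshes, solves pressure-driven Stokes
    and Navier-Stokes flow on a staggered (MAC) finite-volume
    discretization, extracts wall shear stress fields, profiles, peaks
    and in-crack shear gradients, and drives the parametric sweeps over
    pressure difference, gap width, gap height and microcrack size with
    regression summaries. Closed-form plane-Poiseuille and
    rectangular-duct series solutions are included as independent
    verification oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
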