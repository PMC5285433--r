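Package: scarsim
Title: Continuum Mechanobiological Simulation of Hypertrophic Scar
    Formation and Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the formation and slow regression of hypertrophic
    scar tissue in a two-dimensional plane-strain slice of dermis. Four
    coupled transport-kinetics equations (fibroblasts, myofibroblasts, a
    generic signaling molecule and collagen) are mechanically coupled to a
    quasi-static compressible neo-Hookean force balance driven by
    myofibroblast traction. The solver is a moving-grid linear
    finite-element method with backward-Euler time integration, a
    flux-corrected-transport limiter and Patankar source-term splitting for
    positivity, segregated fixed-point defect correction, and adaptive time
    stepping with local-truncation-error control. Includes a deterministic
    structured near-equilateral mesh generator, scenario presets for high
    and low myofibroblast apoptosis rates, dermal-thickness and
    material-point tracing, strain-energy-density fields, and plain-text
    (CSV/VTK/YAML) input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
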