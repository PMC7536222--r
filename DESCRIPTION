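Package: mitovolt
Title: Electrical-Circuit Analysis of Mitochondrial Membrane Potential in Mitosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring relative mitochondrial ATP synthesis rates
    through mitosis from single-cell membrane-potential dye traces. Models the
    inner mitochondrial membrane as an RC circuit whose conductances switch
    with CDK1 activity, converts mass-normalized potentiometric dye signal to
    approximate membrane potential via the Nernst equation, fits
    state-specific exponential relaxation time constants, extracts the
    ATP-synthase conductance from a control versus oligomycin comparison, and
    derives Ohm's-law ATP synthesis currents with cohort-level uncertainty.
    Includes a synthetic single-cell trace generator for validation, and
    population-level flux utilities: cell-cycle synchrony unmixing of
    population measurements, oligomycin-sensitive oxygen-consumption
    decomposition, and lactate efflux rate estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
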