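Package: pmbflash
Title: Proton Minibeam FLASH Delivery Simulation and Dose-Rate Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for pencil-beam-scanned proton
    minibeam delivery through brass multi-slit collimators at ultra-high
    (FLASH) and conventional dose rates. Provides an analytic pencil-beam
    model in water (power-law range-energy, Bortfeld-style Bragg curve,
    Highland/Fermi-Eyges lateral scattering), Monte Carlo transport of spot
    phase space through multi-slit collimators, hybrid dose scoring on a
    non-uniform phantom grid, pulsed spot-scanning delivery schedules and
    log files, field-average and PBS (Folkerts) dose-rate metrics with a
    brute-force oracle, and profile analysis: peak/valley location,
    peak-to-valley dose ratio (PVDR), and 1-D gamma comparison. A synthetic
    data module emulates film-scan profiles and bundles named scenario
    presets so the full pipeline runs from configuration alone.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
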