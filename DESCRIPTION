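Package: contraplast
Title: Quantification of Contralesional Cortical Plasticity After Brain Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for structural and functional plasticity of
    contralesional cortical neurons after traumatic brain injury. Computes
    longitudinal dendritic-spine turnover statistics (density, elimination and
    formation rates, stable fractions, morphology-type fractions, persistence
    indices), calcium-trace activity calls with explicit neuropil compensation
    (zero-phase low-pass filtering, robust transient detection, activity-fate
    taxonomies), monosynaptic rabies-tracing connectivity ratios with
    starter-cell interpolation, small histomorphometry formulas (lesion volume,
    cortical thickness, cell and synaptic-pair densities), and nonparametric
    bootstrap inference on neuron fractions. Ships seeded synthetic-data
    generators (spine birth-death process, spike-to-fluorescence simulator,
    Poisson tracing counts) so every analysis stage is testable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    multcomp,
    signal,
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
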