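Package: gatecontext
Title: Characterization of Genetic NOT Gates Across Plasmid and Host Contexts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantitative characterization of genetic
    inverters (NOT logic gates) measured in multiple plasmid-backbone and
    host-strain contexts. Converts event-level flow-cytometry-like data to
    relative promoter units (RPU) via autofluorescence and reference-standard
    controls, fits four-parameter repressive Hill transfer functions with
    logarithmic residuals, derives input/output thresholds and an
    operational criterion, scores pairwise gate compatibility and
    discrete-Frechet shape similarity, searches the compatibility graph for
    the deepest repressor-distinct inverter chains, and fits affine
    cross-context predictors. Includes a synthetic event-level data
    generator with known ground truth so the entire pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
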