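Package: gsmn
Title: Reconciliation, Curation and Constraint-Based Analysis of
    Genome-Scale Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling, reconciling and curating genome-scale
    metabolic network (GSMN) reconstructions and for turning them into
    constraint-based flux models. Supports SBML Level 3 (FBC v2) read/write,
    multi-source subnetwork merging with reaction provenance, identifier
    reconciliation (including tiered InChIKey matching), duplicate reaction
    resolution, seed-based topological producibility (network expansion),
    minimal topological gap-filling with tiered repair databases, elemental
    mass and charge balance quality control, leak/siphon and
    energy-generating-cycle screening, and flux balance / flux variability
    analysis under configurable growth media. A synthetic-network generator
    with known ground truth (scope, minimal completions, closed-form growth
    optima, injected defects) makes every pipeline stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
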