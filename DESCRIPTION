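Package: tbpAffinity
Title: TBP-Promoter Binding Affinity Estimation and Group Comparison for
    Plant Proximal Promoters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the equilibrium dissociation constant (KD) of
    TATA-binding protein (TBP) complexes with 90 bp plant proximal
    promoter sequences using a calibrated three-step binding model:
    nonspecific sliding sets an affinity ceiling, position-weight-matrix
    recognition of the TATA box scores candidate sites on both strands,
    and complex stabilization is absorbed into a log-linear interpolation
    between two experimentally motivated affinity anchors. Per-promoter
    estimates are aggregated into per-species and per-group summaries
    (mean and standard error) and compared between promoter groups with a
    difference-of-means Z-test. Includes a deterministic synthetic cohort
    generator that plants TATA-like sites of controlled strength, and a
    reproducible end-to-end pipeline emitting tabular reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
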