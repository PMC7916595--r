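Package: comprof
Title: SILAC Complexome Profiling of Blue-Native Gels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of SILAC-labelled complexome profiling
    experiments, in which digitonin-solubilised mitochondrial complexes are
    separated on a blue-native polyacrylamide gradient gel, the lane is cut
    into slices, and peptides are quantified per slice by mass spectrometry
    in a heavy and a light isotope channel. The package separates SILAC
    channels, selects a representative peptide per protein, builds
    max-normalised migration profiles averaged over label-swapped replicate
    experiments, computes protein- and complex-level abundance ratios between
    conditions, calibrates slice position against apparent molecular mass,
    and detects migration peaks and condition-specific peak shifts such as
    stalled assembly intermediates. A synthetic-data generator emulates a
    two-condition (wild-type versus cytochrome c oxidase subunit 4 knock-out)
    experiment so every stage of the pipeline can be verified at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
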