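Package: pentascan
Title: Structural Deviation Mapping and Proton Dose-Response Analysis for
    Pentameric Ligand-Gated Ion Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two complementary analyses of mutational scans of
    homopentameric proton-gated ion channels. The structural arm maps
    per-residue deviations of a mutant pentamer against duplicate wild-type
    reference structures using a 25-alignment pairwise-chain superposition
    scheme and normalizes them by the intrinsic variability between the two
    references, flagging residues whose backbone moves more than a fold-change
    threshold. The electrophysiology arm fits per-oocyte proton dose-response
    (Hill) curves from two-electrode voltage clamp recordings, applies quality
    filters, computes batch-matched pH50 shifts, and classifies mutants as
    gain or loss of function. Includes seeded synthetic-data generators for
    both data types so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
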