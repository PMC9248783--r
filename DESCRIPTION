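Package: hrmelt
Title: High-Resolution Melting Curve Analysis for Species and Haplotype
    Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for high-resolution melting (HRM) curve
    analysis of PCR amplicons, built around COI-based identification of
    soil invertebrates such as earthworms. Reads raw melt-fluorescence
    plate exports, derives negative-derivative melting curves and melting
    temperatures, averages technical replicates, computes mean-subtracted
    difference curves, classifies unknown samples against a reference
    curve library with explicit ambiguity handling and multiplex-assay
    resolution, and clusters difference curves into haplotype groups. An
    in-silico PCR engine evaluates IUPAC-degenerate primers against
    template sequences, and a companion haplotype toolkit extracts
    primer-anchored COI subregions, collapses them to haplotypes, and
    builds UPGMA trees. A two-state thermodynamic melt simulator
    generates complete synthetic plates and sequence sets with known
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
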