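Package: scatdiet
Title: Scat DNA-Metabarcoding Diet Analysis with Majority-LCA Taxonomic Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reproducible pipeline for carnivore diet analysis from
    scat (faecal) 12S amplicon metabarcoding data. Implements exact
    dereplication, minimum-cluster-size filtering, UNOISE-style abundance-skew
    denoising, de-novo bimera (two-parent chimera) screening, filtering of
    BLAST-tabular alignment hits by bit-score window, identity and query
    coverage, a majority lowest-common-ancestor (MLCA) consensus taxonomic
    assignment over unique reference lineages, molecular confirmation of the
    depositing host species, and predator-diet summaries: percent frequency of
    occurrence (FOO), relative read abundance (RRA), per-sample prey richness,
    prey-group aggregates, woodland to open habitat ratios, and field-versus-DNA
    host confusion. A seeded synthetic-data generator emulates host-dominated
    scat samples with skewed prey read counts, human contamination,
    positive-control spikes, substitution errors, bimeric reads and
    field-misidentification, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
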