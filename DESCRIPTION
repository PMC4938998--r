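Package: moacliff
Title: Scaffold, Matched Molecular Pair and Mechanism-of-Action Cliff
    Analysis for Paired Agonist/Antagonist Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for the cheminformatics analysis of paired
    high-throughput screens that probe opposing mechanisms of action
    against one target, such as nuclear-receptor agonist and antagonist
    assays run over a common compound library. Provides curation of
    PubChem-BioAssay-style result tables with a per-stage audit trail,
    Bemis-Murcko scaffold and cyclic-skeleton decomposition with
    frequency, ring-count, exclusivity and fingerprint-diversity
    statistics, size-restricted matched-molecular-pair (MMP) generation
    by fragment-and-index, binary-outcome activity-cliff calling, and a
    same/weak/strong mechanism-of-action cliff classification for
    compounds screened in both assays. Includes a seeded synthetic
    screening-library generator with planted ground truth so every stage
    is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
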