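Package: aneuscore
Title: Genome-Wide Aneuploidy Scoring and Outcome Analysis for Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Arm-level aneuploidy analysis of cell-free DNA from LINE-1
    amplicon sequencing. Counts reads per chromosome arm, normalizes to
    library size, computes per-arm Z-scores against a healthy-control
    reference, and summarizes them into a genome-wide aneuploidy (GWA)
    score dichotomized at 5. Includes segment-to-arm aggregation of tissue
    copy-number calls with Spearman concordance against cfDNA Z-scores,
    Kaplan-Meier / log-rank / Cox proportional-hazards machinery with a
    treatment-by-GWA interaction model, Poisson-corrected digital-PCR
    copy-number ratios, and a Dirichlet-multinomial synthetic-data
    generator emulating healthy controls, tumor-fraction mixtures, matched
    tissue segments and survival outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
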