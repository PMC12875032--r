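Package: sepsisproteome
Title: Plasma Proteomics Analysis Pipeline for Pediatric Sepsis Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible analysis pipeline for targeted plasma proteomics
    case-control cohorts with paired longitudinal sampling. Implements
    empirical-Bayes moderated t-test differential expression with
    Benjamini-Hochberg false-discovery control and fold-change gating,
    Boruta shadow-feature biomarker selection around depth-limited random
    forests, protein-wise Pearson and point-biserial correlations with
    clinical severity scores and mortality, hypergeometric
    over-representation analysis against user-supplied gene sets, and a
    weighted bipartite pathway-clinical association graph in which each
    protein contributes w = rho * R with R the Euclidean norm of its
    volcano-plot coordinates. A synthetic cohort generator with planted
    effects supports parameter-recovery and calibration testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
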