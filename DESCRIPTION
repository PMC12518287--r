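Package: digeflow
Title: Differential Analysis of 2D-DIGE Proteomic Spot Intensities with
    Trajectory and Promoter Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-acquisition analysis of two-dimensional difference gel
    electrophoresis (2D-DIGE) experiments with a three-level oxygen
    treatment design (control, anoxia, re-aeration) in two plant organs.
    Provides readers and writers for spot-intensity tables, log2
    transformation and quantile normalization, three per-spot significance
    frameworks (Kruskal-Wallis, a random-intercept mixed model fitted by
    restricted maximum likelihood, and an empirical-Bayes moderated F test
    with variance shrinkage), p-value adjustment and significant-spot
    selection, k-means and complete-linkage hierarchical clustering with
    automated k selection and set-overlap partition-concordance scores,
    classification of condition trajectories into four abundance groups,
    sequence-derived protein physicochemistry (isoelectric point,
    molecular weight, composition, in-silico tryptic digestion, autolysis
    peak filtering, Rf-based mass estimation), promoter extraction with
    AT-content profiling and transcription-factor binding-site
    summarization, and a seeded synthetic-data generator emulating the
    full experimental design.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    cluster,
    yaml,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    jsonlite
Config/testthat/edition: 3
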