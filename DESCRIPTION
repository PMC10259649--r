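Package: moldscore
Title: qPCR-Based Indoor Mold Assessment: ERMI Scoring, Diversity, and
    Year/Region Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative assessment of indoor fungal contamination
    from dust-sample qPCR panels. Converts cycle-threshold records for the
    36-species Environmental Relative Moldiness Index (ERMI) panel into cell
    equivalents per milligram of dust with spike-in extraction quality
    control, computes per-home ERMI scores and Shannon diversity/equitability,
    and runs the between-year and between-region comparison battery
    (per-species Wilcoxon rank-sum tests with Holm-Bonferroni correction,
    Student's t-tests on group log-sums, and one-way ANOVA with Tukey HSD
    pairwise comparisons and compact letter displays). A seeded synthetic
    cohort generator with lognormal species abundances, water-damage and
    phylloplane-bloom effects provides ground-truth data for validating every
    stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
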