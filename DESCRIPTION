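Package: spikexpr
Title: MEA Spike Detection and Transcriptomic Statistics for Brain Organoid Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-density multi-electrode array (HD-MEA)
    recordings and bulk RNA-seq expression matrices from human brain organoid
    experiments. Provides recalibration-artifact excision, saturation-flash
    removal, Remez FIR bandpass filtering, moving-window threshold spike
    detection with channel selection and activity summaries; group-comparison
    statistics (unpaired t, one-way ANOVA with Sidak multiple comparisons,
    Shapiro-Wilk, robust outlier screening); TPM expression filtering and
    threshold-based differential expression calling; gene-list overlap
    statistics (representation factor, hypergeometric tails, Venn partitions),
    GMT over-representation and pre-ranked gene-set enrichment analysis; unit
    conversions for dosing; and seeded synthetic-data generators with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    yaml,
    jsonlite,
    fgsea,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
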