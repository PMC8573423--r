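Package: paraplank
Title: Parasite Identification and Seasonal Community Dynamics from
    Plankton Metabarcoding Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies parasitic amplicon sequence variants (ASVs) in 18S
    rRNA metabarcoding data by linking sequence records to hosts through an
    offline literature registry and sequence-record metadata (host,
    isolation source, title fields of BLAST-style hits), and analyses the
    seasonal and inter-annual dynamics of the resulting parasite community:
    relative read abundance and richness with two-way ANOVA and Tukey HSD,
    Baselga turnover/nestedness partitioning of Sorensen dissimilarity with
    per-year resampling, PERMANOVA with pairwise comparisons, non-metric
    multidimensional scaling, and SIMPER decomposition of Bray-Curtis
    dissimilarity. Ships a synthetic-data generator with exported ground
    truth so every stage is testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
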