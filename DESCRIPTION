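Package: regionburden
Title: Regional Rare-Variant Burden Scans and Ancestor-Mutation
    Prioritization for Tumor Microdissection Studies
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing non-coding candidate driver mutations
    from deep targeted sequencing of tumor cohorts.  Identifies ancestor
    ("root") mutations shared across laser-capture microdissected tumor
    islets, filters rare single-nucleotide variants against a reference
    allele-frequency panel, scans a genomic region with overlapping
    windows for rare-variant enrichment using a Hardy-Weinberg
    genotype-simulation null, a resampled control-cohort order-statistic
    p-value and a uniform-rate Poisson model, assigns variants to genes
    through GREAT-style cis-regulatory domains with a permutation test for
    gene-ontology enrichment, and computes downstream
    immunohistochemistry biomarker statistics (intensity-score
    aggregation, ANOVA with Tukey contrasts, logistic-model ROC, power
    calculations) and droplet-digital-PCR mutant fractions.  A synthetic
    data generator emulates every input so the full pipeline is testable
    without controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
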