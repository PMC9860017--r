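Package: finewas
Title: Fine-Mapping Annotations, Partitioned Heritability, TWAS and
    Rare-Variant Burden Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative statistical-genetics toolkit covering the summary
    statistic machinery used to dissect the genetic architecture of complex
    disease: inverse-variance fixed-effect meta-analysis of molecular QTL
    effect sizes, enumeration-based Bayesian fine-mapping with causal
    posterior probabilities and credible sets, construction of MaxCPP and
    binding-site annotations, stratified LD-score regression with
    standardized per-annotation effect sizes and block-jackknife inference,
    two-stage transcriptome-wide association with weighted Stouffer
    meta-analysis and gene-level posterior inclusion probabilities, and
    rare-variant genic burden testing via Firth-penalized logistic
    regression with inverse-variance-weighted meta-analysis. Includes
    generators for synthetic genotype panels, GWAS summary statistics,
    expression panels and rare-variant cohorts with recorded simulation
    truth, so every stage is testable without access-controlled cohort
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
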