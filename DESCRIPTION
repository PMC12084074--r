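Package: smn2meth
Title: Haplotype-Aware CpG Methylation Analysis of the SMN2 Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of targeted DNA methylation data across the
    duplicated SMN2 locus in spinal muscular atrophy cohorts: parsers for
    bedMethyl-dialect modified-base count files and Bismark coverage files,
    strand merging and SNV-aware CpG masking into a site-by-sample
    methylation-percentage matrix (per patient and per haplotype), variance
    and correlation based site reduction, per-CpG covariate-adjusted linear
    model differential methylation with Benjamini-Hochberg false discovery
    rate control, noncentral-F power analysis for linear models, PCA and
    Ward clustering for exploration, and a seeded synthetic-cohort generator
    with planted effects for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
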