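Package: methlink
Title: Genetically Influenced Differential Methylation Discovery and
    Characterisation from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-step pipeline for identifying genetically influenced,
    differentially methylated CpG sites associated with disease risk.
    Discovery combines a summary-statistics methylome-wide association test
    (imputed methylation Z scores built from cis-meQTL weight models, GWAS
    effect sizes and a reference linkage-disequilibrium panel) with
    conventional tumour-versus-control differential methylation regression.
    An exact-binomial stepwise overlap cascade selects the enriched CpG set.
    Characterisation links CpGs to genes by interval annotation, distance
    windows and eQTL-SNP overlap, tests differential and conditional
    (mediation) expression, apportions familial relative risk to meQTL SNPs,
    scans for independent SNPs by approximate conditional analysis, and
    meta-analyses summary statistics across traits with heterogeneity
    statistics. A synthetic-data module generates reference panels, weight
    models, summary statistics, methylation and expression matrices with
    known truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
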