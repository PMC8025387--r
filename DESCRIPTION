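Package: ewasmed
Title: Treatment EWAS and Methylation-Mediated Risk of Chronic Health Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying how cancer-treatment exposures
    leave persistent marks on blood DNA methylation and how those marks relate
    to later cardiometabolic disease. Provides post-array quality control of
    beta-value matrices (detection-p masking, missingness filters, quantile
    normalization, beta/M transforms), reference-based leukocyte deconvolution
    and methylation principal components; treatment-specific epigenome-wide
    association studies on M-values with phi-coefficient-driven adjustment-set
    selection and genomic-control correction; dose-response and paired-exposure
    scans with CpG-island and functional-region enrichment; polygenic risk
    scores by r-squared pruning and risk-allele counting; logistic association
    of residual methylation with incident chronic health conditions under FDR
    control; and quasi-Bayesian causal mediation (ACME/ADE/percent mediated)
    for single CpGs and combined methylation scores. A synthetic-cohort
    generator with full ground truth (correlated binary treatments via a
    Gaussian copula, cell-mixture methylation with treatment-shifted CpGs,
    genotypes, and partially mediated binary outcomes) supports calibration
    and parameter-recovery testing of the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    pracma,
    limma,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
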