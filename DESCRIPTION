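Package: grsresp
Title: Protein-Predicting Genetic Risk Scores and Biologic Therapy Response in Asthma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline linking protein-predicting
    genetic risk scores (GRS) to response to biologic therapy in asthma.
    Includes polygenic scoring from VCF genotypes with allele harmonization,
    score quality control (training-R2 filter, rank-based inverse-normal
    transformation, normality screening, trimodality detection with fallback
    to top-effect-SNP allele dosage), rule-based electronic-health-record
    exacerbation phenotyping with temporal windows and censoring at biologic
    switch, principal-component-adjusted logistic association testing,
    two-cohort replication screening, empirical type-I-error calibration with
    random score sets, and discrimination/calibration evaluation (AUROC with
    DeLong intervals and comparison, Hosmer-Lemeshow tests, confusion
    metrics). A synthetic two-cohort generator with known ground truth makes
    every stage exercisable without access-controlled biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    cluster,
    pROC,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
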