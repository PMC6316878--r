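Package: pgxprio
Title: Two-Phase Germline Pharmacogenomic Variant Prioritization
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quality control, association testing and evidence-based
    prioritization of germline pharmacogenomic variants in a two-phase
    (testing/validation) cohort design. Provides per-variant minor allele
    frequency, exact Hardy-Weinberg testing and missingness filters,
    Pearson chi-square response tests and Kaplan-Meier/log-rank
    disease-free-survival tests with permutation-adjusted p-values,
    Cox and logistic multivariate adjustment, a gene-dosage consistency
    gate, a priority-matrix evidence integrator combining database flags
    with in-silico predictions, and a synthetic-cohort generator with
    planted genotype effects so the whole pipeline is testable without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse,
    withr
Config/testthat/edition: 3
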