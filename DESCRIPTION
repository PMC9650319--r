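Package: apoemqtl
Title: APOE-Allele-Stratified SNP-Metabolite Association and
    Effect-Heterogeneity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stratified genetic association analysis of plasma metabolites
    in family cohorts. Implements genotype quality control (minor allele
    frequency, exact Hardy-Weinberg, missingness, Mendel error filters),
    APOE epsilon-allele group assignment from rs429358/rs7412, linear
    mixed-model association scans of log-transformed metabolite
    concentrations with a pedigree kinship random effect and
    Benjamini-Hochberg discovery, cross-group effect-heterogeneity
    chi-square contrasts with interaction-model corroboration, supporting
    diagnostics (linkage disequilibrium, variance inflation factors,
    metabolite summaries), hypergeometric pathway over-representation,
    and a synthetic nuclear-family cohort generator with planted
    stratum-specific effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
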