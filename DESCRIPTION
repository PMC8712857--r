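Package: haplodose
Title: Haplotype-Based Noninvasive Prenatal Diagnosis by Relative Haplotype Dosage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Relative haplotype dosage (RHDO) analysis for noninvasive prenatal
    diagnosis (NIPD) of X-linked single-gene disorders, modelled on clinical
    cell-free DNA (cfDNA) workflows for Duchenne muscular dystrophy. Provides
    fetal-fraction and fetal-sex estimation from targeted maternal plasma
    sequencing counts, pedigree-based maternal haplotype phasing, Type 1 /
    Type 2 informative-SNP classification, per-SNP dosage-change series with
    circular binary segmentation (CBS) for meiotic recombination detection,
    Bayes-factor fetal genotype calling, a binomial in-silico assay
    performance model, cohort-level summaries, and a fully seeded synthetic
    family generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
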