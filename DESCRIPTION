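Package: egvkit
Title: Estimated Genetic Values and Family-Based Association in Extended Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes BLUP-style estimated genetic values (EGVs) for members of
    extended pedigrees from pedigree-based or marker-based relatedness, and uses
    them as refined phenotypes in family-based genome-wide association. Provides
    recursive pedigree kinship (2*Phi), KING-robust empirical kinship with
    nearest-correlation (alternating projections) repair, genotype principal
    components on an unrelated subset with parental-mean projection onto
    relatives, maximum-likelihood variance-component polygenic models fitted by
    spectral decomposition, measured-genotype likelihood-ratio association
    scans under a family covariance structure, true/false-positive adjudication
    of significant SNPs by linkage disequilibrium with a known causal
    architecture, and a gene-drop simulator that generates pedigrees,
    LD-structured genotypes, covariates and replicate phenotypes with a
    configurable multi-gene causal architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    vcfR
Config/testthat/edition: 3
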