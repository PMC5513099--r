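Package: marv
Title: Multi-Phenotype Analysis of Rare Variants via Reverse Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Region-based burden testing of rare genetic variants against
    several phenotypes at once.  The per-individual proportion of rare
    variants at which minor alleles are carried is modelled as a weighted
    linear function of the phenotypes ("reverse regression"); association
    is assessed with a likelihood-ratio test against the null of no
    phenotype effects, and the best-fitting phenotype combination is
    selected by BIC over all subsets.  Includes readers for VCF and
    IMPUTE2 GEN/SAMPLE dosage files with minor-allele-frequency and
    imputation-quality filters, a synthetic genotype/phenotype simulator
    with a calibrated rare-variant frequency spectrum, and a replicate
    harness for estimating type-I error and power against a univariate
    burden test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    MASS,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
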