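Package: gdtest
Title: Family-Based Association Tests via Gene-Dropping Null Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Score tests of genotype-phenotype association in samples of
    related individuals, using the analytical mean and variance of the score
    statistic under gene dropping. Provides pedigree loading and validation,
    kinship and identity-by-descent computation, exact enumeration and
    sampling of inheritance vectors, a gene-dropping Monte-Carlo engine,
    the unconditional and inheritance-vector-conditional variance formulas,
    the decomposition of the test statistic into linkage and association
    components, a Monte-Carlo linkage test, SNP and phenotype preprocessing
    (Hardy-Weinberg filtering, minor-allele-frequency filtering,
    medication-effect adjustment, tie-aware ranking), and a synthetic cohort
    generator for simulation studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), vcfR, jsonlite, optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
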