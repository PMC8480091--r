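Package: pcselscan
Title: PCA-Based Selection Scans from Genotype Likelihoods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide selection scans for low-coverage sequencing data
    operating directly on genotype likelihoods. Individual allele
    frequencies are estimated by an iterative procedure that alternates
    posterior genotype dosages, Binomial standardization and truncated
    singular value decomposition, capturing continuous population
    structure without calling genotypes. Two calibrated per-site test
    statistics are derived from the factorization: a per-component
    normalized variant-weight statistic (chi-square, 1 df) and a
    multivariate robust-Mahalanobis statistic over regression z-scores
    (chi-square, K df) with genomic-inflation correction. Includes a
    Beagle-format reader/writer, EM allele-frequency estimation with a
    likelihood-ratio SNP test and minor-allele-frequency filtering, a
    Balding-Nichols simulator of structured low-coverage datasets, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
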