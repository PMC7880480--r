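Package: gsemkit
Title: Variance-Component Structural Equation Models on Genomic-Relationship Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage developmental genetic analysis of multivariate traits in
    unrelated individuals. Builds genomic-relationship matrices (GRMs) from SNP
    dosage data with standard quality control, estimates SNP heritability and
    genetic correlations by average-information REML (univariate and bivariate
    GREML), and fits saturated Cholesky-decomposition structural equation models
    (GSEM) in which latent genetic factors are identified through the GRM and
    residual factors through the identity matrix. Derived statistics include
    per-factor variance explained, SNP heritability, genetic and residual
    correlations, factorial co-heritability and bivariate heritability, with
    delta-method and parametric-bootstrap standard errors. A synthetic cohort
    generator with known lower-triangular genetic/residual factor structure,
    wave-specific missingness and sex/age covariate effects supports end-to-end
    validation. Reads and writes PLINK bed/bim/fam and GCTA binary GRM formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
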