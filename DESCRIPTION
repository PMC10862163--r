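Package: pedgenvar
Title: Pedigree Versus Genomic Relatedness in Quantitative Genetic Animal Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating additive genetic variance and heritability of
    repeatedly measured quantitative traits in wild populations with a Bayesian
    animal model, using either a pedigree-derived additive relationship matrix
    or a SNP-based identity-by-state genomic similarity matrix. Includes the
    tabular-method relationship matrix, PLINK-style SNP quality control with an
    exact Hardy-Weinberg test, Mantel comparison of relatedness matrices,
    genetic-similarity classification of extra-pair paternity, a conjugate
    Gibbs sampler for variance components with Gelman-Rubin diagnostics, and a
    synthetic-data generator (dual social/genetic pedigrees with controlled
    extra-pair paternity, gene-dropped genotypes, polygenic repeated-measure
    phenotypes) for parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), vegan, lme4, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
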