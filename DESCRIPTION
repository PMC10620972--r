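Package: famlmm
Title: Family-Based Bayesian Linear Mixed Models for Genomic Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a Bayesian linear mixed model with multiple random effects
    for quantitative-trait risk prediction from family-based sequencing
    studies. Isolated common-variant effects receive a spike-and-slab prior,
    gene- or pathway-level effects of common and rare variants are modelled
    through weighted genetic-similarity kernels, and the family design
    contributes two surrogate random effects built from the theoretical
    kinship matrix and a shared-environment block kernel. Inference is by
    coordinate-ascent mean-field variational Bayes with an evidence lower
    bound (ELBO) convergence criterion. The package also provides readers
    and writers for PLINK and text genotype formats, a pedigree
    gene-dropping simulator with configurable family structures and
    phenotype-generation models, family-aware prediction for new
    individuals, a generalized-least-squares marginal variant screen, a
    gBLUP ridge baseline, and replicated benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    graphics,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
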