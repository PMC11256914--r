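Package: mbaugment
Title: Microbiome Data Augmentation with Conditional GANs and
    Phylum-Stratified Convolutional Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Generates labelled synthetic gut-microbiome samples with a
    conditional generative adversarial network (C-GAN), aligns real and
    generated samples in a common latent subspace with a target-swapped
    autoencoder, and predicts binary disease status with a
    phylum-stratified, correlation-ordered ensemble of one-dimensional
    convolutional networks. Includes a seeded compositional-data
    simulator for sparse genus-level abundance tables, alpha-diversity
    realism diagnostics (sparsity, Shannon, Chao1), and a stratified
    repeated cross-validation harness with percentile confidence
    intervals that keeps generative augmentation inside training folds.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
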