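---
title: "Generative augmentation and stratified prediction for microbiome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative augmentation and stratified prediction for microbiome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Case/control microbiome studies typically have hundreds of samples and
at least as many genus-level features, 70–80% of which are zero in any
given sample. Deep classifiers overfit badly at that size. `mbaugment`
implements a three-stage remedy: synthesize additional labelled samples
with a conditional GAN, align real and synthetic data in a common
latent subspace with a target-swapped autoencoder, and classify with a
phylum-stratified, correlation-ordered ensemble of small 1D CNNs.
An evaluation harness (stratified 70/30 split, repeated stratified
cross-validation with percentile confidence intervals, alpha-diversity
realism diagnostics) quantifies whether augmentation actually helps.

All networks are implemented in base R matrix code with explicit
backpropagation. They are deliberately small — multilayer perceptrons
and single-block CNNs — because the input is a vector of at most a few
hundred proportions, not an image.

## The conditional GAN

The generator maps a noise vector concatenated with a one-hot class
label through an MLP (defaults `noise 64 + 2 -> 128 -> 256 ->
feature_dim`, LeakyReLU(0.2)) to a softmax head, so every generated
sample is a valid composition. The discriminator is the mirrored MLP
with a sigmoid head; both are trained by minibatch SGD on the standard
minimax objective
`E[log D(x|c)] + E[log(1 - D(G(z|c)))]`, with probabilities clamped at
`1e-7`. A non-saturating generator loss is available behind a flag.
Defaults follow the study protocol this package implements: 400 epochs,
batch size 5, learning rate 0.001 (an optional momentum term is off by
default).

Four design elements beyond the textbook C-GAN proved necessary, and
all are visible, documented switches:

* **Moment-matched head initialization.** The softmax head's bias
  starts at the log mean composition and its weights are rescaled so
  the per-sample spread of the logits matches the spread of residual
  log-abundances in the training data. Without this, initial logits
  have near-zero variance, every generated sample is close to the same
  overly-even composition, and SGD cannot repair the evenness gap in
  any practical number of epochs.
* **Class-conditional output bias.** A 2 x feature bias matrix, added
  to the logits according to the sample's class and trained with the
  rest of the generator, initialized at each class's log-mean deviation
  from the pooled mean. Conditioning through the input layer alone
  never produced a measurable case/control difference in generated
  data; with the explicit bias the generated effect profile correlates
  strongly with the real one.
* **Sparsification as part of the output map.** A softmax never emits
  exact zeros, but sparsity is a first-class property of microbiome
  data. The default `sparsify_tau = "match"` zeroes each generated
  row's smallest entries, with the zero count resampled from the
  training rows' zero counts — the same lower-tail censoring that
  produces zeros in sequencing data (see the simulator below). A fixed
  numeric threshold is also supported. With `train_sparsify = TRUE`
  (default) the map is applied during training with a straight-through
  gradient, so the discriminator compares sparse fakes against sparse
  reals instead of keying on the mere existence of zeros.
* **Diversity-matched snapshot selection.** GAN training oscillates;
  the marginal evenness of generated samples drifts over epochs. Since
  the pipeline's explicit goal is diversity-faithful synthesis, the
  returned generator is the per-epoch snapshot whose fixed probe batch
  best matches the real data's per-sample Shannon index in mean and
  spread (`snapshot_best = TRUE`). A small feature-matching term on
  the discriminator's penultimate features (weight 1) additionally
  stabilizes the marginals. The realism diagnostics reported by the
  package are computed on fresh noise draws, not the probe.

## The target-swapped autoencoder

A plain autoencoder reconstructs its input. Here the reconstruction
target of each real sample is swapped for a paired GAN-generated sample
of the same class, and the squared error `||reconstruction - target||^2`
is minimized. Minimizing this loss forces the encoder to place real
samples where the decoder can produce generated-like output, i.e. it
pulls both domains onto a common latent subspace; the last encoder
layer is the representation used downstream. With generated data
identical to the real data and an identity pairing, the module is
exactly a standard autoencoder — a property asserted in the tests.

Pairing is `nearest_within_class` by default (minimal Euclidean
distance on relative abundances, ties to the lower index), with a
`random_within_class` alternative. The architecture is a symmetric MLP
(`feature -> 2*latent (tanh) -> latent`, mirrored decoder with a
softmax head so reconstructions stay compositional).

## The stratified, correlation-ordered CNN ensemble

OTUs are grouped by phylum; the `top_k = 3` phyla with the most OTUs
become clusters (remaining OTUs are dropped with a warning or kept as
an `other` cluster). Within each cluster the Spearman correlation
matrix is computed (average ranks for ties; a constant feature gets
correlation 0 by convention so it annihilates rather than errors), each
row is reduced to the geometric mean of its absolute entries — the
cumulative correlation coefficient — and the cluster's columns are
re-ordered by decreasing coefficient with stable ties. This ordering
places correlated OTUs next to each other so that a 1D convolution
sees meaningful local structure.

Each cluster feeds one small CNN (32 filters, kernel 5, stride 1, one
convolution + ReLU + max-pool(2) + flatten); clusters narrower than the
kernel use a dense layer instead. The flattened branch outputs are
concatenated into one fully connected layer with a 2-class softmax,
trained end-to-end with SGD on a weighted cross-entropy whose class
weights default to inverse class frequencies normalized to sum to 2.
Integrated-gradients attributions (midpoint Riemann rule; completeness
checked in the tests) rank features for interpretation.

When the autoencoder is active (`feature_space = "latent"`), one
autoencoder is trained per phylum cluster on within-cluster
subcompositions, and the Spearman ordering runs on each latent block;
`feature_space = "otu"` skips the autoencoder and runs the ensemble on
raw abundances with generated samples appended as extra rows. Both
modes are first-class. The package's own augmentation benchmarks use
the OTU space, which proved the more robust of the two at benchmark
scale (the latent route showed larger per-seed variance when the
autoencoder is trained on very few real samples).

## The synthetic benchmark

No real cohort ships with the package; a seeded simulator generates
data with the statistical signature of genus-level gut tables:

1. per-OTU log-mean abundances from `N(0, dispersion = 1.5)`;
2. latent per-sample Gaussians with block-equicorrelation 0.5 inside
   each phylum (default four phyla at 45/30/20/5% of 120 OTUs), 0
   across;
3. exponentiation and closure to proportions (log-normal abundances:
   variances large relative to means);
4. a planted effect: 12 OTUs multiplied by `2^1.5` in cases before
   renormalization;
5. entry-wise Bernoulli zero-masking calibrated so the expected zero
   fraction is 0.75.

The masking mechanism deserves emphasis. With a uniform masking
probability, prevalence carries no class information and the planted
magnitude shift is swamped by the zero-dominated variance: the
asymptotic AUC of a centered linear read-out saturates near 0.55 even
at 1000 samples per class, so no classifier — and therefore no
augmentation scheme — can demonstrate anything. Real zeros arise
largely from finite sequencing depth: the probability of observing a
taxon falls as its abundance approaches the detection limit, so
abundant taxa are always seen and case-enriched taxa are seen in more
cases. The default `mask_mode = "detection_limit"` implements exactly
that (dropout probability logistic in realized log-abundance, solved
per sample to hit the target sparsity); it yields oracle AUCs of
0.89–0.95, in line with published gut-microbiome cohorts.
`mask_mode = "uniform"` remains available.

What the simulator does **not** emulate: phylogenetic tree structure
beyond phylum blocks, overdispersed count noise (it produces
proportions directly), batch effects, and non-monotone taxon–taxon
dependencies. Passing benchmarks on simulated data therefore shows the
machinery works under the stated statistical assumptions, not that any
particular real cohort will gain the same amounts.

## Evaluation protocol and problem sizes

The harness follows the study protocol: stratified 70/30 split,
10 x 10-fold stratified cross-validation producing exactly 100 AUC
values, 95% confidence intervals as the empirical 2.5/97.5 percentiles
of those values (linear-interpolation quantiles, R type 7), and point
metrics (sensitivity, specificity, PPV, NPV) at a 0.5 threshold.
Generative models are fitted inside training folds only, so synthetic
samples never leak into validation folds.

The package's own benchmarks run at desk scale, chosen once: cohorts
of 200 real samples x 120 OTUs (sparsity 0.75); GAN training for 150
epochs at batch 20 with momentum 0.9; CNN training for 100 epochs at
batch 20, learning rate 0.01 with momentum 0.9 (an overfitting-prone
schedule on 70 training samples, mirroring the role the full 400-epoch
protocol plays at cohort scale); 600 + 600 generated samples for
augmentation; 150 + 150 for the transfer workflow on a 40-sample
sibling cohort with 3-fold cross-validation. The realism comparison
uses an equal-sized generated draw (200 vs 200) so the rank-sum test
compares like with like.

## Numerical choices and degenerate inputs

* Probabilities are clamped to `[1e-7, 1 - 1e-7]` before logs.
* Geometric means are computed through logs; an exact zero correlation
  annihilates an OTU's cumulative coefficient (`exp(-Inf) = 0`).
* Sorting is stable everywhere (radix order); pooling ties keep the
  first position; nearest-pair ties keep the lower generated index.
* All-zero rows are forbidden in relative mode; sparsification and
  simulation guard against producing them by keeping each sample's
  largest entry alive.
* Chao1 requires counts; relative data must be converted explicitly
  (`as_counts = TRUE`, default depth 10000) since richness from
  singletons is undefined on proportions — the conversion is logged in
  the function's documentation rather than silent.
* Every stochastic routine takes a seed and derives per-stage
  sub-streams deterministically; identical seeds give bit-identical
  models, tables and reports.

## Known limitations

* The GAN learns marginal and class-conditional structure well at
  benchmark scale but underrepresents tails; with very small training
  cohorts its class signal inherits the noise of the empirical class
  difference.
* The latent feature space inherits autoencoder seed variance when the
  real cohort is tiny; the OTU space is the safer default there.
* Only binary outcomes are supported, and only one taxonomy rank
  (phylum) drives stratification.
* The CNN treats real and generated training rows identically; no
  importance weighting between domains is implemented.
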