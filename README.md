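# mbaugment

Data augmentation for case/control microbiome studies. Small cohorts
(a few hundred stool samples, hundreds of genus-level OTUs, 75–80%
zeros) are too small to train expressive classifiers; `mbaugment`
synthesizes additional labelled samples with a **conditional GAN**,
aligns real and synthetic data with a **target-swapped autoencoder**,
and predicts disease status with a **phylum-stratified,
correlation-ordered CNN ensemble**, together with the evaluation
harness needed to show whether the augmentation actually helped.

## The method in brief

Given a relative-abundance table with labels `c ∈ {0, 1}`:

1. **C-GAN.** Generator `G(z | c)` (MLP, softmax head, so outputs live
   on the simplex) and discriminator `D(x | c)` play the minimax game

   `min_G max_D  E[log D(x|c)] + E[log(1 − D(G(z|c)))]`

   with SGD (defaults: 400 epochs, batch 5, lr 0.001). A
   sparsification output map gives generated samples exact zeros with
   the training data's zero-count distribution.

2. **Common-subspace autoencoder.** An encoder/decoder pair
   `E: x → z`, `D: z → x̂` is trained with the reconstruction target
   swapped for a paired GAN-generated sample `x′` of the same class,
   minimizing `‖x̂ − x′‖²`. The last encoder layer is a latent space
   shared by real and generated data.

3. **taxoNN-style ensemble.** OTUs are stratified by phylum (top-3
   phyla by OTU count); inside each cluster the Spearman matrix `ρ` is
   reduced per row to the cumulative correlation coefficient
   `(∏_k |ρ_jk|)^{1/p}`, features are re-ordered by decreasing
   coefficient, and each cluster feeds a small 1D CNN (32 filters,
   kernel 5, stride 1). Flattened branch outputs are concatenated into
   a softmax head trained with class-weighted cross-entropy.

4. **Evaluation.** Stratified 70/30 split; 10×10-fold stratified CV
   producing 100 AUC values, with 95% percentile confidence intervals;
   sensitivity/specificity/PPV/NPV at threshold 0.5; realism
   diagnostics for generated data (per-sample sparsity, Shannon and
   Chao1 diversity, Wilcoxon rank-sum comparisons).

A seeded simulator (`simulate_dataset()`) generates sparse
compositional cohorts with phylum-block correlation, detection-limit
zeros and a planted case/control shift, so the whole pipeline is
testable without any data download.

## Worked example

```r
library(mbaugment)

# a synthetic cohort: 100 cases, 100 controls, 120 genus-level OTUs
sim <- simulate_dataset(sim_config(n_cases = 100, n_controls = 100,
                                   n_otus = 120, seed = 1))
tab <- sim$table
sparsity(tab)$mean

# train the conditional GAN and generate labelled synthetic samples
gan <- train_cgan(tab, gan_config(feature_dim = 120, epochs = 150,
                                  batch_size = 20, momentum = 0.9, seed = 1))
gen <- sample_synthetic(gan, n_cases = 100, n_controls = 100, seed = 2)

# realism: sparsity and Shannon diversity of generated vs real data
sparsity(gen)$mean
compare_distributions(apply(tab$values, 1, shannon_index),
                      apply(gen$values, 1, shannon_index))

# augmented disease model vs original-only, on a held-out test set
sp <- train_test_split(tab$labels, 0.3, seed = 1)
tr <- otu_table(tab$values[sp$train, ], tab$sample_ids[sp$train], tab$otu_ids,
                labels = tab$labels[sp$train], mode = "relative")
te <- otu_table(tab$values[sp$test, ], tab$sample_ids[sp$test], tab$otu_ids,
                labels = tab$labels[sp$test], mode = "relative")
cnn <- cnn_config(epochs = 100, batch_size = 20, lr = 0.01, momentum = 0.9,
                  seed = 1)
m_orig <- train_disease_model(tr, sim$taxonomy, feature_space = "otu",
                              keep_other = TRUE, cnn = cnn, seed = 1)
m_aug  <- train_disease_model(tr, sim$taxonomy, generated = gen,
                              feature_space = "otu", keep_other = TRUE,
                              cnn = cnn, seed = 1)
binary_metrics(m_orig$predict(te), te$labels)$auc
binary_metrics(m_aug$predict(te),  te$labels)$auc
```

Output of this exact script (seeds included):

```
[1] 0.7472917          # sparsity of the real table
[1] 0.747125           # sparsity of the generated table
[1] 0.2336422          # Wilcoxon p, Shannon real vs generated (ns)
[1] 0.8288889          # held-out AUC, original-only model
[1] 0.8544444          # held-out AUC, augmented model
```

The generated table matches the real table's zero fraction to three
decimals, its Shannon-diversity distribution is not distinguishable
from the real one (rank-sum p = 0.23), and augmenting the 70-sample
training set with 100 + 100 synthetic samples lifts the held-out AUC
from 0.829 to 0.854.

`run_pipeline(pipeline_config(...), out_dir)` chains every stage
(simulate/read → GAN → generate → harmonize → classify → evaluate)
into a run directory with models, tables, a JSON report and a
manifest; `inst/cli/mbaugment.R` exposes the same stages as shell
subcommands (`simulate`, `train-gan`, `generate`, `harmonize`,
`train-classifier`, `predict`, `evaluate`, `run`,
`transfer-augment`).

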