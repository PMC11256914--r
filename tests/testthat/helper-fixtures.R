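# shared fixtures and fast training configs for the test suite

tiny_counts <- function() {
  otu_table(matrix(c(2, 2, 0, 4,
                     1, 0, 3, 0,
                     5, 5, 5, 5), nrow = 3, byrow = TRUE),
            sample_ids = c("s1", "s2", "s3"),
            otu_ids = c("g1", "g2", "g3", "g4"),
            labels = c(1, 0, 1), mode = "counts")
}

tiny_tax <- function(otu_ids = c("g1", "g2", "g3", "g4"),
                     phyla = c("Firmicutes", "Firmicutes",
                               "Proteobacteria", "Actinobacteria")) {
  taxonomy_map(stats::setNames(
    sprintf("k__Bacteria;p__%s;c__;o__;f__;g__%s", phyla, otu_ids), otu_ids))
}

# small labelled relative table drawn from the simulator
small_sim <- function(seed = 7, n = 30, p = 40, ...) {
  simulate_dataset(sim_config(n_cases = n, n_controls = n, n_otus = p,
                              seed = seed, ...))
}

fast_gan <- function(p, seed = 1, epochs = 10, ...) {
  gan_config(feature_dim = p, epochs = epochs, batch_size = 10,
             momentum = 0.9, hidden_dims_g = c(32, 64),
             hidden_dims_d = c(64, 32), noise_dim = 16, seed = seed, ...)
}

fast_cnn <- function(seed = 1, epochs = 10, ...) {
  cnn_config(epochs = epochs, batch_size = 10, lr = 0.01, momentum = 0.9,
             seed = seed, ...)
}

subset_table <- function(t, idx) {
  otu_table(t$values[idx, , drop = FALSE], t$sample_ids[idx], t$otu_ids,
            labels = t$labels[idx], mode = t$mode)
}
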