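# Shared seeded benchmark for the heavier end-to-end tests. One
# simulated cohort per seed is split into a large cohort A (100 cases +
# 100 controls; GAN training and realism checks) and a small sibling
# cohort B (20 + 20; transfer workflow), and the trained GAN plus a
# generated draw are cached so several tests can reuse them.

.bench_cache <- new.env(parent = emptyenv())

bench_gan_config <- function(seed) {
  gan_config(feature_dim = 120L, epochs = 150L, batch_size = 20L,
             momentum = 0.9, seed = seed)
}

bench_run <- function(seed) {
  key <- paste0("s", seed)
  if (!is.null(.bench_cache[[key]])) return(.bench_cache[[key]])
  sim <- simulate_dataset(sim_config(n_cases = 120L, n_controls = 120L,
                                     n_otus = 120L, seed = seed))
  A <- subset_table(sim$table, c(1:100, 121:220))
  B <- subset_table(sim$table, c(101:120, 221:240))
  gan <- train_cgan(A, bench_gan_config(seed))
  gen <- sample_synthetic(gan, 100L, 100L, seed = seed + 500L)
  res <- list(A = A, B = B, tax = sim$taxonomy, truth = sim$truth,
              gan = gan, gen = gen)
  .bench_cache[[key]] <- res
  res
}
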