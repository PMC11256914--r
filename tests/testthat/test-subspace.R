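test_that("reconstruction_loss is the squared Euclidean norm", {
  expect_equal(reconstruction_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(reconstruction_loss(c(1, 0), c(0, 0)), 1)
  set.seed(8)
  for (i in 1:5) {
    a <- rnorm(50); b <- rnorm(50)
    expect_equal(reconstruction_loss(a, b), sum((a - b)^2), tolerance = 1e-12)
    # symmetric, zero iff equal
    expect_equal(reconstruction_loss(a, b), reconstruction_loss(b, a))
    expect_gt(reconstruction_loss(a, b), 0)
  }
  expect_error(reconstruction_loss(1:3, 1:4), "length mismatch")
})

test_that("pair_targets matches each real sample within its class", {
  sim <- small_sim(seed = 2)
  t <- sim$table
  # identical tables, nearest rule: every sample pairs with its own copy
  p <- pair_targets(t, t, rule = "nearest_within_class", seed = 1)
  expect_identical(p[, "generated"], p[, "real"])

  # hand case: nearest of three candidates wins
  real <- otu_table(matrix(c(0.5, 0.5), 1), "r1", c("a", "b"),
                    labels = 1, mode = "relative")
  gen <- otu_table(rbind(c(0.9, 0.1), c(0.55, 0.45), c(0.1, 0.9)),
                   paste0("g", 1:3), c("a", "b"),
                   labels = c(1, 1, 1), mode = "relative")
  expect_identical(pair_targets(real, gen)[1, "generated"], c(generated = 2L))

  # brute-force check on random data
  set.seed(5)
  g2 <- sample_synthetic(train_cgan(t, fast_gan(40, epochs = 2)), 20, 20, seed = 3)
  p2 <- pair_targets(t, g2)
  for (i in sample(nrow(t$values), 5)) {
    cls <- t$labels[i]
    cand <- which(g2$labels == cls)
    d <- colSums((t(g2$values[cand, , drop = FALSE]) - t$values[i, ])^2)
    expect_identical(p2[i, "generated"], c(generated = cand[which.min(d)]))
  }

  no_cases <- otu_table(matrix(c(0.2, 0.8), 1), "g9", c("a", "b"),
                        labels = 0, mode = "relative")
  expect_error(pair_targets(real, no_cases), "class 1")
})

test_that("train_subspace_ae is deterministic with a per-epoch loss log", {
  sim <- small_sim(seed = 4, n = 15, p = 30)
  t <- sim$table
  p <- pair_targets(t, t)
  m1 <- train_subspace_ae(t, t, p, latent_dim = 4, epochs = 1, seed = 9)
  expect_identical(nrow(m1$training_log), 1L)
  m2 <- train_subspace_ae(t, t, p, latent_dim = 4, epochs = 6, seed = 9)
  m3 <- train_subspace_ae(t, t, p, latent_dim = 4, epochs = 6, seed = 9)
  expect_identical(m2$encoder, m3$encoder)
  expect_identical(m2$decoder, m3$decoder)
  expect_error(train_subspace_ae(t, t, p, latent_dim = 30), "latent_dim")
  expect_error(train_subspace_ae(t, t, p, latent_dim = 1), "latent_dim")
  bad <- p[-1, , drop = FALSE]
  expect_error(train_subspace_ae(t, t, bad, latent_dim = 4), "pairing")
})

test_that("with generated = real the model trains as a plain autoencoder", {
  sim <- small_sim(seed = 6, n = 20, p = 30)
  t <- sim$table
  p <- pair_targets(t, t)
  m <- train_subspace_ae(t, t, p, latent_dim = 8, epochs = 200, lr = 0.05,
                         batch_size = 10, momentum = 0.9, seed = 11)
  loss <- m$training_log$mean_loss
  expect_lt(loss[length(loss)], 0.1 * loss[1])
  expect_lt(loss[length(loss)], loss[1])     # decreasing trend
})

test_that("encode returns latent features of the right shape", {
  sim <- small_sim(seed = 12, n = 10, p = 25)
  t <- sim$table
  m <- train_subspace_ae(t, t, pair_targets(t, t), latent_dim = 16,
                         epochs = 3, seed = 2)
  lat <- encode(m, t, origin = "real")
  expect_identical(dim(lat$features), c(20L, 16L))
  expect_identical(lat$origin, rep("real", 20))
  expect_identical(lat$labels, t$labels)
  expect_identical(encode(m, t)$features, lat$features)

  other <- t; other$otu_ids[1] <- "alien"
  colnames(other$values) <- other$otu_ids
  expect_error(encode(m, other), "alien")
})

test_that("build_augmented concatenates and preserves label multisets", {
  sim <- small_sim(seed = 13, n = 10, p = 25)
  t <- sim$table
  m <- train_subspace_ae(t, t, pair_targets(t, t), latent_dim = 4,
                         epochs = 2, seed = 3)
  a <- encode(m, t, "real")
  b <- encode(m, subset_table(t, 1:5), "generated")
  ab <- build_augmented(a, b)
  expect_identical(nrow(ab$features), 25L)
  expect_identical(sort(ab$labels), sort(c(a$labels, b$labels)))
  expect_identical(ab$origin, c(rep("real", 20), rep("generated", 5)))

  empty <- b; empty$features <- b$features[0, , drop = FALSE]
  empty$labels <- integer(0); empty$origin <- character(0)
  expect_identical(build_augmented(a, empty), a)
  wide <- b; wide$features <- cbind(b$features, 0)
  expect_error(build_augmented(a, wide), "width")
})

test_that("the common subspace draws real and generated data together", {
  sim <- small_sim(seed = 20, n = 40, p = 40)
  t <- sim$table
  gan <- train_cgan(t, fast_gan(40, epochs = 20, seed = 20))
  gen <- sample_synthetic(gan, 40, 40, seed = 21)
  ae <- train_subspace_ae(t, gen, pair_targets(t, gen), latent_dim = 8,
                          epochs = 60, lr = 0.05, batch_size = 10,
                          momentum = 0.9, seed = 22)
  lr_acc <- function(X, y) {
    set.seed(23)
    idx <- sample.int(nrow(X)); tr <- idx[1:112]; te <- setdiff(idx, tr)
    df <- data.frame(y = factor(y), X)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df[tr, ], family = binomial))
    p <- suppressWarnings(stats::predict(fit, df[te, ], type = "response"))
    mean((p > 0.5) == (y[te] == 1))
  }
  orig <- c(rep(1, 80), rep(0, 80))
  raw_acc <- lr_acc(rbind(t$values, gen$values), orig)
  lat_acc <- lr_acc(rbind(encode(ae, t, "real")$features,
                          encode(ae, gen, "generated")$features), orig)
  expect_lt(lat_acc, raw_acc + 0.05)   # latent never clearly easier to tell apart
})
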