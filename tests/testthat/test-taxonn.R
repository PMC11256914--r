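test_that("assign_phylum_clusters keeps the top-k phyla and overflows the rest", {
  ids <- sprintf("g%03d", 1:102)
  phy <- c(rep("Firmicutes", 50), rep("Proteobacteria", 30),
           rep("Actinobacteria", 20), rep("Fusobacteria", 2))
  tax <- tiny_tax(ids, phy)
  p3 <- suppressWarnings(assign_phylum_clusters(ids, tax, top_k = 3))
  expect_identical(names(p3$clusters),
                   c("Firmicutes", "Proteobacteria", "Actinobacteria"))
  expect_identical(lengths(p3$clusters),
                   c(Firmicutes = 50L, Proteobacteria = 30L, Actinobacteria = 20L))
  expect_identical(p3$overflow, 101:102)
  expect_warning(assign_phylum_clusters(ids, tax, top_k = 3), "minor phyla")

  p4 <- assign_phylum_clusters(ids, tax, top_k = 3, keep_other = TRUE)
  expect_identical(p4$clusters$other, 101:102)
  expect_identical(p4$overflow, integer(0))

  no_minor <- assign_phylum_clusters(ids[1:100], tiny_tax(ids[1:100], phy[1:100]), 3)
  expect_identical(no_minor$overflow, integer(0))
  expect_error(assign_phylum_clusters(c(ids, "gX"), tax), "gX")
})

test_that("cluster sizes match brute-force phylum counting", {
  set.seed(31)
  phy_pool <- c("Firmicutes", "Proteobacteria", "Actinobacteria",
                "Bacteroidetes", "Fusobacteria")
  phy <- sample(phy_pool, 80, replace = TRUE, prob = c(.4, .25, .2, .1, .05))
  ids <- sprintf("t%02d", 1:80)
  part <- suppressWarnings(assign_phylum_clusters(ids, tiny_tax(ids, phy), top_k = 3))
  counts <- sort(table(phy), decreasing = TRUE)
  for (nm in names(part$clusters)) {
    expect_identical(length(part$clusters[[nm]]), as.integer(counts[[nm]]))
    expect_true(all(phy[part$clusters[[nm]]] == nm))
  }
  got_all <- sort(unname(c(unlist(part$clusters), part$overflow)))
  expect_identical(got_all, 1:80)
})

test_that("spearman_matrix agrees with rank-then-Pearson", {
  x <- cbind(a = 1:6, b = c(2, 4, 6, 8, 10, 12))     # co-monotone
  expect_equal(spearman_matrix(x)[1, 2], 1)
  y <- cbind(a = 1:6, b = 6:1)                        # anti-monotone
  expect_equal(spearman_matrix(y)[1, 2], -1)

  set.seed(17)
  m <- matrix(rexp(20 * 5), 20, 5)
  m[sample(100, 30)] <- 0                             # heavy ties
  rho <- spearman_matrix(m)
  ranks <- apply(m, 2, rank)                          # average ranks
  expect_equal(rho, stats::cor(ranks), tolerance = 1e-10)
  expect_true(isSymmetric(rho))
  expect_equal(unname(diag(rho)), rep(1, 5))
  expect_error(spearman_matrix(m[1:2, ]), "3 samples")
})

test_that("a constant OTU gets correlation 0 by convention", {
  m <- cbind(a = rnorm(10), b = rep(0.3, 10), c = rnorm(10))
  rho <- spearman_matrix(m)
  expect_equal(rho["b", "a"], 0)
  expect_equal(rho["b", "c"], 0)
  expect_equal(rho["b", "b"], 1)
})

test_that("cumulative_correlation is the geometric mean of |rho| rows", {
  expect_equal(cumulative_correlation(matrix(1, 4, 4)), rep(1, 4))
  expect_equal(cumulative_correlation(diag(3)), rep(0, 3))
  rho <- rbind(c(1, 0.5, 0.5), c(0.5, 1, 0.5), c(0.5, 0.5, 1))
  expect_equal(cumulative_correlation(rho)[1], (1 * 0.5 * 0.5)^(1 / 3),
               tolerance = 1e-4)
  expect_error(cumulative_correlation(matrix(numeric(0), 0, 0)), "empty")
})

test_that("cumulative_correlation matches the product-root oracle on random matrices", {
  set.seed(91)
  for (i in 1:100) {
    p <- sample(2:20, 1)
    base <- matrix(rnorm(30 * p), 30, p)
    rho <- suppressWarnings(stats::cor(base, method = "spearman"))
    got <- cumulative_correlation(rho)
    want <- vapply(seq_len(p),
                   function(j) prod(abs(rho[j, ]))^(1 / p), numeric(1))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("cumulative_correlation commutes with symmetric permutations", {
  set.seed(14)
  base <- matrix(rnorm(40 * 8), 40, 8)
  rho <- stats::cor(base, method = "spearman")
  perm <- sample(8)
  expect_equal(cumulative_correlation(rho[perm, perm]),
               cumulative_correlation(rho)[perm], tolerance = 1e-12)
})

test_that("order_features sorts decreasing with stable ties", {
  expect_identical(order_features(c(0.2, 0.9, 0.5)), c(2L, 3L, 1L))
  expect_identical(order_features(rep(0.4, 5)), 1:5)
  set.seed(3)
  v <- sample(round(runif(100), 2))                   # some ties
  got <- order_features(v)
  want <- order(-v)                                   # radix: stable
  expect_identical(got, want)
  expect_true(all(diff(v[got]) <= 0))
  expect_error(order_features(c(1, NaN)), "finite")
  # idempotence: ordering an ordered vector is the identity
  expect_identical(order_features(v[got]), seq_along(v))
})

test_that("weighted_cross_entropy matches brute-force summation", {
  expect_equal(weighted_cross_entropy(0.5, 1, c(1, 1)), -log(0.5),
               tolerance = 1e-4)
  set.seed(77)
  for (i in 1:5) {
    p <- runif(16, 0.01, 0.99)
    y <- rbinom(16, 1, 0.5)
    w <- runif(2, 0.5, 2)
    want <- -mean(w[2] * y * log(p) + w[1] * (1 - y) * log(1 - p))
    expect_equal(weighted_cross_entropy(p, y, w), want, tolerance = 1e-12)
  }
  # balanced labels with unit weights reduce to plain cross-entropy
  p <- runif(10, .1, .9); y <- rep(c(0, 1), 5)
  expect_equal(weighted_cross_entropy(p, y),
               -mean(y * log(p) + (1 - y) * log(1 - p)), tolerance = 1e-12)
  expect_error(weighted_cross_entropy(numeric(0), integer(0)), "empty")
  expect_error(weighted_cross_entropy(p, y, c(-1, 1)), "positive")
})

test_that("train_ensemble builds one branch per cluster and is deterministic", {
  sim <- small_sim(seed = 41, n = 20, p = 40)
  part <- assign_phylum_clusters(sim$table$otu_ids, sim$taxonomy, 3,
                                 keep_other = TRUE)
  cfg <- fast_cnn(seed = 5, epochs = 4)
  m1 <- suppressWarnings(train_ensemble(sim$table$values, sim$table$labels, part, cfg))
  expect_length(m1$branches, 4L)
  expect_identical(nrow(m1$training_log), 4L)
  m2 <- suppressWarnings(train_ensemble(sim$table$values, sim$table$labels, part, cfg))
  expect_identical(m1$branches, m2$branches)
  expect_identical(m1$head_W, m2$head_W)
  expect_error(train_ensemble(sim$table$values, rep(1L, 40), part, cfg),
               "per class")
})

test_that("clusters narrower than the kernel fall back to a dense layer", {
  ids <- c(sprintf("a%02d", 1:12), "b1", "b2")
  tax <- tiny_tax(ids, c(rep("Firmicutes", 12), rep("Fusobacteria", 2)))
  part <- assign_phylum_clusters(ids, tax, top_k = 2)
  set.seed(9)
  x <- matrix(rexp(20 * 14), 20, 14, dimnames = list(NULL, ids))
  expect_warning(
    m <- train_ensemble(x, rep(c(0L, 1L), 10), part, fast_cnn(epochs = 2)),
    "dense layer")
  expect_identical(m$branches$Fusobacteria$type, "dense")
  expect_identical(m$branches$Firmicutes$type, "conv")
  p <- predict_proba(m, x)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("ensemble predictions are softmax probabilities and reproducible", {
  sim <- small_sim(seed = 43, n = 15, p = 40)
  part <- assign_phylum_clusters(sim$table$otu_ids, sim$taxonomy, 3,
                                 keep_other = TRUE)
  m <- suppressWarnings(train_ensemble(sim$table$values, sim$table$labels, part,
                                       fast_cnn(epochs = 3)))
  p1 <- predict_proba(m, sim$table$values)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, predict_proba(m, sim$table$values))
  expect_error(predict_proba(m, sim$table$values[, 1:10]), "mismatch")
})

test_that("the stratified CNN learns a strong planted effect", {
  sim <- simulate_dataset(sim_config(n_cases = 200, n_controls = 200,
                                     n_otus = 80, effect_log2fc = 2, seed = 44))
  t <- sim$table
  sp <- train_test_split(t$labels, 0.3, seed = 44)
  part <- assign_phylum_clusters(t$otu_ids, sim$taxonomy, 3, keep_other = TRUE)
  m <- suppressWarnings(train_ensemble(t$values[sp$train, ], t$labels[sp$train],
                                       part, fast_cnn(seed = 44, epochs = 40)))
  auc <- binary_metrics(predict_proba(m, t$values[sp$test, ]),
                        t$labels[sp$test])$auc
  expect_gt(auc, 0.85)
})

test_that("integrated gradients satisfy the axioms", {
  sim <- small_sim(seed = 45, n = 15, p = 30)
  part <- assign_phylum_clusters(sim$table$otu_ids, sim$taxonomy, 3,
                                 keep_other = TRUE)
  m <- suppressWarnings(train_ensemble(sim$table$values, sim$table$labels, part,
                                       fast_cnn(epochs = 5)))
  x <- sim$table$values[1, ]

  # sample = baseline -> zero attributions
  expect_equal(integrated_gradients(m, x, baseline = x, steps = 16),
               rep(0, 30), ignore_attr = TRUE)

  # completeness, and the residual shrinks as steps double
  f <- function(v) predict_proba(m, rbind(v))[1]
  target <- f(x) - f(numeric(30))
  resid <- vapply(c(64, 128), function(s) {
    abs(sum(integrated_gradients(m, x, steps = s)) - target)
  }, numeric(1))
  expect_lt(resid[2], abs(target) * 0.02 + 1e-8)
  expect_lte(resid[2], resid[1] + 1e-12)
  expect_error(integrated_gradients(m, x, steps = 4), ">= 8")
})

test_that("integrated gradients are exact for an effectively linear model", {
  # dense branch with positive weights and inputs stays in the ReLU's
  # linear region, so logit-space attributions obey the closed form
  ids <- c("u1", "u2", "u3")
  tax <- tiny_tax(ids, rep("Firmicutes", 3))
  part <- assign_phylum_clusters(ids, tax, top_k = 1)
  set.seed(2)
  x <- matrix(runif(40 * 3, 0.1, 1), 40, 3, dimnames = list(NULL, ids))
  m <- suppressWarnings(train_ensemble(x, rep(c(0L, 1L), 20), part,
                                       fast_cnn(epochs = 2, kernel_size = 5)))
  m$branches$Firmicutes$W <- abs(m$branches$Firmicutes$W)
  m$branches$Firmicutes$b <- abs(m$branches$Firmicutes$b)
  v <- c(0.5, 0.2, 0.9)
  base <- c(0.1, 0.1, 0.1)
  ig <- integrated_gradients(m, v, baseline = base, steps = 64,
                             output = "logit")
  # effective linear weights of the logit difference
  Wb <- m$branches$Firmicutes$W
  wlin <- Wb %*% (m$head_W[, 2] - m$head_W[, 1])
  want <- (v - base) * drop(wlin)[match(1:3, m$ordered_cols$Firmicutes)]
  expect_equal(ig, unname(want), tolerance = 1e-8)
})
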