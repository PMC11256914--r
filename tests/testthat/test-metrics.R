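test_that("sparsity counts zero fractions per sample", {
  t <- otu_table(rbind(c(0, 0, 1, 3), c(0, 0, 0, 0), c(1, 1, 1, 1)))
  s <- sparsity(t)
  expect_equal(s$per_sample, c(0.5, 1, 0), ignore_attr = TRUE)
  expect_equal(s$mean, 0.5)
  expect_equal(s$range, c(0, 1))
  set.seed(4)
  m <- matrix(rbinom(200, 1, 0.3) * runif(200), 20, 10)
  expect_equal(sparsity(otu_table(m))$per_sample,
               apply(m, 1, function(r) sum(r == 0) / 10), ignore_attr = TRUE)
  expect_error(sparsity(matrix(numeric(0), 0, 0)), "empty")
})

test_that("shannon_index has its closed-form values", {
  expect_equal(shannon_index(rep(0.25, 4)), log(4), tolerance = 1e-4)
  expect_equal(shannon_index(c(1, 0, 0)), 0)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.0397, tolerance = 1e-4)
  # zero-padding invariance and maximality at uniform
  expect_equal(shannon_index(c(rep(0.25, 4), 0, 0)), shannon_index(rep(0.25, 4)))
  set.seed(6)
  x <- runif(8); x <- x / sum(x)
  expect_lte(shannon_index(x), log(8))
  expect_error(shannon_index(c(-0.1, 1.1)), "negative")
  expect_error(shannon_index(c(0.5, 0.4)), "sum to 1")
})

test_that("chao1_index implements the bias-corrected estimator", {
  # S_obs = 10, F1 = 4, F2 = 2 -> 10 + 4*3/6 = 12
  counts <- c(rep(1, 4), rep(2, 2), rep(5, 4))
  expect_equal(chao1_index(counts), 12)
  expect_equal(chao1_index(c(0, 3, 3, 7)), 3)         # no singletons
  expect_equal(chao1_index(rep(0, 5)), 0)
  set.seed(8)
  for (i in 1:10) {
    x <- rpois(50, 1)
    expect_gte(chao1_index(x), sum(x > 0))            # never below richness
  }
  expect_error(chao1_index(c(0.5, 0.5)), "as_counts")
  expect_equal(chao1_index(c(0.5, 0.5), as_counts = TRUE, depth = 10),
               chao1_index(c(5, 5)))
})

test_that("compare_distributions is a two-sided rank-sum test", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7)
  expect_equal(compare_distributions(x, x), 1.0)
  expect_identical(compare_distributions(x, x * 2),
                   compare_distributions(x * 2, x))     # symmetric
  a <- 1:20; b <- 101:120
  expect_lt(compare_distributions(a, b), 0.001)
  # agrees with an explicit permutation test on small samples
  set.seed(10)
  for (i in 1:3) {
    a <- rnorm(15); b <- rnorm(15, 0.5)
    got <- compare_distributions(a, b)
    stat <- function(aa, bb) sum(rank(c(aa, bb))[seq_along(aa)])
    obs <- stat(a, b)
    perm <- replicate(4000, {
      z <- sample(c(a, b)); stat(z[1:15], z[16:30])
    })
    p_perm <- mean(abs(perm - mean(perm)) >= abs(obs - mean(perm)))
    expect_lt(abs(got - p_perm), 0.02)
  }
  expect_error(compare_distributions(numeric(0), 1:3), "empty")
})

test_that("binary_metrics computes rank AUC and threshold metrics", {
  expect_equal(binary_metrics(c(.9, .8, .7, .3, .2, .1),
                              c(1, 1, 1, 0, 0, 0))$auc, 1)
  expect_equal(suppressWarnings(binary_metrics(rep(0.5, 10), rep(c(0, 1), 5))$auc),
               0.5)
  # exhaustive pair counting: wins 3 + 3 + 2 of the 9 case/control pairs
  m <- binary_metrics(c(.9, .8, .4, .7, .3, .2), c(1, 1, 1, 0, 0, 0))
  expect_equal(m$auc, 8 / 9, tolerance = 1e-4)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$ppv, 2 / 3)
  expect_equal(m$npv, 2 / 3)
  expect_error(binary_metrics(runif(4), rep(1, 4)), "both classes")
  expect_warning(binary_metrics(c(.9, .8, .7), c(1, 1, 0), threshold = 0.5),
                 "NPV undefined")
})

test_that("AUC matches exhaustive pair counting with ties", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(round(runif(n), 1))                   # many ties
    got <- binary_metrics(s, y)$auc
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(got, mean(cmp), tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(13)
  y <- rbinom(40, 1, 0.5); s <- runif(40)
  roc <- suppressMessages(pROC::roc(y, s, direction = "<", levels = c(0, 1)))
  expect_equal(binary_metrics(s, y)$auc, as.numeric(pROC::auc(roc)),
               tolerance = 1e-10)
})

test_that("train_test_split stratifies and reproduces", {
  y <- rep(c(0L, 1L), each = 50)
  sp <- train_test_split(y, 0.3, seed = 5)
  expect_length(sp$test, 30)
  expect_length(sp$train, 70)
  expect_equal(sum(y[sp$test] == 1), 15)
  expect_equal(sum(y[sp$train] == 1), 35)
  expect_identical(sp, train_test_split(y, 0.3, seed = 5))
  expect_identical(sort(c(sp$train, sp$test)), seq_along(y))  # multiset union
  expect_error(train_test_split(y, 0), "test_fraction")
  expect_error(train_test_split(c(0L, rep(1L, 20)), 0.3), "empty")
})

test_that("cross_validate runs stratified repeats and percentile CIs", {
  set.seed(20)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 5), n, 5)
  x[, 1] <- x[, 1] + y                                # separable-ish
  fit_lm <- function(xt, yt, seed) {
    b <- stats::coef(stats::lm(yt ~ xt))
    function(xs) drop(cbind(1, xs) %*% b)
  }
  cv <- cross_validate(x, y, fit_lm, n_repeats = 2, n_folds = 5, seed = 3)
  expect_length(cv$auc_values, 10)
  expect_identical(cv$report$n_cv_values, 10L)
  expect_gte(cv$report$auc_ci[1], min(cv$auc_values))
  expect_lte(cv$report$auc, cv$report$auc_ci[2])
  expect_gt(cv$report$auc, 0.5)
  expect_error(cross_validate(x, y, fit_lm, n_folds = 40), "n_folds")
})

test_that("fold assignment is exactly stratified", {
  y <- rep(c(0L, 1L), each = 25)
  x <- matrix(rnorm(50 * 2), 50, 2)
  seen <- new.env()
  fit_probe <- function(xt, yt, seed) {
    # each training fold must hold 4/5 of both classes
    expect_identical(sum(yt == 1L), 20L)
    expect_identical(sum(yt == 0L), 20L)
    function(xs) {
      expect_identical(nrow(xs), 10L)
      rep(0.5, nrow(xs))
    }
  }
  suppressWarnings(
    cross_validate(x, y, fit_probe, n_repeats = 1, n_folds = 5, seed = 2))
  succeed()
})
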