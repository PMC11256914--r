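#' Per-sample sparsity
#'
#' The proportion of zero entries in each sample's OTU vector, with its
#' mean and min/max across samples — the first realism diagnostic for
#' generated data.
#'
#' @param t an [otu_table].
#' @return List with `mean`, `range = c(lo, hi)` and the `per_sample`
#'   vector.
#' @export
sparsity <- function(t) {
  m <- if (inherits(t, "otu_table")) t$values else as.matrix(t)
  if (!length(m)) stop("empty table")
  per <- rowMeans(m == 0)
  list(mean = mean(per), range = c(min(per), max(per)), per_sample = per)
}

#' Shannon diversity index
#'
#' `-sum(x * log(x))` over the nonzero entries of one relative-abundance
#' vector (natural log); zero for a single-taxon sample, maximal
#' (`log(k)`) at the uniform composition over k taxa.
#'
#' @param sample nonnegative vector summing to 1 within 1e-6.
#' @return Nonnegative scalar.
#' @export
shannon_index <- function(sample) {
  sample <- as.numeric(sample)
  if (any(sample < 0)) stop("negative abundances")
  if (abs(sum(sample) - 1) > 1e-6) stop("sample must sum to 1 (relative mode)")
  x <- sample[sample > 0]
  -sum(x * log(x))
}

#' Bias-corrected Chao1 richness estimator
#'
#' `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))` where `F1`/`F2` are the
#' singleton and doubleton counts of one sample's count vector. Always
#' at least the observed richness. Requires counts: relative abundances
#' can be converted with `as_counts` (times a sequencing `depth`,
#' rounded), since richness based on singletons is undefined on
#' proportions.
#'
#' @param sample nonnegative integer vector (or numeric with
#'   `as_counts = TRUE`).
#' @param as_counts convert a relative-abundance vector to counts first.
#' @param depth conversion depth used when `as_counts = TRUE`.
#' @return Estimated richness (0 for an all-zero sample).
#' @export
chao1_index <- function(sample, as_counts = FALSE, depth = 10000L) {
  sample <- as.numeric(sample)
  if (any(sample < 0)) stop("negative abundances")
  if (as_counts) sample <- round(sample * depth)
  if (any(sample != round(sample))) {
    stop("chao1_index needs integer counts; for relative abundances call ",
         "with as_counts = TRUE (values are multiplied by `depth` and rounded)")
  }
  s_obs <- sum(sample > 0)
  if (s_obs == 0L) return(0)
  f1 <- sum(sample == 1)
  f2 <- sum(sample == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Compares two independent samples (e.g. per-sample Shannon indices of
#' real vs generated data): exact p-value for small untied samples,
#' normal approximation with tie correction otherwise.
#'
#' @param a,b nonempty numeric vectors.
#' @return The two-sided p-value.
#' @export
compare_distributions <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty input")
  use_exact <- max(length(a), length(b)) <= 20 && !any(duplicated(c(a, b)))
  stats::wilcox.test(a, b, exact = use_exact, correct = FALSE)$p.value
}

#' Threshold classification metrics with rank-based AUC
#'
#' AUC by the Mann-Whitney rank formula with average-rank tie
#' correction; sensitivity, specificity, PPV and NPV at the given
#' probability threshold. Ratios with a zero denominator are reported
#' as `NaN` with a warning.
#'
#' @param probs class-1 scores/probabilities.
#' @param labels 0/1 vector containing both classes.
#' @param threshold decision threshold on the class-1 score.
#' @return A `metrics_report` list: `auc`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `threshold`.
#' @export
binary_metrics <- function(probs, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(probs) != length(labels)) stop("probs/labels length mismatch")
  if (length(unique(labels)) < 2L) stop("labels must contain both classes")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0,1)")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  r <- rank(probs)                            # average ranks handle ties
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1L & labels == 1L); fn <- n1 - tp
  tn <- sum(pred == 0L & labels == 0L); fp <- n0 - tn
  safe_div <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator)"); return(NaN) }
    num / den
  }
  structure(list(auc = auc,
                 sensitivity = safe_div(tp, tp + fn, "sensitivity"),
                 specificity = safe_div(tn, tn + fp, "specificity"),
                 ppv = safe_div(tp, tp + fp, "PPV"),
                 npv = safe_div(tn, tn + fn, "NPV"),
                 threshold = threshold),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("AUC %.3f | sens %.3f spec %.3f | PPV %.3f NPV %.3f (thr %.2f)\n",
              x$auc, x$sensitivity, x$specificity, x$ppv, x$npv, x$threshold))
  if (!is.null(x$auc_ci)) {
    cat(sprintf("mean AUC %.3f, 95%% CI [%.3f, %.3f] over %d CV values\n",
                x$auc, x$auc_ci[1], x$auc_ci[2], x$n_cv_values))
  }
  invisible(x)
}

# stratified fold assignment: per class, shuffled round-robin
.stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Stratified train/test split
#'
#' Splits indices into disjoint stratified train and test sets (default
#' 70/30), reproducible by seed.
#'
#' @param labels 0/1 vector.
#' @param test_fraction fraction of each class held out, in (0,1).
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
train_test_split <- function(labels, test_fraction = 0.3, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie in (0,1)")
  }
  labels <- as.integer(labels)
  set.seed(seed)
  test <- integer(0)
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    n_test <- round(length(idx) * test_fraction)
    if (n_test == 0L || n_test == length(idx)) {
      stop("split leaves class ", cls, " empty on one side")
    }
    test <- c(test, sample(idx, n_test))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Repeated stratified cross-validation
#'
#' Runs `n_repeats` rounds of `n_folds`-fold stratified CV (defaults
#' 10 x 10, i.e. 100 AUC values). `fit_fun(x_train, y_train, seed)` must
#' return a prediction function `function(x_test) -> class-1 scores`;
#' any augmentation (GAN / autoencoder fitting) must happen inside
#' `fit_fun` so that generated samples never enter validation folds.
#' The 95% CI is the empirical 2.5/97.5 percentile of the AUC values
#' (linear-interpolation quantiles, R type 7).
#'
#' @param x feature matrix.
#' @param labels 0/1 vector with at least `n_folds` samples per class.
#' @param fit_fun model-fitting closure (see above).
#' @param n_repeats,n_folds CV schedule (defaults 10 and 10).
#' @param seed integer seed; each repeat and fold derives its own.
#' @param threshold decision threshold for the point metrics.
#' @return List with `auc_values` (length `n_repeats * n_folds`) and
#'   `report` (a `metrics_report` with `auc_ci` and mean fold metrics).
#' @export
cross_validate <- function(x, labels, fit_fun, n_repeats = 10L, n_folds = 10L,
                           seed = 1L, threshold = 0.5) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (min(table(factor(labels, levels = 0:1))) < n_folds) {
    stop("need at least n_folds samples per class for stratified CV")
  }
  aucs <- numeric(0)
  fold_metrics <- list()
  for (r in seq_len(n_repeats)) {
    set.seed(seed + 1000L * r)
    fold <- .stratified_folds(labels, n_folds)
    for (k in seq_len(n_folds)) {
      tr <- which(fold != k); te <- which(fold == k)
      predictor <- fit_fun(x[tr, , drop = FALSE], labels[tr],
                           seed = seed + 1000L * r + k)
      pr <- predictor(x[te, , drop = FALSE])
      m <- suppressWarnings(binary_metrics(pr, labels[te], threshold))
      aucs <- c(aucs, m$auc)
      fold_metrics[[length(fold_metrics) + 1L]] <- m
    }
  }
  ci <- stats::quantile(aucs, c(0.025, 0.975), names = FALSE, type = 7)
  mean_of <- function(f) mean(vapply(fold_metrics, `[[`, numeric(1), f), na.rm = TRUE)
  report <- structure(list(
    auc = mean(aucs),
    sensitivity = mean_of("sensitivity"), specificity = mean_of("specificity"),
    ppv = mean_of("ppv"), npv = mean_of("npv"), threshold = threshold,
    auc_ci = ci, n_cv_values = length(aucs)
  ), class = "metrics_report")
  list(auc_values = aucs, report = report)
}
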