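#' Stratify OTUs into phylum clusters
#'
#' Assigns every OTU to a cluster named after its phylum. The `top_k`
#' phyla holding the most OTUs become clusters (ties broken by phylum
#' name); all remaining OTUs form an overflow group, which becomes an
#' extra `"other"` cluster when `keep_other = TRUE` and is otherwise
#' excluded from the model with a warning.
#'
#' @param otu_ids character vector of OTU ids (column order of the table).
#' @param tax a [taxonomy_map] covering every id.
#' @param top_k number of major phyla to keep as clusters (default 3).
#' @param keep_other promote the overflow group to its own cluster.
#' @return A `phylum_partition`: `clusters` (named list of integer
#'   column indices, largest phylum first) and `overflow` indices.
#' @export
assign_phylum_clusters <- function(otu_ids, tax, top_k = 3L, keep_other = FALSE) {
  phy <- phylum_of(tax, otu_ids)
  counts <- table(phy)
  ord <- order(-as.integer(counts), names(counts))   # size desc, name ties
  major <- names(counts)[ord][seq_len(min(top_k, length(counts)))]
  clusters <- lapply(major, function(ph) which(phy == ph))
  names(clusters) <- major
  overflow <- which(!(phy %in% major))
  if (length(overflow)) {
    if (keep_other) {
      clusters$other <- overflow
      overflow <- integer(0)
    } else {
      warning(length(overflow), " OTU(s) in minor phyla excluded from the model (",
              paste(unique(phy[overflow]), collapse = ", "),
              "); set keep_other = TRUE to keep them")
    }
  }
  structure(list(clusters = clusters, overflow = overflow,
                 otu_ids = otu_ids),
            class = "phylum_partition")
}

#' Spearman correlation matrix of a cluster
#'
#' Rank correlation among the OTU columns of one phylum cluster, with
#' average ranks for ties. A constant column (zero rank variance) gets
#' correlation 0 with every other OTU by convention, so that the
#' cumulative coefficient annihilates uninformative features instead of
#' propagating NAs.
#'
#' @param t an [otu_table] with at least 3 samples, or a numeric matrix.
#' @param cluster integer column indices of the cluster (size >= 1).
#' @return Symmetric p x p matrix, unit diagonal, entries in [-1, 1].
#' @export
spearman_matrix <- function(t, cluster = NULL) {
  m <- if (inherits(t, "otu_table")) t$values else as.matrix(t)
  if (!is.null(cluster)) m <- m[, cluster, drop = FALSE]
  if (nrow(m) < 3L) stop("need at least 3 samples for rank correlations")
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  if (anyNA(rho)) {
    rho[is.na(rho)] <- 0
    diag(rho) <- 1
  }
  rho
}

#' Cumulative correlation coefficient per OTU
#'
#' Reduces each row of a cluster's Spearman matrix to a single score:
#' the geometric mean of the absolute correlations of that OTU with all
#' p cluster members (the unit self-term included),
#' `(prod_k |rho_jk|)^(1/p)`. Any exact-zero correlation annihilates the
#' row's score.
#'
#' @param rho symmetric correlation matrix with unit diagonal.
#' @return Numeric vector of length `ncol(rho)`.
#' @export
cumulative_correlation <- function(rho) {
  rho <- as.matrix(rho)
  p <- ncol(rho)
  if (p == 0L) stop("empty correlation matrix")
  a <- abs(rho)
  # geometric mean via logs; log(0) = -Inf -> exp(-Inf) = 0 as required
  exp(rowMeans(log(a)))
}

#' Decreasing-order feature permutation
#'
#' Stable permutation putting cumulative correlation coefficients in
#' non-increasing order; ties keep their original relative order. The
#' cluster's data columns (and its correlation heatmap) are re-indexed
#' by this permutation before entering the CNN, so correlated OTUs sit
#' next to each other.
#'
#' @param coeffs finite numeric vector.
#' @return Integer permutation of `seq_along(coeffs)`.
#' @export
order_features <- function(coeffs) {
  if (anyNA(coeffs) || any(!is.finite(coeffs))) stop("coefficients must be finite")
  order(-coeffs)                            # radix order is stable
}

#' Weighted binary cross-entropy
#'
#' `-mean(w1 * y * log(p) + w0 * (1-y) * log(1-p))` with probabilities
#' clamped to `[1e-7, 1-1e-7]`. Default class weights are inversely
#' proportional to the class frequencies, normalized so `w0 + w1 = 2`,
#' which reduces to the unweighted loss on balanced labels.
#'
#' @param probs predicted class-1 probabilities.
#' @param labels 0/1 vector.
#' @param class_weights length-2 positive vector `(w0, w1)`, or `NULL`
#'   for the inverse-frequency default.
#' @return Nonnegative scalar.
#' @export
weighted_cross_entropy <- function(probs, labels, class_weights = NULL) {
  if (!length(probs)) stop("empty batch")
  if (length(probs) != length(labels)) stop("probs/labels length mismatch")
  if (is.null(class_weights)) class_weights <- .inverse_freq_weights(labels)
  if (length(class_weights) != 2L || any(class_weights <= 0)) {
    stop("class_weights must be two positive numbers (w0, w1)")
  }
  p <- .clamp_prob(probs)
  y <- as.numeric(labels)
  -mean(class_weights[2L] * y * log(p) + class_weights[1L] * (1 - y) * log(1 - p))
}

.inverse_freq_weights <- function(labels) {
  n <- length(labels); n1 <- sum(labels == 1L); n0 <- n - n1
  if (n0 == 0L || n1 == 0L) return(c(1, 1))
  w <- c(n / (2 * n0), n / (2 * n1))
  2 * w / sum(w)
}

#' CNN ensemble configuration
#'
#' @param epochs,batch_size,lr,momentum SGD schedule (defaults 400 / 5 /
#'   0.001, the study protocol).
#' @param n_filters convolution filters per cluster (default 32).
#' @param kernel_size convolution width (default 5); clusters narrower
#'   than the kernel fall back to a dense layer.
#' @param stride convolution stride (default 1).
#' @param pool_size max-pooling width (default 2).
#' @param class_weights optional `(w0, w1)`; `NULL` = inverse frequency.
#' @param seed integer seed.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(epochs = 400L, batch_size = 5L, lr = 0.001,
                       momentum = 0, n_filters = 32L, kernel_size = 5L,
                       stride = 1L, pool_size = 2L, class_weights = NULL,
                       seed = 1L) {
  if (stride != 1L) stop("only stride 1 is supported")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, momentum = momentum, n_filters = as.integer(n_filters),
                 kernel_size = as.integer(kernel_size), stride = 1L,
                 pool_size = as.integer(pool_size), class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "cnn_config")
}

# ---- 1D conv branch internals ------------------------------------------

# patch matrix for stride-1 convolution: (b*L) x k, position-major blocks
.conv_patches <- function(Xc, k) {
  b <- nrow(Xc); L <- ncol(Xc) - k + 1L
  P <- matrix(0, b * L, k)
  for (j in seq_len(L)) {
    P[((j - 1L) * b + 1L):(j * b), ] <- Xc[, j:(j + k - 1L), drop = FALSE]
  }
  P
}

.branch_init <- function(p, cfg) {
  k <- cfg$kernel_size; f <- cfg$n_filters
  if (p < k) {
    list(type = "dense", p = p,
         W = matrix(stats::rnorm(p * f, sd = sqrt(2 / p)), p, f),
         b = numeric(f), out_dim = f)
  } else {
    L <- p - k + 1L
    L2 <- if (L >= cfg$pool_size) L %/% cfg$pool_size else L
    list(type = "conv", p = p, L = L, L2 = L2,
         W = matrix(stats::rnorm(k * f, sd = sqrt(2 / k)), k, f),
         b = numeric(f), out_dim = L2 * f)
  }
}

# pooled-pair row indices for a position-major (b*L) x f activation
.pool_rows <- function(b, L2, ps) {
  j <- rep((seq_len(L2) - 1L) * ps, each = b)       # leading position of pool
  i <- rep(seq_len(b), L2)
  cbind(r1 = j * b + i, r2 = (j + 1L) * b + i)
}

# forward through one conv (or dense-fallback) branch; activations kept
# in position-major (b*L) x n_filters matrices to avoid array copies.
# `P` may carry precomputed convolution patches for this batch.
.branch_forward <- function(br, Xc, cfg, cache = FALSE, P = NULL) {
  if (br$type == "dense") {
    Z <- Xc %*% br$W + rep(br$b, each = nrow(Xc))
    A <- (Z > 0) * Z
    if (cache) return(list(out = A, A = A, Xc = Xc))
    return(A)
  }
  b <- nrow(Xc); L <- br$L; L2 <- br$L2; ps <- cfg$pool_size
  if (is.null(P)) P <- .conv_patches(Xc, cfg$kernel_size)
  Z <- P %*% br$W + rep(br$b, each = nrow(P))
  A <- (Z > 0) * Z                           # (b*L) x f, position-major
  if (L >= ps) {
    pr <- .pool_rows(b, L2, ps)
    A1 <- A[pr[, 1L], , drop = FALSE]
    A2 <- A[pr[, 2L], , drop = FALSE]
    mask1 <- A1 >= A2
    pooled <- A1 * mask1 + A2 * !mask1       # (b*L2) x f
  } else {
    pr <- NULL; mask1 <- NULL; pooled <- A
  }
  out <- matrix(pooled, b, br$out_dim)
  if (cache) list(out = out, A = A, pr = pr, mask1 = mask1, P = P, Xc = Xc)
  else out
}

# returns parameter grads and (optionally) gradient wrt branch input
.branch_backward <- function(br, cache, dout, cfg, want_dx = FALSE) {
  f <- cfg$n_filters
  if (br$type == "dense") {
    dZ <- dout * (cache$A > 0)
    return(list(dW = crossprod(cache$Xc, dZ), db = colSums(dZ),
                dX = if (want_dx) tcrossprod(dZ, br$W) else NULL))
  }
  b <- nrow(cache$Xc); L <- br$L; L2 <- br$L2
  dpool <- matrix(dout, b * L2, f)
  if (!is.null(cache$pr)) {
    dA <- matrix(0, b * L, f)
    dA[cache$pr[, 1L], ] <- dpool * cache$mask1
    dA[cache$pr[, 2L], ] <- dpool * !cache$mask1
  } else {
    dA <- dpool
  }
  dZ <- dA * (cache$A > 0)
  dW <- crossprod(cache$P, dZ)
  db <- colSums(dZ)
  dX <- NULL
  if (want_dx) {
    dP <- tcrossprod(dZ, br$W)               # (b*L) x k
    dX <- matrix(0, b, br$p)
    k <- cfg$kernel_size
    for (j in seq_len(L)) {
      rows <- ((j - 1L) * b + 1L):(j * b)
      dX[, j:(j + k - 1L)] <- dX[, j:(j + k - 1L)] + dP[rows, , drop = FALSE]
    }
  }
  list(dW = dW, db = db, dX = dX)
}

# ---- ensemble -----------------------------------------------------------

#' Train the phylum-stratified CNN ensemble
#'
#' One 1D CNN per phylum cluster (convolution, ReLU, max-pooling,
#' flatten); within each cluster the OTU columns are first re-ordered by
#' decreasing cumulative Spearman correlation ([cumulative_correlation]
#' / [order_features]) so correlated OTUs are adjacent. The flattened
#' branch outputs are concatenated and passed through one fully
#' connected layer with a 2-class softmax; the whole ensemble is trained
#' end-to-end with SGD on the weighted cross-entropy. Clusters narrower
#' than the kernel bypass convolution through a dense layer (warning).
#'
#' @param x numeric matrix (samples x features) — OTU relative
#'   abundances or latent features.
#' @param labels 0/1 vector (both classes, >= 2 samples each).
#' @param partition a [phylum_partition] over the columns of `x`, or
#'   `NULL` to treat all columns as a single cluster.
#' @param cfg a [cnn_config].
#' @return An `ensemble_model` storing per-cluster orderings, branch and
#'   head parameters, class weights and a training log.
#' @export
train_ensemble <- function(x, labels, partition = NULL, cfg = cnn_config()) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x)) stop("labels length must match rows of x")
  if (min(table(factor(labels, levels = 0:1))) < 2L) {
    stop("need at least 2 samples per class")
  }
  clusters <- if (is.null(partition)) list(all = seq_len(ncol(x)))
              else partition$clusters
  if (!length(clusters)) stop("partition has no clusters")

  set.seed(cfg$seed)
  # per-cluster correlation ordering (computed on training data only)
  ordered_cols <- list(); coeffs_list <- list()
  for (nm in names(clusters)) {
    cols <- clusters[[nm]]
    rho <- spearman_matrix(x[, cols, drop = FALSE])
    cc <- cumulative_correlation(rho)
    perm <- order_features(cc)
    ordered_cols[[nm]] <- cols[perm]
    coeffs_list[[nm]] <- cc[perm]
  }
  branches <- list()
  for (nm in names(clusters)) {
    br <- .branch_init(length(ordered_cols[[nm]]), cfg)
    if (br$type == "dense") {
      warning("cluster '", nm, "' (", br$p, " features) is narrower than the ",
              "kernel; using a dense layer instead of convolution")
    }
    branches[[nm]] <- br
  }
  D <- sum(vapply(branches, `[[`, numeric(1), "out_dim"))
  head_W <- matrix(stats::rnorm(D * 2L, sd = sqrt(1 / D)), D, 2L)
  head_b <- numeric(2L)
  cw <- if (is.null(cfg$class_weights)) .inverse_freq_weights(labels) else cfg$class_weights

  vel <- list(head_W = head_W * 0, head_b = head_b * 0,
              br = lapply(branches, function(b) list(W = b$W * 0, b = b$b * 0)))
  n <- nrow(x)
  # precompute convolution patches over the full data; batches slice rows
  P_full <- list()
  for (nm in names(branches)) {
    if (branches[[nm]]$type == "conv") {
      P_full[[nm]] <- .conv_patches(x[, ordered_cols[[nm]], drop = FALSE],
                                    cfg$kernel_size)
    }
  }
  Y <- .one_hot(labels)
  loss_log <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    acc <- 0; nb <- 0L
    for (idx in .batches(n, cfg$batch_size)) {
      b_n <- length(idx)
      caches <- list(); H <- NULL
      for (nm in names(branches)) {
        br <- branches[[nm]]
        Pb <- if (br$type == "conv") {
          P_full[[nm]][as.vector(outer(idx, (seq_len(br$L) - 1L) * n, "+")), ,
                       drop = FALSE]
        }
        cc <- .branch_forward(br, x[idx, ordered_cols[[nm]], drop = FALSE],
                              cfg, cache = TRUE, P = Pb)
        caches[[nm]] <- cc
        H <- if (is.null(H)) cc$out else cbind(H, cc$out)
      }
      logits <- H %*% head_W + rep(head_b, each = b_n)
      Pm <- .softmax_rows(logits)
      yb <- labels[idx]
      w_i <- cw[yb + 1L]
      acc <- acc + weighted_cross_entropy(Pm[, 2L], yb, cw); nb <- nb + 1L
      dlogits <- (Pm - Y[idx, , drop = FALSE]) * w_i / b_n
      dHW <- crossprod(H, dlogits); dHb <- colSums(dlogits)
      dH <- tcrossprod(dlogits, head_W)
      off <- 0L
      for (nm in names(branches)) {
        br <- branches[[nm]]
        dout <- dH[, (off + 1L):(off + br$out_dim), drop = FALSE]
        off <- off + br$out_dim
        g <- .branch_backward(br, caches[[nm]], dout, cfg)
        vel$br[[nm]]$W <- cfg$momentum * vel$br[[nm]]$W + g$dW
        vel$br[[nm]]$b <- cfg$momentum * vel$br[[nm]]$b + g$db
        branches[[nm]]$W <- br$W - cfg$lr * vel$br[[nm]]$W
        branches[[nm]]$b <- br$b - cfg$lr * vel$br[[nm]]$b
      }
      vel$head_W <- cfg$momentum * vel$head_W + dHW
      vel$head_b <- cfg$momentum * vel$head_b + dHb
      head_W <- head_W - cfg$lr * vel$head_W
      head_b <- head_b - cfg$lr * vel$head_b
    }
    loss_log[epoch] <- acc / nb
  }
  structure(list(branches = branches, head_W = head_W, head_b = head_b,
                 ordered_cols = ordered_cols, coeffs = coeffs_list,
                 class_weights = cw, config = cfg, n_features = ncol(x),
                 feature_names = colnames(x),
                 training_log = data.frame(epoch = seq_len(cfg$epochs),
                                           loss = loss_log)),
            class = "ensemble_model")
}

.ensemble_forward <- function(model, x, cache = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) != model$n_features) {
    stop("feature layout mismatch: model expects ", model$n_features,
         " features, got ", ncol(x))
  }
  caches <- list(); H <- NULL
  for (nm in names(model$branches)) {
    cc <- .branch_forward(model$branches[[nm]], x[, model$ordered_cols[[nm]], drop = FALSE],
                          model$config, cache = cache)
    if (cache) { caches[[nm]] <- cc; out <- cc$out } else out <- cc
    H <- if (is.null(H)) out else cbind(H, out)
  }
  logits <- H %*% model$head_W + rep(model$head_b, each = nrow(x))
  P <- .softmax_rows(logits)
  if (cache) list(P = P, logits = logits, H = H, caches = caches) else P
}

#' Predict class-1 probabilities from a trained ensemble
#'
#' Re-applies the stored per-cluster orderings and branch/head
#' parameters; the two softmax outputs per sample sum to 1.
#'
#' @param model an `ensemble_model`.
#' @param x feature matrix with the training layout.
#' @return Numeric vector of class-1 probabilities.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "ensemble_model"))
  .ensemble_forward(model, x)[, 2L]
}

# gradient of the chosen output wrt the input features
.ensemble_input_grad <- function(model, x, output = c("prob", "logit")) {
  output <- match.arg(output)
  fw <- .ensemble_forward(model, x, cache = TRUE)
  p1 <- fw$P[, 2L]
  dlogits <- if (output == "prob") {
    cbind(-p1 * fw$P[, 1L], p1 * (1 - p1))   # d p1 / d logits
  } else {
    matrix(rep(c(-1, 1), each = nrow(x)), nrow(x))   # logit diff l1 - l0
  }
  dH <- tcrossprod(dlogits, model$head_W)
  dx <- matrix(0, nrow(x), model$n_features)
  off <- 0L
  for (nm in names(model$branches)) {
    br <- model$branches[[nm]]
    dout <- dH[, (off + 1L):(off + br$out_dim), drop = FALSE]
    off <- off + br$out_dim
    g <- .branch_backward(br, fw$caches[[nm]], dout, model$config, want_dx = TRUE)
    dx[, model$ordered_cols[[nm]]] <- dx[, model$ordered_cols[[nm]]] + g$dX
  }
  list(grad = dx, value = if (output == "prob") p1 else fw$logits[, 2L] - fw$logits[, 1L])
}

#' Integrated-gradients attribution
#'
#' Path-integral feature attribution for one sample: the gradient of
#' the model output is averaged over `steps` midpoint interpolations
#' between `baseline` and `sample` and multiplied by the displacement.
#' Satisfies completeness — attributions sum to `f(sample) -
#' f(baseline)` — up to Riemann-sum error that shrinks as `steps` grows.
#'
#' @param model an `ensemble_model`.
#' @param sample numeric feature vector.
#' @param baseline reference vector; defaults to all zeros.
#' @param steps number of interpolation points, `>= 8` (default 128).
#' @param output attribute the class-1 probability (`"prob"`, default)
#'   or the class-1 vs class-0 logit difference (`"logit"`).
#' @return Numeric attribution vector, one entry per feature.
#' @export
integrated_gradients <- function(model, sample, baseline = NULL, steps = 128L,
                                 output = c("prob", "logit")) {
  output <- match.arg(output)
  stopifnot(inherits(model, "ensemble_model"))
  sample <- as.numeric(sample)
  if (length(sample) != model$n_features) stop("sample has wrong length")
  if (is.null(baseline)) baseline <- numeric(model$n_features)
  if (length(baseline) != model$n_features) stop("baseline has wrong length")
  if (steps < 8L) stop("steps must be >= 8")
  alphas <- (seq_len(steps) - 0.5) / steps
  pts <- outer(alphas, sample - baseline) + rep(baseline, each = steps)
  g <- .ensemble_input_grad(model, pts, output)$grad
  (sample - baseline) * colMeans(g)
}
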