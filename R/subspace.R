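#' Pair real samples with generated reconstruction targets
#'
#' Assigns every real sample one GAN-generated sample of the same class
#' to serve as its autoencoder reconstruction target. The
#' `nearest_within_class` rule picks the generated sample at minimal
#' Euclidean distance on relative abundances (ties broken by the lower
#' generated index); `random_within_class` draws uniformly. Both are
#' deterministic given `seed`.
#'
#' @param real,generated labelled [otu_table]s sharing the same OTU ids.
#' @param rule `"nearest_within_class"` or `"random_within_class"`.
#' @param seed integer seed (used by the random rule).
#' @return Integer matrix with columns `real` and `generated` (row
#'   indices), one row per real sample.
#' @export
pair_targets <- function(real, generated,
                         rule = c("nearest_within_class", "random_within_class"),
                         seed = 1L) {
  rule <- match.arg(rule)
  validate_otu_table(real); validate_otu_table(generated)
  if (!identical(real$otu_ids, generated$otu_ids)) {
    stop("real and generated tables must share identical OTU ids")
  }
  if (is.null(real$labels) || is.null(generated$labels)) stop("both tables need labels")
  missing_cls <- setdiff(unique(real$labels), unique(generated$labels))
  if (length(missing_cls)) {
    stop("class ", paste(missing_cls, collapse = ","),
         " present in real data but absent from generated data")
  }
  set.seed(seed)
  out <- integer(nrow(real$values))
  for (cls in unique(real$labels)) {
    ri <- which(real$labels == cls)
    gi <- which(generated$labels == cls)
    if (rule == "random_within_class") {
      out[ri] <- gi[sample.int(length(gi), length(ri), replace = TRUE)]
    } else {
      Gm <- generated$values[gi, , drop = FALSE]
      g_sq <- rowSums(Gm^2)
      for (i in ri) {
        d2 <- g_sq - 2 * drop(Gm %*% real$values[i, ])
        out[i] <- gi[which.min(d2)]        # which.min = lowest index on ties
      }
    }
  }
  cbind(real = seq_len(nrow(real$values)), generated = out)
}

#' Squared-error reconstruction loss
#'
#' The squared Euclidean norm `||reconstructed - target||^2` between the
#' decoder output and its paired GAN-generated target.
#'
#' @param reconstructed,target_generated numeric vectors of equal length.
#' @return Nonnegative scalar.
#' @export
reconstruction_loss <- function(reconstructed, target_generated) {
  if (length(reconstructed) != length(target_generated)) {
    stop("length mismatch: ", length(reconstructed), " vs ",
         length(target_generated))
  }
  sum((reconstructed - target_generated)^2)
}

#' Train the common-subspace autoencoder
#'
#' A symmetric MLP autoencoder whose reconstruction target is not the
#' input itself but the paired GAN-generated sample of the same class:
#' minimizing the squared error between decoder output and generated
#' target maps real and generated data onto a common latent subspace.
#' With `generated` identical to `real` and an identity pairing this
#' reduces exactly to a standard autoencoder.
#'
#' Architecture: encoder `feature_dim -> 2*latent_dim (tanh) -> latent
#' (linear)`, decoder mirrored with a softmax head so reconstructions
#' stay compositional. Trained with mini-batch SGD.
#'
#' @param real labelled relative-mode [otu_table] (encoder inputs).
#' @param generated [otu_table] providing reconstruction targets.
#' @param pairing matrix from [pair_targets()].
#' @param latent_dim latent width, `>= 2` and `< feature_dim`.
#' @param epochs,lr,batch_size,momentum SGD schedule (lr default 0.001).
#' @param seed integer seed.
#' @return A `subspace_model` with encoder/decoder bundles, the pairing
#'   and a per-epoch mean-loss `training_log`.
#' @export
train_subspace_ae <- function(real, generated, pairing, latent_dim = 32L,
                              epochs = 200L, lr = 0.001, batch_size = 5L,
                              momentum = 0, seed = 1L) {
  validate_otu_table(real)
  p <- ncol(real$values)
  if (latent_dim >= p) stop("latent_dim must be smaller than feature_dim")
  if (latent_dim < 2L) stop("latent_dim must be >= 2")
  if (!is.matrix(pairing) || !all(c("real", "generated") %in% colnames(pairing)) ||
      !setequal(pairing[, "real"], seq_len(nrow(real$values)))) {
    stop("pairing must cover every real sample exactly once (use pair_targets)")
  }
  set.seed(seed)
  X <- real$values
  Tm <- generated$values[pairing[order(pairing[, "real"]), "generated"], , drop = FALSE]
  core <- .ae_core(X, Tm, latent_dim, epochs, lr, batch_size, momentum)
  structure(list(encoder = core$encoder, decoder = core$decoder,
                 latent_dim = as.integer(latent_dim),
                 otu_ids = real$otu_ids, pairing = pairing,
                 training_log = data.frame(epoch = seq_len(epochs),
                                           mean_loss = core$loss_log)),
            class = "subspace_model")
}

# mini-batch SGD on the target-swapped squared loss; RNG state is the
# caller's (set.seed before calling for reproducibility)
.ae_core <- function(X, Tm, latent_dim, epochs, lr, batch_size, momentum = 0) {
  p <- ncol(X)
  enc <- .mlp_init(c(p, 2L * latent_dim, latent_dim), c("tanh", "linear"))
  dec <- .mlp_init(c(latent_dim, 2L * latent_dim, p), c("tanh", "softmax"))
  se <- .sgd_state(enc); sd_ <- .sgd_state(dec)
  n <- nrow(X)
  loss_log <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    acc <- 0
    for (idx in .batches(n, batch_size)) {
      b <- length(idx)
      ef <- .mlp_forward(enc, X[idx, , drop = FALSE], cache = TRUE)
      df <- .mlp_forward(dec, ef$out, cache = TRUE)
      diff <- df$out - Tm[idx, , drop = FALSE]
      acc <- acc + sum(diff^2)
      gd <- .mlp_backward(dec, df$caches, 2 * diff / b)
      ge <- .mlp_backward(enc, ef$caches, gd$dinput)
      upd <- .sgd_step(dec, gd$grads, sd_, lr, momentum); dec <- upd$net; sd_ <- upd$state
      upd <- .sgd_step(enc, ge$grads, se, lr, momentum); enc <- upd$net; se <- upd$state
    }
    loss_log[epoch] <- acc / n
  }
  list(encoder = enc, decoder = dec, loss_log = loss_log)
}

#' Encode a table into the common latent subspace
#'
#' Maps samples through the trained encoder; the latent features (the
#' last encoder layer) are the common-subspace representation used for
#' augmentation and prediction.
#'
#' @param model a `subspace_model`.
#' @param t an [otu_table] with the model's OTU ids (order enforced).
#' @param origin `"real"` or `"generated"`, recorded per row.
#' @return A `latent_dataset`: `features` (n x latent_dim), `labels`
#'   (may be `NULL`), `origin`.
#' @export
encode <- function(model, t, origin = c("real", "generated")) {
  origin <- match.arg(origin)
  stopifnot(inherits(model, "subspace_model"))
  validate_otu_table(t)
  if (!identical(t$otu_ids, model$otu_ids)) {
    extra <- setdiff(t$otu_ids, model$otu_ids)
    miss <- setdiff(model$otu_ids, t$otu_ids)
    if (length(extra) || length(miss)) {
      stop("feature mismatch; missing: [", paste(miss, collapse = ", "),
           "] extra: [", paste(extra, collapse = ", "), "]")
    }
    t$values <- t$values[, model$otu_ids, drop = FALSE]   # same set, reorder
  }
  f <- .mlp_forward(model$encoder, t$values)
  rownames(f) <- t$sample_ids
  structure(list(features = f, labels = t$labels,
                 origin = rep(origin, nrow(f))),
            class = "latent_dataset")
}

#' Concatenate real and generated latent datasets
#'
#' Row-binds two latent datasets of equal width, preserving labels and
#' origin flags — the augmented training set for the predictor.
#'
#' @param real_latent,gen_latent `latent_dataset` objects.
#' @return A combined `latent_dataset`.
#' @export
build_augmented <- function(real_latent, gen_latent) {
  stopifnot(inherits(real_latent, "latent_dataset"))
  if (is.null(gen_latent) || !nrow(gen_latent$features)) return(real_latent)
  if (ncol(real_latent$features) != ncol(gen_latent$features)) {
    stop("latent width mismatch: ", ncol(real_latent$features), " vs ",
         ncol(gen_latent$features))
  }
  structure(list(
    features = rbind(real_latent$features, gen_latent$features),
    labels = c(real_latent$labels, gen_latent$labels),
    origin = c(real_latent$origin, gen_latent$origin)
  ), class = "latent_dataset")
}
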