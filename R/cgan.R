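#' Conditional GAN configuration
#'
#' Hyperparameters for the conditional generator/discriminator pair.
#' The training defaults (400 epochs, batch size 5, SGD at learning
#' rate 0.001) follow the study protocol this package implements;
#' architectures are multilayer perceptrons with LeakyReLU(0.2) hidden
#' units, a softmax generator head (outputs live on the simplex) and a
#' sigmoid discriminator head.
#'
#' @param feature_dim number of OTU features (required).
#' @param noise_dim generator noise dimension.
#' @param hidden_dims_g,hidden_dims_d hidden layer widths.
#' @param n_classes number of condition classes; fixed at 2.
#' @param epochs,batch_size,lr,momentum SGD training schedule.
#' @param d_steps_per_g_step discriminator updates per generator update.
#' @param non_saturating if `TRUE` the generator minimizes
#'   `-mean(log D(fake))` instead of the minimax `mean(log(1 - D(fake)))`.
#' @param feature_matching weight of a feature-matching term added to
#'   the generator objective: the squared distance between the batch
#'   means of the discriminator's penultimate-layer features on real
#'   and generated samples. Stabilizes the generated marginals against
#'   adversarial drift; 0 disables.
#' @param snapshot_best if `TRUE` (default), the returned generator is
#'   the per-epoch snapshot whose probe samples best match the real
#'   data's per-sample Shannon diversity (mean and spread on a fixed
#'   probe batch) rather than the last-epoch state — early stopping
#'   against generator oscillation, aligned with the pipeline's goal of
#'   diversity-faithful synthesis.
#' @param sparsify_tau sparsification of generated rows: a numeric
#'   threshold (entries below it are zeroed, rows renormalized) or
#'   `"match"` (default) to zero the smallest entries of each generated
#'   row so its zero count is resampled from the training rows' zero
#'   counts. A softmax head never emits exact zeros, so without this
#'   output map generated samples could not reproduce the sparsity of
#'   real data.
#' @param train_sparsify apply the sparsification map already during
#'   training, with a straight-through gradient, so the discriminator
#'   compares sparse fakes against sparse reals instead of keying on
#'   the mere presence of zeros (default `TRUE`).
#' @param seed integer seed.
#' @return A `gan_config` list.
#' @export
gan_config <- function(feature_dim, noise_dim = 64L,
                       hidden_dims_g = c(128L, 256L),
                       hidden_dims_d = c(256L, 128L),
                       n_classes = 2L, epochs = 400L, batch_size = 5L,
                       lr = 0.001, momentum = 0, d_steps_per_g_step = 1L,
                       non_saturating = FALSE, feature_matching = 1,
                       snapshot_best = TRUE, sparsify_tau = "match",
                       train_sparsify = TRUE, seed = 1L) {
  if (missing(feature_dim) || feature_dim <= 0) stop("feature_dim must be positive")
  if (n_classes != 2L) stop("only binary conditioning (n_classes = 2) is supported")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (is.numeric(sparsify_tau)) {
    if (sparsify_tau < 0) stop("sparsify_tau must be nonnegative")
  } else if (!identical(sparsify_tau, "match")) {
    stop("sparsify_tau must be a numeric threshold or \"match\"")
  }
  structure(list(feature_dim = as.integer(feature_dim),
                 noise_dim = as.integer(noise_dim),
                 hidden_dims_g = as.integer(hidden_dims_g),
                 hidden_dims_d = as.integer(hidden_dims_d),
                 n_classes = 2L, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum,
                 d_steps_per_g_step = as.integer(d_steps_per_g_step),
                 non_saturating = isTRUE(non_saturating),
                 feature_matching = feature_matching,
                 snapshot_best = isTRUE(snapshot_best),
                 sparsify_tau = sparsify_tau,
                 train_sparsify = isTRUE(train_sparsify),
                 seed = as.integer(seed)),
            class = "gan_config")
}

# generator = linear-head MLP + class-conditional output bias + softmax;
# the explicit class bias keeps the conditioning signal first-class
# instead of burying it in the hidden layers
.gan_nets <- function(cfg) {
  g_dims <- c(cfg$noise_dim + cfg$n_classes, cfg$hidden_dims_g, cfg$feature_dim)
  d_dims <- c(cfg$feature_dim + cfg$n_classes, cfg$hidden_dims_d, 1L)
  list(
    G = .mlp_init(g_dims, c(rep("lrelu", length(cfg$hidden_dims_g)), "linear")),
    class_bias = matrix(0, cfg$n_classes, cfg$feature_dim),
    D = .mlp_init(d_dims, c(rep("lrelu", length(cfg$hidden_dims_d)), "sigmoid"))
  )
}

# raw softmax generator output for noise z and one-hot labels Y
.gen_forward <- function(G, class_bias, z, Y, cache = FALSE) {
  fw <- .mlp_forward(G, cbind(z, Y), cache = cache)
  logits <- (if (cache) fw$out else fw) + Y %*% class_bias
  out <- .softmax_rows(logits)
  if (cache) list(out = out, caches = fw$caches) else out
}

#' Conditional GAN objectives
#'
#' Computes the two sides of the minimax objective from discriminator
#' probabilities on a real and a generated batch, after clamping all
#' probabilities to `[1e-7, 1 - 1e-7]`: the discriminator maximizes
#' `mean(log d_real) + mean(log(1 - d_fake))` while the generator
#' minimizes `mean(log(1 - d_fake))` (or, in the non-saturating
#' variant, `-mean(log d_fake)`).
#'
#' @param d_real,d_fake discriminator probabilities on real and
#'   generated samples; both nonempty.
#' @param non_saturating use the non-saturating generator objective.
#' @return List with `d_objective` and `g_objective`.
#' @export
cgan_loss <- function(d_real, d_fake, non_saturating = FALSE) {
  if (!length(d_real) || !length(d_fake)) stop("empty batch")
  d_real <- .clamp_prob(d_real)
  d_fake <- .clamp_prob(d_fake)
  d_obj <- mean(log(d_real)) + mean(log(1 - d_fake))
  g_obj <- if (non_saturating) -mean(log(d_fake)) else mean(log(1 - d_fake))
  list(d_objective = d_obj, g_objective = g_obj)
}

#' Generator forward pass
#'
#' Maps noise plus one-hot class conditioning through the generator.
#' Rows of the output are valid relative-abundance vectors (nonnegative,
#' summing to 1 within 1e-6, by the softmax head). Deterministic in
#' (noise, labels, parameters).
#'
#' @param model a trained or initialized `gan_model`.
#' @param noise numeric matrix, batch x noise_dim.
#' @param class_labels 0/1 vector of length `nrow(noise)`.
#' @return Batch x feature_dim matrix of compositions.
#' @export
generator_forward <- function(model, noise, class_labels) {
  stopifnot(inherits(model, "gan_model"))
  noise <- as.matrix(noise)
  if (ncol(noise) != model$config$noise_dim) stop("noise has wrong width")
  if (length(class_labels) != nrow(noise)) stop("one label per noise row required")
  if (!all(class_labels %in% c(0L, 1L))) stop("class labels must be 0 or 1")
  .gen_forward(model$G, model$class_bias, noise,
               .one_hot(as.integer(class_labels)))
}

#' Train a conditional GAN on a labelled relative-abundance table
#'
#' Alternates `d_steps_per_g_step` discriminator updates with one
#' generator update per mini-batch, by stochastic gradient descent. Both
#' networks receive the one-hot class label concatenated to their input.
#' The per-epoch discriminator and generator objectives are recorded in
#' `training_log`. Runs are deterministic given `cfg$seed`.
#'
#' @param t a labelled [otu_table] in relative mode with both classes.
#' @param cfg a [gan_config]; its `feature_dim` must match the table.
#' @return A `gan_model` with generator/discriminator parameter bundles,
#'   the config, training feature metadata and the training log.
#' @export
train_cgan <- function(t, cfg) {
  validate_otu_table(t)
  stopifnot(inherits(cfg, "gan_config"))
  if (t$mode != "relative") stop("train_cgan expects a relative-mode table")
  if (is.null(t$labels)) stop("train_cgan needs labelled samples")
  if (length(unique(t$labels)) < 2L) {
    stop("both classes must be present (conditioning is undefined otherwise)")
  }
  if (ncol(t$values) != cfg$feature_dim) {
    stop("cfg$feature_dim (", cfg$feature_dim, ") != table OTU count (",
         ncol(t$values), ")")
  }
  set.seed(cfg$seed)
  nets <- .gan_nets(cfg)
  G <- nets$G; D <- nets$D; CB <- nets$class_bias
  # Moment-matched head initialization. The softmax head starts at the
  # real marginal composition (bias = log mean abundance), the
  # class-bias rows at each class's log-mean deviation from it, and the
  # head weights are rescaled so the per-sample spread of the logits
  # matches the spread of residual log-abundances in the data. Without
  # this the initial logits have near-zero variance and carry no class
  # signal, and plain SGD cannot repair either in any reasonable number
  # of epochs.
  nl <- length(G$layers)
  lmu <- log(colMeans(t$values) + 1e-8)
  G$layers[[nl]]$b <- lmu
  for (cls in 0:1) {
    CB[cls + 1L, ] <- log(colMeans(t$values[t$labels == cls, , drop = FALSE]) + 1e-8) - lmu
  }
  resid <- log(t$values) - rep(lmu, each = nrow(t$values))
  s_target <- mean(apply(resid, 1L, function(r) stats::sd(r[is.finite(r)])),
                   na.rm = TRUE)
  if (is.finite(s_target) && s_target > 0) {
    probe_n <- 64L
    probe <- cbind(matrix(stats::rnorm(probe_n * cfg$noise_dim), probe_n),
                   .one_hot(sample(t$labels, probe_n, replace = TRUE)))
    h <- probe
    for (l in seq_len(nl - 1L)) {
      h <- .activate(h %*% G$layers[[l]]$W + rep(G$layers[[l]]$b, each = probe_n),
                     G$acts[l])
    }
    s_obs <- mean(apply(h %*% G$layers[[nl]]$W, 1L, stats::sd))
    if (is.finite(s_obs) && s_obs > 0) {
      G$layers[[nl]]$W <- G$layers[[nl]]$W * (s_target / s_obs)
    }
  }
  sG <- .sgd_state(G); sD <- .sgd_state(D); sCB <- CB * 0

  # fixed probe for the per-epoch snapshot criterion: distance between
  # generated and real per-sample Shannon diversity (mean and spread)
  probe_n2 <- 100L
  probe_z <- matrix(stats::rnorm(probe_n2 * cfg$noise_dim), probe_n2)
  probe_Y <- .one_hot(rep_len(0:1, probe_n2))
  probe_ks <- pmin(sample(as.integer(rowSums(t$values == 0)), probe_n2,
                          replace = TRUE), cfg$feature_dim - 1L)
  shannon_moments <- function(m) {
    h <- apply(m, 1L, function(r) { r <- r[r > 0]; -sum(r * log(r)) })
    c(mean(h), stats::sd(h))
  }
  real_moments <- shannon_moments(t$values)
  probe_dist <- function(G_, CB_) {
    m <- .gen_forward(G_, CB_, probe_z, probe_Y)
    for (i in seq_len(probe_n2)) {
      if (probe_ks[i] > 0L) m[i, order(m[i, ])[seq_len(probe_ks[i])]] <- 0
    }
    m <- m / rowSums(m)
    sum((shannon_moments(m) - real_moments)^2)
  }
  best_dist <- Inf; best_G <- G; best_CB <- CB; best_epoch <- 0L
  X <- t$values
  Y <- .one_hot(t$labels)
  n <- nrow(X)
  zero_counts <- as.integer(rowSums(X == 0))
  sparsify <- function(m) {
    if (!cfg$train_sparsify) return(m)
    .sparsify_rows(m, cfg$sparsify_tau, zero_counts)
  }
  log_d <- log_g <- numeric(cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    d_obj_acc <- g_obj_acc <- 0; n_b <- 0L
    for (idx in .batches(n, cfg$batch_size)) {
      b <- length(idx)
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      yb <- t$labels[idx]
      # --- discriminator steps ---
      for (k in seq_len(cfg$d_steps_per_g_step)) {
        z <- matrix(stats::rnorm(b * cfg$noise_dim), b)
        fake <- sparsify(.gen_forward(G, CB, z, Yb))
        fr <- .mlp_forward(D, cbind(Xb, Yb), cache = TRUE)
        ff <- .mlp_forward(D, cbind(fake, Yb), cache = TRUE)
        p_r <- .clamp_prob(fr$out); p_f <- .clamp_prob(ff$out)
        # minimize -(log p_r + log(1 - p_f)); grads wrt sigmoid pre-activation
        gr <- .mlp_backward(D, fr$caches, (p_r - 1) / b, dout_is_dz = TRUE)
        gf <- .mlp_backward(D, ff$caches, p_f / b, dout_is_dz = TRUE)
        upd <- .sgd_step(D, Map(function(a, c) list(W = a$W + c$W, b = a$b + c$b),
                                gr$grads, gf$grads), sD, cfg$lr, cfg$momentum)
        D <- upd$net; sD <- upd$state
      }
      # --- generator step ---
      z <- matrix(stats::rnorm(b * cfg$noise_dim), b)
      gfwd <- .gen_forward(G, CB, z, Yb, cache = TRUE)
      # sparsification enters D's input; its gradient passes straight
      # through to the raw softmax output
      dfwd <- .mlp_forward(D, cbind(sparsify(gfwd$out), Yb), cache = TRUE)
      p_f <- .clamp_prob(dfwd$out)
      # saturating: minimize mean log(1-p_f)  -> dL/da = -p_f / b
      # non-saturating: minimize -mean log p_f -> dL/da = (p_f - 1) / b
      dz_d <- if (cfg$non_saturating) (p_f - 1) / b else -p_f / b
      dD <- .mlp_backward(D, dfwd$caches, dz_d, dout_is_dz = TRUE)
      d_fake_grad <- dD$dinput[, seq_len(cfg$feature_dim), drop = FALSE]
      if (cfg$feature_matching > 0) {
        # match batch means of D's penultimate features on real vs fake
        pen <- length(D$layers) - 1L
        Dh <- list(layers = D$layers[seq_len(pen)], acts = D$acts[seq_len(pen)])
        rh <- .mlp_forward(Dh, cbind(Xb, Yb))
        fdiff <- colMeans(dfwd$caches[[pen]]$out) - colMeans(rh)
        dH <- matrix(2 * cfg$feature_matching * fdiff / b, b,
                     length(fdiff), byrow = TRUE)
        fmg <- .mlp_backward(Dh, dfwd$caches[seq_len(pen)], dH)
        d_fake_grad <- d_fake_grad +
          fmg$dinput[, seq_len(cfg$feature_dim), drop = FALSE]
      }
      dlogits <- .activate_grad(gfwd$out, d_fake_grad, "softmax")
      gG <- .mlp_backward(G, gfwd$caches, dlogits, dout_is_dz = TRUE)
      upd <- .sgd_step(G, gG$grads, sG, cfg$lr, cfg$momentum)
      G <- upd$net; sG <- upd$state
      sCB <- cfg$momentum * sCB + crossprod(Yb, dlogits)
      CB <- CB - cfg$lr * sCB

      obj <- cgan_loss(p_r, p_f, cfg$non_saturating)
      d_obj_acc <- d_obj_acc + obj$d_objective
      g_obj_acc <- g_obj_acc + obj$g_objective
      n_b <- n_b + 1L
    }
    log_d[epoch] <- d_obj_acc / n_b
    log_g[epoch] <- g_obj_acc / n_b
    if (cfg$snapshot_best) {
      d <- probe_dist(G, CB)
      if (d < best_dist) {
        best_dist <- d; best_G <- G; best_CB <- CB; best_epoch <- epoch
      }
    }
  }
  if (cfg$snapshot_best) {
    G <- best_G; CB <- best_CB
  }

  structure(list(
    G = G, class_bias = CB, D = D, config = cfg,
    snapshot_epoch = if (cfg$snapshot_best) best_epoch else cfg$epochs,
    otu_ids = t$otu_ids,
    train_zero_counts = as.integer(rowSums(t$values == 0)),
    training_log = data.frame(epoch = seq_len(cfg$epochs),
                              d_objective = log_d, g_objective = log_g)
  ), class = "gan_model")
}

# sparsification output map. "match" emulates detection-limit dropout:
# each row zeroes its smallest entries, with the zero count resampled
# from the training rows' zero counts — the same lower-tail censoring
# that produces zeros in sparse sequencing data. A numeric tau zeroes
# entries below a fixed threshold. Rows are renormalized.
.sparsify_rows <- function(m, tau, train_zero_counts = NULL) {
  p <- ncol(m)
  if (identical(tau, "match")) {
    if (is.null(train_zero_counts)) stop("no training zero counts recorded")
    ks <- pmin(sample(train_zero_counts, nrow(m), replace = TRUE), p - 1L)
    for (i in seq_len(nrow(m))) {
      if (ks[i] > 0L) {
        m[i, order(m[i, ])[seq_len(ks[i])]] <- 0
      }
    }
  } else if (tau > 0) {
    keep_top <- max.col(m)                  # never zero a whole row
    m[m < tau] <- 0
    dead <- rowSums(m) == 0
    if (any(dead)) m[cbind(which(dead), keep_top[dead])] <- 1
  }
  m / rowSums(m)
}

#' Sample labelled synthetic data from a trained conditional GAN
#'
#' Draws the requested number of case and control compositions from the
#' generator and returns them as a labelled relative-mode [otu_table]
#' whose OTU ids are copied from the training table. Generated rows are
#' sparsified according to the model's `sparsify_tau` policy so that the
#' synthetic table carries exact zeros like real data.
#'
#' @param model a trained `gan_model`.
#' @param n_cases,n_controls nonnegative sample counts (defaults 600).
#' @param seed integer seed for the noise draws.
#' @return A labelled [otu_table] with `n_cases + n_controls` samples.
#' @export
sample_synthetic <- function(model, n_cases = 600L, n_controls = 600L, seed = 1L) {
  stopifnot(inherits(model, "gan_model"))
  if (n_cases < 0 || n_controls < 0) stop("sample counts must be nonnegative")
  n <- n_cases + n_controls
  if (n == 0L) stop("requested zero samples")
  set.seed(seed)
  labels <- c(rep(1L, n_cases), rep(0L, n_controls))
  z <- matrix(stats::rnorm(n * model$config$noise_dim), n)
  m <- generator_forward(model, z, labels)
  m <- .sparsify_rows(m, model$config$sparsify_tau, model$train_zero_counts)
  otu_table(m, sprintf("gen_%04d", seq_len(n)), model$otu_ids,
            labels = labels, mode = "relative")
}
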