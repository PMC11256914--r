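# Internal dense-network primitives shared by the C-GAN, the subspace
# autoencoder and the convolutional ensemble. Plain matrix backprop with
# SGD(+momentum); all randomness comes from R's global RNG so callers
# control determinism with a single set.seed().

.EPS <- 1e-7

.clamp_prob <- function(p, eps = .EPS) pmin(pmax(p, eps), 1 - eps)

.softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

.activate <- function(z, kind) {
  switch(kind,
    linear  = z,
    relu    = pmax(z, 0),
    lrelu   = pmax(z, 0) + 0.2 * pmin(z, 0),
    tanh    = tanh(z),
    sigmoid = 1 / (1 + exp(-z)),
    softmax = .softmax_rows(z),
    stop("unknown activation: ", kind)
  )
}

# derivative wrt pre-activation, given activation value `a` and upstream
# gradient `da` (softmax needs the full Jacobian contraction)
.activate_grad <- function(a, da, kind) {
  switch(kind,
    linear  = da,
    relu    = da * (a > 0),
    lrelu   = da * ifelse(a > 0, 1, 0.2),
    tanh    = da * (1 - a^2),
    sigmoid = da * a * (1 - a),
    softmax = a * (da - rowSums(da * a)),
    stop("unknown activation: ", kind)
  )
}

# He-style init scaled for leaky/plain ReLU, Xavier otherwise
.mlp_init <- function(dims, acts) {
  stopifnot(length(dims) >= 2L, length(acts) == length(dims) - 1L)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- dims[l]
    sd <- if (acts[l] %in% c("relu", "lrelu")) sqrt(2 / fan_in) else sqrt(1 / fan_in)
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * dims[l + 1L], sd = sd), fan_in, dims[l + 1L]),
      b = numeric(dims[l + 1L])
    )
  }
  structure(list(layers = layers, acts = acts, dims = dims), class = "mb_mlp")
}

.mlp_forward <- function(net, X, cache = FALSE) {
  A <- X
  caches <- if (cache) vector("list", length(net$layers)) else NULL
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    Z <- A %*% ly$W
    Z <- Z + rep(ly$b, each = nrow(Z))
    A_new <- .activate(Z, net$acts[l])
    if (cache) caches[[l]] <- list(input = A, out = A_new)
    A <- A_new
  }
  if (cache) list(out = A, caches = caches) else A
}

# dout: gradient wrt the network OUTPUT (post-activation) unless
# `dout_is_dz` (gradient already wrt last-layer pre-activation, e.g. the
# fused softmax/sigmoid + cross-entropy shortcut).
.mlp_backward <- function(net, caches, dout, dout_is_dz = FALSE) {
  L <- length(net$layers)
  grads <- vector("list", L)
  dZ <- if (dout_is_dz) dout else .activate_grad(caches[[L]]$out, dout, net$acts[L])
  for (l in L:1) {
    A_prev <- caches[[l]]$input
    grads[[l]] <- list(W = crossprod(A_prev, dZ), b = colSums(dZ))
    if (l > 1L) {
      dA <- tcrossprod(dZ, net$layers[[l]]$W)
      dZ <- .activate_grad(caches[[l - 1L]]$out, dA, net$acts[l - 1L])
    } else {
      dA <- tcrossprod(dZ, net$layers[[l]]$W)
    }
  }
  list(grads = grads, dinput = dA)
}

.sgd_state <- function(net) {
  lapply(net$layers, function(ly) list(W = ly$W * 0, b = ly$b * 0))
}

.sgd_step <- function(net, grads, state, lr, momentum = 0) {
  for (l in seq_along(net$layers)) {
    state[[l]]$W <- momentum * state[[l]]$W + grads[[l]]$W
    state[[l]]$b <- momentum * state[[l]]$b + grads[[l]]$b
    net$layers[[l]]$W <- net$layers[[l]]$W - lr * state[[l]]$W
    net$layers[[l]]$b <- net$layers[[l]]$b - lr * state[[l]]$b
  }
  list(net = net, state = state)
}

.one_hot <- function(labels, n_classes = 2L) {
  Y <- matrix(0, length(labels), n_classes)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  Y
}

# shuffled mini-batch index list for one epoch
.batches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

# flat numeric checksum over all parameters (model integrity on reload)
.param_checksum <- function(x) {
  v <- suppressWarnings(as.numeric(unlist(x, use.names = FALSE)))
  v <- v[is.finite(v)]
  signif(sum(v) + sum(abs(v)), 12)
}
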