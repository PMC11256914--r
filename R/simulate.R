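#' Simulation configuration for synthetic case/control cohorts
#'
#' Describes a seeded synthetic genus-level gut-microbiome cohort: a
#' sparse compositional table with phylum-block correlation structure
#' and a planted case/control abundance shift on a subset of OTUs.
#'
#' Defaults emulate the shape of shotgun-sequencing gut cohorts: ~75%
#' zeros per sample, three major phyla (Firmicutes, Proteobacteria,
#' Actinobacteria) holding most OTUs plus a small minor phylum, log-normal
#' abundances with large variance relative to the mean, and a moderate
#' planted effect.
#'
#' @param n_cases,n_controls sample counts per class.
#' @param n_otus total number of OTUs (features).
#' @param phyla named integer vector: OTUs per phylum; must sum to
#'   `n_otus`. `NULL` gives a default 45/30/20/5% split across
#'   Firmicutes, Proteobacteria, Actinobacteria, Bacteroidetes.
#' @param target_sparsity expected fraction of zero entries, in (0,1).
#' @param block_correlation latent within-phylum correlation in [0,1).
#' @param n_differential number of OTUs carrying the planted effect.
#' @param effect_log2fc planted case/control log2 fold change.
#' @param dispersion standard deviation of per-OTU log-mean abundances.
#' @param mask_mode zero-masking mechanism. `"detection_limit"`
#'   (default) draws entry-wise Bernoulli dropout whose probability
#'   falls logistically with the realized log abundance, calibrated per
#'   sample so the expected zero fraction equals `target_sparsity` —
#'   emulating finite sequencing depth, under which abundant taxa are
#'   always observed and prevalence tracks abundance. `"uniform"` masks
#'   every entry with the same probability regardless of abundance.
#' @param mask_softness logistic scale (natural-log units) of the
#'   detection-limit dropout curve.
#' @param seed integer seed governing all draws.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cases = 100L, n_controls = 100L, n_otus = 120L,
                       phyla = NULL, target_sparsity = 0.75,
                       block_correlation = 0.5, n_differential = 12L,
                       effect_log2fc = 1.5, dispersion = 1.5,
                       mask_mode = c("detection_limit", "uniform"),
                       mask_softness = 0.5, seed = 1L) {
  mask_mode <- match.arg(mask_mode)
  if (is.null(phyla)) {
    props <- c(Firmicutes = 0.45, Proteobacteria = 0.30,
               Actinobacteria = 0.20, Bacteroidetes = 0.05)
    counts <- floor(props * n_otus)
    counts[1L] <- counts[1L] + (n_otus - sum(counts))
    phyla <- counts
  }
  cfg <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              n_otus = as.integer(n_otus), phyla = phyla,
              target_sparsity = target_sparsity,
              block_correlation = block_correlation,
              n_differential = as.integer(n_differential),
              effect_log2fc = effect_log2fc, dispersion = dispersion,
              mask_mode = mask_mode, mask_softness = mask_softness,
              seed = as.integer(seed))
  if (sum(cfg$phyla) != cfg$n_otus) stop("phyla OTU counts must sum to n_otus")
  if (cfg$n_differential > cfg$n_otus) stop("n_differential exceeds n_otus")
  if (cfg$target_sparsity <= 0 || cfg$target_sparsity >= 1) {
    stop("target_sparsity must lie in (0,1)")
  }
  if (cfg$block_correlation < 0 || cfg$block_correlation >= 1) {
    stop("block_correlation must lie in [0,1)")
  }
  if (cfg$dispersion <= 0) stop("dispersion must be positive")
  structure(cfg, class = "sim_config")
}

#' Simulate a labelled synthetic case/control OTU table
#'
#' Fixed generative procedure: (1) per-OTU log-mean abundances drawn
#' from `N(0, dispersion)`; (2) latent per-sample vectors from a
#' multivariate normal whose correlation is block-diagonal by phylum
#' (equicorrelation `block_correlation` inside each block, 0 across);
#' (3) exponentiation and row renormalization to proportions; (4) the
#' planted OTUs multiplied by `2^effect_log2fc` in case samples before
#' renormalizing; (5) Bernoulli zero-masking calibrated so the expected
#' zero fraction equals `target_sparsity`, then renormalization of the
#' surviving entries. The same seed yields bit-identical output.
#'
#' @param cfg a [sim_config].
#' @return A list with `table` (relative-mode labelled [otu_table]),
#'   `taxonomy` (a [taxonomy_map]), and `truth` (ids of planted
#'   differential OTUs).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$target_sparsity >= 1 - 1 / cfg$n_otus) {
    stop("infeasible target_sparsity: would leave < 1 nonzero OTU per sample")
  }
  set.seed(cfg$seed)
  n <- cfg$n_cases + cfg$n_controls
  p <- cfg$n_otus
  labels <- c(rep(1L, cfg$n_cases), rep(0L, cfg$n_controls))
  otu_ids <- sprintf("otu_%03d", seq_len(p))
  phy_names <- rep(names(cfg$phyla), cfg$phyla)

  # (1) per-OTU log-means
  mu <- stats::rnorm(p, 0, cfg$dispersion)
  # (2) block-equicorrelated latent field: z = sqrt(r)*u_block + sqrt(1-r)*e
  r <- cfg$block_correlation
  z <- matrix(stats::rnorm(n * p), n, p) * sqrt(1 - r)
  for (ph in unique(phy_names)) {
    cols <- which(phy_names == ph)
    z[, cols] <- z[, cols] + sqrt(r) * stats::rnorm(n)
  }
  x <- exp(sweep(z, 2L, mu, "+"))
  # (4) planted effect on case rows (before the final renormalization)
  truth_idx <- sort(sample.int(p, cfg$n_differential))
  x[labels == 1L, truth_idx] <- x[labels == 1L, truth_idx] * 2^cfg$effect_log2fc
  # (5) Bernoulli zero-masking with expected zero fraction = target_sparsity
  q <- cfg$target_sparsity
  if (cfg$mask_mode == "detection_limit") {
    # dropout probability falls logistically with realized log
    # abundance; the per-sample threshold is solved so the expected
    # dropout equals q (finite-depth detection limit)
    s <- cfg$mask_softness
    lx <- log(x)
    for (i in seq_len(n)) {
      th <- stats::uniroot(function(t) mean(stats::plogis((t - lx[i, ]) / s)) - q,
                           range(lx[i, ]) + c(-10 * s, 10 * s))$root
      drop <- stats::runif(p) < stats::plogis((th - lx[i, ]) / s)
      x[i, drop] <- 0
    }
  } else {
    mask <- matrix(stats::runif(n * p) < q, n, p)
    x[mask] <- 0
  }
  dead <- rowSums(x) == 0
  if (any(dead)) {                          # keep each sample's top OTU alive
    top <- max.col(exp(sweep(z, 2L, mu, "+")))
    x[cbind(which(dead), top[dead])] <- 1
  }
  x <- x / rowSums(x)

  lineages <- stats::setNames(
    sprintf("k__Bacteria;p__%s;c__;o__;f__;g__genus_%03d", phy_names, seq_len(p)),
    otu_ids)
  list(
    table = otu_table(x, sprintf("s%04d", seq_len(n)), otu_ids,
                      labels = labels, mode = "relative"),
    taxonomy = taxonomy_map(lineages),
    truth = otu_ids[truth_idx]
  )
}

#' Mean case/control log-ratio per OTU
#'
#' Diagnostic for the planted effect: for every OTU, the log of (mean
#' case abundance + eps) over (mean control abundance + eps).
#'
#' @param t a labelled [otu_table].
#' @param truth optional ids of planted OTUs; validated to be a subset
#'   of the table's OTUs (the returned vector always covers all OTUs).
#' @param eps stabilizer added to both means (default `1e-8`).
#' @return Named numeric vector over all OTUs.
#' @export
planted_effect_check <- function(t, truth = NULL, eps = 1e-8) {
  validate_otu_table(t)
  if (is.null(t$labels)) stop("table has no labels")
  if (!is.null(truth) && length(setdiff(truth, t$otu_ids))) {
    stop("truth ids absent from table: ",
         paste(setdiff(truth, t$otu_ids), collapse = ", "))
  }
  mc <- colMeans(t$values[t$labels == 1L, , drop = FALSE])
  m0 <- colMeans(t$values[t$labels == 0L, , drop = FALSE])
  stats::setNames(log((mc + eps) / (m0 + eps)), t$otu_ids)
}
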