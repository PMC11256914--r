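#' Save a model bundle to disk
#'
#' Single-file, version-tagged serialization for GAN, subspace and
#' ensemble models. The payload carries a parameter checksum that is
#' re-verified on load.
#'
#' @param model a `gan_model`, `subspace_model` or `ensemble_model`.
#' @param path output file path.
#' @export
save_model <- function(model, path) {
  type <- class(model)[1L]
  if (!type %in% c("gan_model", "subspace_model", "ensemble_model")) {
    stop("unsupported model type: ", type)
  }
  bundle <- list(format = "mbaugment_model", version = 1L, type = type,
                 checksum = .param_checksum(model), payload = model)
  saveRDS(bundle, path)
  invisible(path)
}

#' Load a model bundle
#'
#' Validates the format tag, version, optional expected type and the
#' parameter checksum; refuses corrupt or mismatched files.
#'
#' @param path file written by [save_model()].
#' @param expected_type optionally one of `"gan_model"`,
#'   `"subspace_model"`, `"ensemble_model"`.
#' @return The deserialized model.
#' @export
load_model <- function(path, expected_type = NULL) {
  bundle <- tryCatch(readRDS(path),
                     error = function(e) stop("cannot read model file '", path,
                                              "' (corrupt or truncated): ",
                                              conditionMessage(e)))
  if (!is.list(bundle) || !identical(bundle$format, "mbaugment_model")) {
    stop("not an mbaugment model file: ", path)
  }
  if (!identical(bundle$version, 1L)) stop("unsupported model version: ", bundle$version)
  if (!is.null(expected_type) && !identical(bundle$type, expected_type)) {
    stop("model type mismatch: file holds a ", bundle$type,
         ", expected a ", expected_type)
  }
  if (!isTRUE(all.equal(.param_checksum(bundle$payload), bundle$checksum))) {
    stop("model checksum mismatch (file corrupted?): ", path)
  }
  bundle$payload
}

#' Augment a new cohort with a frozen, previously trained GAN
#'
#' Transfer-learning workflow: loads (or takes) a trained conditional
#' GAN and samples synthetic cases/controls for a new, typically
#' smaller cohort — without retraining. The new table must cover
#' exactly the GAN's training OTU set (column order may differ and is
#' realigned); a mismatch is rejected, since transfer is only valid
#' when both cohorts were processed by the same feature pipeline.
#'
#' @param gan a `gan_model` or the path of a saved one.
#' @param new_table the new cohort's [otu_table].
#' @param n_cases,n_controls synthetic samples to draw.
#' @param seed integer seed.
#' @return A labelled relative-mode [otu_table] whose columns follow
#'   `new_table`'s OTU order.
#' @export
transfer_augment <- function(gan, new_table, n_cases = 600L, n_controls = 600L,
                             seed = 1L) {
  if (is.character(gan)) gan <- load_model(gan, expected_type = "gan_model")
  stopifnot(inherits(gan, "gan_model"))
  validate_otu_table(new_table)
  if (!setequal(gan$otu_ids, new_table$otu_ids)) {
    miss <- setdiff(gan$otu_ids, new_table$otu_ids)
    extra <- setdiff(new_table$otu_ids, gan$otu_ids)
    stop("OTU sets differ between the GAN's training cohort and the new ",
         "cohort (the sequencing/feature pipeline must be identical). ",
         "Missing from new cohort: [", paste(miss, collapse = ", "),
         "]; not in GAN: [", paste(extra, collapse = ", "), "]")
  }
  gen <- sample_synthetic(gan, n_cases, n_controls, seed = seed)
  otu_table(gen$values[, new_table$otu_ids, drop = FALSE],
            gen$sample_ids, new_table$otu_ids,
            labels = gen$labels, mode = "relative")
}

# close a cluster submatrix to within-cluster proportions; all-zero
# rows become uniform
.subcomposition <- function(m) {
  rs <- rowSums(m)
  dead <- rs == 0
  if (any(dead)) {
    m[dead, ] <- 1 / ncol(m)
    rs[dead] <- 1
  }
  m / rs
}

#' Train the full disease predictor, with optional augmentation
#'
#' Fits the phylum-stratified correlation-ordered CNN ensemble on real
#' data, optionally augmented with GAN-generated samples. Two feature
#' spaces are supported:
#'
#' * `"otu"`: the ensemble consumes raw relative abundances; generated
#'   samples (if any) are appended as extra training rows.
#' * `"latent"`: one common-subspace autoencoder is trained per phylum
#'   cluster (inputs: real within-cluster subcompositions; targets: the
#'   paired generated samples), and the ensemble consumes the
#'   concatenated latent blocks of real plus generated samples.
#'
#' @param real labelled relative-mode [otu_table].
#' @param taxonomy a [taxonomy_map] covering the table's OTUs.
#' @param generated optional labelled [otu_table] of synthetic samples.
#' @param feature_space `"otu"` or `"latent"`.
#' @param top_k,keep_other passed to [assign_phylum_clusters()].
#' @param cnn a [cnn_config].
#' @param latent_dim,ae_epochs,ae_lr,ae_batch_size autoencoder schedule
#'   (latent mode only).
#' @param pair_rule pairing rule for [pair_targets()].
#' @param seed integer seed.
#' @return A `disease_model` with a `$predict(table)` closure returning
#'   class-1 probabilities for a new [otu_table].
#' @export
train_disease_model <- function(real, taxonomy, generated = NULL,
                                feature_space = c("latent", "otu"),
                                top_k = 3L, keep_other = FALSE,
                                cnn = cnn_config(),
                                latent_dim = 8L, ae_epochs = 100L,
                                ae_lr = 0.05, ae_batch_size = 10L,
                                pair_rule = "nearest_within_class",
                                seed = 1L) {
  feature_space <- match.arg(feature_space)
  validate_otu_table(real)
  if (is.null(real$labels)) stop("real table needs labels")
  partition <- assign_phylum_clusters(real$otu_ids, taxonomy, top_k = top_k,
                                      keep_other = keep_other)
  if (feature_space == "otu" || is.null(generated)) {
    if (feature_space == "latent" && is.null(generated)) {
      feature_space <- "otu"   # no generated targets: plain stratified CNN
    }
    x <- real$values; y <- real$labels
    if (!is.null(generated)) {
      x <- rbind(x, generated$values[, real$otu_ids, drop = FALSE])
      y <- c(y, generated$labels)
    }
    cnn$seed <- seed
    model <- train_ensemble(x, y, partition, cnn)
    predict_fn <- function(t) {
      m <- if (inherits(t, "otu_table")) t$values[, real$otu_ids, drop = FALSE]
           else as.matrix(t)
      predict_proba(model, m)
    }
    return(structure(list(feature_space = "otu", ensemble = model,
                          partition = partition, otu_ids = real$otu_ids,
                          predict = predict_fn),
                     class = "disease_model"))
  }

  # latent mode: one target-swapped AE per phylum cluster
  pairing <- pair_targets(real, generated, rule = pair_rule, seed = seed)
  gen_aligned <- generated$values[, real$otu_ids, drop = FALSE]
  aes <- list()
  lat_real <- NULL; lat_gen <- NULL
  lat_clusters <- list(); off <- 0L
  set.seed(seed)
  for (nm in names(partition$clusters)) {
    cols <- partition$clusters[[nm]]
    ld <- max(2L, min(latent_dim, length(cols) - 1L))
    Xr <- .subcomposition(real$values[, cols, drop = FALSE])
    Xg <- .subcomposition(gen_aligned[, cols, drop = FALSE])
    Tm <- Xg[pairing[, "generated"], , drop = FALSE]
    ae <- .ae_core(Xr, Tm, latent_dim = ld, epochs = ae_epochs, lr = ae_lr,
                   batch_size = ae_batch_size, momentum = 0.9)
    aes[[nm]] <- list(ae = ae, cols = cols, latent_dim = ld)
    lat_real <- cbind(lat_real, .mlp_forward(ae$encoder, Xr))
    lat_gen <- cbind(lat_gen, .mlp_forward(ae$encoder, Xg))
    lat_clusters[[nm]] <- (off + 1L):(off + ld)
    off <- off + ld
  }
  x <- rbind(lat_real, lat_gen)
  y <- c(real$labels, generated$labels)
  cnn$seed <- seed
  lat_partition <- structure(list(clusters = lat_clusters, overflow = integer(0)),
                             class = "phylum_partition")
  model <- train_ensemble(x, y, lat_partition, cnn)
  predict_fn <- function(t) {
    m <- if (inherits(t, "otu_table")) t$values[, real$otu_ids, drop = FALSE]
         else as.matrix(t)
    lat <- NULL
    for (nm in names(aes)) {
      Xc <- .subcomposition(m[, aes[[nm]]$cols, drop = FALSE])
      lat <- cbind(lat, .mlp_forward(aes[[nm]]$ae$encoder, Xc))
    }
    predict_proba(model, lat)
  }
  structure(list(feature_space = "latent", ensemble = model, aes = aes,
                 partition = partition, otu_ids = real$otu_ids,
                 predict = predict_fn),
            class = "disease_model")
}

# simple config-hash for run manifests: FNV-1a over the JSON encoding
.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Default pipeline configuration
#'
#' One document mirroring every stage of the pipeline with the study
#' protocol's defaults: GAN/CNN trained 400 epochs at batch size 5 and
#' SGD learning rate 0.001, stride 1, 32 filters, 600 + 600 generated
#' samples, a 70/30 stratified split and 10 x 10-fold cross-validation.
#' Any subset of fields can be overridden via a YAML file or a nested
#' list.
#'
#' @param overrides named nested list (or path to a YAML file) whose
#'   entries replace the defaults.
#' @return A `pipeline_config` nested list.
#' @export
pipeline_config <- function(overrides = NULL) {
  cfg <- list(
    seed = 1L,
    feature_space = "latent",
    sim = list(n_cases = 100L, n_controls = 100L, n_otus = 120L,
               target_sparsity = 0.75, block_correlation = 0.5,
               n_differential = 12L, effect_log2fc = 1.5, dispersion = 1.5),
    paths = list(table = NULL, taxonomy = NULL, label_column = "label"),
    gan = list(epochs = 400L, batch_size = 5L, lr = 0.001, momentum = 0,
               noise_dim = 64L, non_saturating = FALSE, sparsify_tau = "match"),
    generate = list(n_cases = 600L, n_controls = 600L),
    ae = list(latent_dim = 8L, epochs = 100L, lr = 0.05, batch_size = 10L),
    cnn = list(epochs = 400L, batch_size = 5L, lr = 0.001, momentum = 0,
               n_filters = 32L, kernel_size = 5L, stride = 1L),
    eval = list(test_fraction = 0.3, n_repeats = 10L, n_folds = 10L,
                top_k = 3L, keep_other = FALSE, run_cv = FALSE)
  )
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  structure(cfg, class = "pipeline_config")
}

.log_line <- function(con, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the end-to-end pipeline
#'
#' simulate/read -> all-zero OTU filter -> 70/30 split -> C-GAN on the
#' training portion -> synthetic generation -> disease model (latent or
#' OTU feature space) -> realism diagnostics and held-out test metrics.
#' All artifacts (tables, models, `report.json`, manifest, log) are
#' written under `out_dir`; the same config and seed reproduce the
#' report bit-identically. A stage failure aborts with the stage named
#' and retains partial outputs under `out_dir/failed/`.
#'
#' @param cfg a [pipeline_config].
#' @param out_dir run directory (created if needed).
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("mbaug_run_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  stage <- "init"
  fail <- function(e) {
    failed_dir <- file.path(out_dir, "failed")
    dir.create(failed_dir, showWarnings = FALSE)
    arts <- setdiff(list.files(out_dir, full.names = TRUE), failed_dir)
    file.copy(arts, failed_dir, recursive = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  report <- tryCatch({
    stage <- "otu_io"
    if (!is.null(cfg$paths$table)) {
      .log_line(log_con, stage, paste("reading", cfg$paths$table))
      tab <- read_otu_table(cfg$paths$table, label_column = cfg$paths$label_column)
      if (tab$mode == "counts") tab <- normalize_relative_abundance(tab)
      tax <- read_taxonomy(cfg$paths$taxonomy)
      truth <- character(0)
    } else {
      stage <- "simulate"
      sc <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
      .log_line(log_con, stage, sprintf("simulating %d+%d samples x %d OTUs",
                                        sc$n_cases, sc$n_controls, sc$n_otus))
      sim <- simulate_dataset(sc)
      tab <- sim$table; tax <- sim$taxonomy; truth <- sim$truth
    }
    stage <- "otu_io"
    filt <- filter_all_zero_otus(tab)
    tab <- filt$table
    if (length(filt$removed_ids)) {
      .log_line(log_con, stage, paste("removed all-zero OTUs:",
                                      paste(filt$removed_ids, collapse = ", ")))
    }
    write_otu_table(tab, file.path(out_dir, "table.tsv"))
    write_taxonomy(tax, file.path(out_dir, "taxonomy.tsv"))

    stage <- "split"
    sp <- train_test_split(tab$labels, cfg$eval$test_fraction, seed = cfg$seed)
    tab_tr <- otu_table(tab$values[sp$train, , drop = FALSE],
                        tab$sample_ids[sp$train], tab$otu_ids,
                        labels = tab$labels[sp$train], mode = "relative")
    tab_te <- otu_table(tab$values[sp$test, , drop = FALSE],
                        tab$sample_ids[sp$test], tab$otu_ids,
                        labels = tab$labels[sp$test], mode = "relative")

    stage <- "train-gan"
    gcfg <- do.call(gan_config, c(list(feature_dim = ncol(tab$values)),
                                  cfg$gan, list(seed = cfg$seed)))
    .log_line(log_con, stage, sprintf("%d epochs, batch %d, lr %g",
                                      gcfg$epochs, gcfg$batch_size, gcfg$lr))
    gan <- train_cgan(tab_tr, gcfg)
    save_model(gan, file.path(out_dir, "gan.bin"))

    stage <- "generate"
    gen <- sample_synthetic(gan, cfg$generate$n_cases, cfg$generate$n_controls,
                            seed = cfg$seed + 1L)
    write_otu_table(gen, file.path(out_dir, "generated.tsv"))

    stage <- "train-classifier"
    cnn <- do.call(cnn_config, c(cfg$cnn[setdiff(names(cfg$cnn), "stride")],
                                 list(seed = cfg$seed)))
    dm <- train_disease_model(tab_tr, tax, generated = gen,
                              feature_space = cfg$feature_space,
                              top_k = cfg$eval$top_k,
                              keep_other = cfg$eval$keep_other, cnn = cnn,
                              latent_dim = cfg$ae$latent_dim,
                              ae_epochs = cfg$ae$epochs, ae_lr = cfg$ae$lr,
                              ae_batch_size = cfg$ae$batch_size,
                              seed = cfg$seed)
    save_model(dm$ensemble, file.path(out_dir, "classifier.bin"))

    stage <- "evaluate"
    sp_real <- sparsity(tab)
    sp_gen <- sparsity(gen)
    sh_real <- apply(tab$values, 1L, shannon_index)
    sh_gen <- apply(gen$values, 1L, shannon_index)
    probs <- dm$predict(tab_te)
    test_metrics <- suppressWarnings(binary_metrics(probs, tab_te$labels))
    report <- list(
      config_hash = .config_hash(unclass(cfg)),
      seed = cfg$seed,
      n_samples = nrow(tab$values), n_otus = ncol(tab$values),
      n_generated = nrow(gen$values),
      realism = list(
        sparsity_real = sp_real$mean, sparsity_generated = sp_gen$mean,
        sparsity_range_real = sp_real$range, sparsity_range_generated = sp_gen$range,
        shannon_wilcoxon_p = compare_distributions(sh_real, sh_gen)
      ),
      test_metrics = list(auc = test_metrics$auc,
                          sensitivity = test_metrics$sensitivity,
                          specificity = test_metrics$specificity,
                          ppv = test_metrics$ppv, npv = test_metrics$npv)
    )
    if (isTRUE(cfg$eval$run_cv)) {
      cv <- cross_validate(tab_tr$values, tab_tr$labels,
                           .plain_cnn_fit(cnn), n_repeats = cfg$eval$n_repeats,
                           n_folds = cfg$eval$n_folds, seed = cfg$seed)
      report$cv <- list(mean_auc = cv$report$auc, ci = cv$report$auc_ci,
                        n_values = cv$report$n_cv_values)
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(list(config = unclass(cfg),
                              config_hash = report$config_hash,
                              seed = cfg$seed),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .log_line(log_con, stage, "done")
    report
  }, error = fail)
  invisible(report)
}

# fit_fun factory: plain (unaugmented) CNN on raw features, no taxonomy
.plain_cnn_fit <- function(cnn) {
  force(cnn)
  function(x_train, y_train, seed) {
    cnn$seed <- seed
    m <- train_ensemble(x_train, y_train, partition = NULL, cfg = cnn)
    function(x_test) predict_proba(m, x_test)
  }
}
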