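#' OTU abundance table
#'
#' Container for a samples x OTUs abundance matrix with optional binary
#' case/control labels. Abundances are either raw counts (`mode =
#' "counts"`) or per-sample proportions on the simplex (`mode =
#' "relative"`); all generative and predictive stages of the package
#' operate on relative abundances.
#'
#' @param values numeric matrix, samples in rows, OTUs in columns;
#'   nonnegative, finite.
#' @param sample_ids character vector of unique sample identifiers.
#' @param otu_ids character vector of unique OTU identifiers.
#' @param labels optional integer vector of 0/1 per sample (1 = case).
#' @param mode `"counts"` or `"relative"`. In relative mode every row
#'   must sum to 1 within `1e-6` and all-zero rows are forbidden.
#'
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(values, sample_ids = rownames(values),
                      otu_ids = colnames(values), labels = NULL,
                      mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(values)))
  if (is.null(otu_ids)) otu_ids <- paste0("otu_", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  dimnames(values) <- list(sample_ids, otu_ids)
  if (!is.null(labels)) {
    labels <- parse_labels(labels)
  }
  out <- structure(
    list(values = values, sample_ids = sample_ids, otu_ids = otu_ids,
         labels = labels, mode = mode),
    class = "otu_table"
  )
  validate_otu_table(out)
  out
}

# {0,1} integers or {control,case} strings -> 0/1 integer vector
parse_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    lab <- tolower(as.character(labels))
    if (!all(lab %in% c("0", "1", "control", "case"))) {
      stop("labels must be 0/1 or 'control'/'case'; got: ",
           paste(unique(setdiff(lab, c("0", "1", "control", "case"))), collapse = ", "))
    }
    labels <- ifelse(lab %in% c("1", "case"), 1L, 0L)
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must only contain 0 and 1")
  labels
}

validate_otu_table <- function(t) {
  v <- t$values
  if (anyNA(v) || any(!is.finite(v))) stop("OTU table contains NA/NaN/Inf values")
  if (any(v < 0)) stop("OTU table contains negative abundances")
  if (anyDuplicated(t$sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(t$sample_ids[duplicated(t$sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(t$otu_ids)) {
    stop("duplicate OTU ids: ",
         paste(unique(t$otu_ids[duplicated(t$otu_ids)]), collapse = ", "))
  }
  if (length(t$sample_ids) != nrow(v) || length(t$otu_ids) != ncol(v)) {
    stop("id vectors do not match matrix dimensions")
  }
  if (!is.null(t$labels)) {
    if (length(t$labels) != nrow(v)) stop("labels length must equal number of samples")
    if (!all(t$labels %in% c(0L, 1L))) stop("labels must be 0/1")
  }
  if (t$mode == "relative") {
    rs <- rowSums(v)
    if (any(rs == 0)) {
      stop("all-zero sample rows forbidden in relative mode: ",
           paste(t$sample_ids[rs == 0], collapse = ", "))
    }
    if (any(abs(rs - 1) > 1e-6)) {
      bad <- which.max(abs(rs - 1))
      stop("relative-mode rows must sum to 1 (sample '", t$sample_ids[bad],
           "' sums to ", format(rs[bad]), ")")
    }
  }
  invisible(t)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs (%s mode)%s\n",
              nrow(x$values), ncol(x$values), x$mode,
              if (is.null(x$labels)) "" else
                sprintf(", labels: %d cases / %d controls",
                        sum(x$labels == 1L), sum(x$labels == 0L))))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$values)

# sniff the field separator from the header line
.sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

#' Read an OTU table from delimited text
#'
#' Reads a comma- or tab-separated table (auto-detected) with a header
#' row and ids in the first column. The on-disk orientation may be
#' samples-in-rows or OTUs-in-rows; the returned table is always
#' samples x OTUs. Mode is inferred: an all-integer body is treated as
#' counts, otherwise as relative abundances whose rows must sum to 1.
#'
#' @param path file path.
#' @param orientation `"samples_rows"` (default) or `"otus_rows"`.
#' @param label_column optional name of a label column (dropped from the
#'   abundance matrix); values 0/1 or control/case.
#' @param labels_file optional two-column file (sample id, label) used
#'   when labels are stored separately.
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, orientation = c("samples_rows", "otus_rows"),
                           label_column = NULL, labels_file = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = NA,
                          row.names = NULL, comment.char = "")
  ids <- as.character(df[[1L]])
  col_ids <- names(df)[-1L]          # before subsetting, which dedupes names
  df <- df[, -1L, drop = FALSE]
  labels <- NULL
  if (!is.null(label_column)) {
    li <- which(col_ids == label_column)
    if (!length(li)) stop("label column '", label_column, "' not found")
    labels <- df[[li[1L]]]
    df <- df[, -li, drop = FALSE]
    col_ids <- col_ids[-li]
  }
  for (j in seq_along(df)) {
    col <- df[[j]]
    num <- suppressWarnings(as.numeric(col))
    if (anyNA(num) && !anyNA(col)) {
      i <- which(is.na(num))[1L]
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   col[i], i, col_ids[j]))
    }
    df[[j]] <- num
  }
  m <- as.matrix(df)
  if (orientation == "otus_rows") {
    m <- t(m)
    otu_ids <- ids
    sample_ids <- col_ids
  } else {
    sample_ids <- ids
    otu_ids <- col_ids
  }
  if (!is.null(labels_file)) {
    lf <- utils::read.table(labels_file, header = FALSE, sep = .sniff_sep(labels_file),
                            stringsAsFactors = FALSE)
    lab_map <- stats::setNames(lf[[2L]], as.character(lf[[1L]]))
    if (!all(sample_ids %in% names(lab_map))) {
      stop("labels file is missing samples: ",
           paste(setdiff(sample_ids, names(lab_map)), collapse = ", "))
    }
    labels <- lab_map[sample_ids]
  }
  mode <- if (all(m == round(m))) "counts" else "relative"
  if (mode == "relative") {
    rs <- rowSums(m)
    if (any(abs(rs - 1) > 1e-3)) {
      bad <- sample_ids[which.max(abs(rs - 1))]
      stop("non-integer table rows do not sum to 1 (sample '", bad,
           "'); if these are counts-per-volume or similar, run ",
           "normalize_relative_abundance() on a counts table instead")
    }
    m <- m / rs
  }
  otu_table(m, sample_ids, otu_ids, labels = labels, mode = mode)
}

#' Write an OTU table to delimited text
#'
#' Writes samples in rows, ids in the first column, optional `label`
#' column appended. The output round-trips through [read_otu_table()].
#'
#' @param t an [otu_table].
#' @param path output file path.
#' @param sep field separator, tab by default.
#' @export
write_otu_table <- function(t, path, sep = "\t") {
  validate_otu_table(t)
  df <- data.frame(sample_id = t$sample_ids, t$values, check.names = FALSE)
  if (!is.null(t$labels)) df$label <- t$labels
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a counts table to relative abundances
#'
#' Divides each sample row by its total count, placing every sample on
#' the probability simplex. Zeros stay exact zeros: no pseudocounts are
#' added, because the zero fraction (sparsity) is itself an evaluation
#' quantity downstream.
#'
#' @param t an [otu_table] in counts mode with positive row sums.
#' @return The table in relative mode; row sums are 1 within 1e-9.
#' @export
normalize_relative_abundance <- function(t) {
  validate_otu_table(t)
  if (t$mode != "counts") stop("table is already in relative mode")
  rs <- rowSums(t$values)
  if (any(rs == 0)) {
    stop("cannot normalize all-zero sample(s): ",
         paste(t$sample_ids[rs == 0], collapse = ", "))
  }
  otu_table(t$values / rs, t$sample_ids, t$otu_ids, labels = t$labels,
            mode = "relative")
}

#' Drop OTUs that are zero in every sample
#'
#' Removes feature columns with no nonzero entry in any individual,
#' preserving the order of the remaining columns.
#'
#' @param t an [otu_table].
#' @return A list with elements `table` (the filtered [otu_table]) and
#'   `removed_ids` (character vector of dropped OTU ids, original order).
#' @export
filter_all_zero_otus <- function(t) {
  validate_otu_table(t)
  keep <- colSums(t$values != 0) > 0
  if (!any(keep)) stop("filtering would remove every OTU")
  removed <- t$otu_ids[!keep]
  out <- otu_table(t$values[, keep, drop = FALSE], t$sample_ids,
                   t$otu_ids[keep], labels = t$labels, mode = t$mode)
  list(table = out, removed_ids = removed)
}
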