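#' Taxonomy map
#'
#' Maps OTU ids to lineage rank vectors (kingdom ... genus). Lineages
#' use semicolon-separated QIIME-style strings; `p__` prefixes are
#' accepted but optional. Every entry must carry a non-empty phylum.
#'
#' @param lineages named character vector or list: OTU id -> lineage
#'   string, e.g. `"k__Bacteria;p__Firmicutes;c__Clostridia;g__Blautia"`.
#' @return An object of class `taxonomy_map` with per-OTU rank vectors
#'   and a `phylum` lookup.
#' @export
taxonomy_map <- function(lineages) {
  ids <- names(lineages)
  if (is.null(ids) || anyDuplicated(ids)) stop("lineages must be uniquely named by OTU id")
  entries <- lapply(as.character(lineages), .parse_lineage)
  names(entries) <- ids
  phylum <- vapply(ids, function(id) {
    p <- entries[[id]]["phylum"]
    if (is.na(p) || !nzchar(p)) {
      stop("OTU '", id, "' has no phylum rank in its lineage")
    }
    p
  }, character(1))
  structure(list(entries = entries, phylum = phylum), class = "taxonomy_map")
}

.RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
.RANK_PREFIX <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
                  f = "family", g = "genus", s = "species")

.parse_lineage <- function(lineage) {
  toks <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1L]])
  out <- stats::setNames(rep(NA_character_, length(.RANKS)), .RANKS)
  prefixed <- grepl("^[kpcofgs]__", toks)
  if (any(prefixed)) {
    for (tk in toks[prefixed]) {
      rank <- .RANK_PREFIX[substr(tk, 1L, 1L)]
      out[rank] <- sub("^[kpcofgs]__", "", tk)
    }
  } else {
    n <- min(length(toks), length(.RANKS))
    out[seq_len(n)] <- toks[seq_len(n)]
  }
  out
}

#' @export
print.taxonomy_map <- function(x, ...) {
  cat(sprintf("taxonomy_map: %d OTUs, %d phyla\n",
              length(x$entries), length(unique(x$phylum))))
  invisible(x)
}

#' Phylum of each OTU
#'
#' @param tax a [taxonomy_map].
#' @param otu_ids OTU ids to look up; all must be present in the map.
#' @return Named character vector of phylum names.
#' @export
phylum_of <- function(tax, otu_ids) {
  missing <- setdiff(otu_ids, names(tax$phylum))
  if (length(missing)) {
    stop("OTUs missing from taxonomy: ", paste(missing, collapse = ", "))
  }
  tax$phylum[otu_ids]
}

#' Read a taxonomy map from a two-column file
#'
#' Expects delimited text (tab or comma, auto-detected) with OTU id in
#' the first column and a lineage string in the second; a header row is
#' tolerated when its first field is not reused as an OTU id elsewhere.
#'
#' @param path file path.
#' @return A [taxonomy_map].
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = FALSE, sep = sep, comment.char = "",
                          stringsAsFactors = FALSE, quote = "\"")
  if (ncol(df) < 2L) stop("taxonomy file needs two columns (OTU id, lineage)")
  # drop a header row if the second field clearly isn't a lineage
  if (nrow(df) > 1L && !grepl(";", df[[2L]][1L]) && grepl(";", df[[2L]][2L])) {
    df <- df[-1L, , drop = FALSE]
  }
  taxonomy_map(stats::setNames(df[[2L]], as.character(df[[1L]])))
}

#' Write a taxonomy map to a two-column TSV
#'
#' @param tax a [taxonomy_map].
#' @param path output file path.
#' @export
write_taxonomy <- function(tax, path) {
  lineage <- vapply(tax$entries, function(e) {
    e <- e[!is.na(e)]
    paste(paste0(substr(names(.RANK_PREFIX)[match(names(e), .RANK_PREFIX)], 1, 1),
                 "__", e), collapse = ";")
  }, character(1))
  utils::write.table(data.frame(otu_id = names(tax$entries), lineage = lineage),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
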