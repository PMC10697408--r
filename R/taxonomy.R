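#' Taxonomy assignments for ASVs
#'
#' A taxonomy map links feature ids to SILVA-style lineages: semicolon
#' separated rank labels, optionally carrying rank prefixes (`d__`, `p__`,
#' `c__`, `o__`, `f__`, `g__`, `s__`), at most seven ranks deep. A lineage
#' may be the single label `Unassigned`. Prefixes are retained for matching;
#' genus-name extraction strips `g__`.
#'
#' @param df Data frame with columns `feature_id`, `taxon` and optionally
#'   `confidence`.
#' @return A `taxonomy_map` data frame.
#' @export
taxonomy_map <- function(df) {
  if (!all(c("feature_id", "taxon") %in% names(df))) {
    fmt_stop("taxonomy requires 'feature_id' and 'taxon' columns")
  }
  out <- data.frame(
    feature_id = as.character(df$feature_id),
    taxon = as.character(df$taxon),
    confidence = if ("confidence" %in% names(df)) {
      suppressWarnings(as.numeric(df$confidence))
    } else {
      NA_real_
    },
    stringsAsFactors = FALSE
  )
  dup <- out$feature_id[duplicated(out$feature_id)]
  if (length(dup)) fmt_stop("duplicate taxonomy feature id(s): %s",
                            paste(unique(dup), collapse = ", "))
  n_ranks <- lengths(strsplit(out$taxon, ";", fixed = TRUE))
  if (any(n_ranks > 7L)) {
    fmt_stop("lineage with more than 7 ranks for feature '%s'",
             out$feature_id[which(n_ranks > 7L)[1L]])
  }
  class(out) <- c("taxonomy_map", "data.frame")
  out
}

#' Read a taxonomy assignment table
#'
#' Expects the exporter dialect with header `Feature ID`, `Taxon` and an
#' optional `Confidence` column. Lineages are kept verbatim; splitting and
#' prefix handling happen in [taxonomy_lineages()] and [feature_genus()].
#'
#' @param path Path to the taxonomy TSV.
#' @return A [taxonomy_map()] data frame.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) fmt_stop("taxonomy file not found: %s", path)
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           comment.char = "")
  if (!"Taxon" %in% names(raw)) fmt_stop("taxonomy file missing 'Taxon' column")
  if (!"Feature ID" %in% names(raw)) fmt_stop("taxonomy file missing 'Feature ID' column")
  df <- data.frame(
    feature_id = raw[["Feature ID"]],
    taxon = raw[["Taxon"]],
    stringsAsFactors = FALSE
  )
  if ("Confidence" %in% names(raw)) df$confidence <- raw[["Confidence"]]
  taxonomy_map(df)
}

#' Write a taxonomy map in the exporter dialect
#' @param tax A [taxonomy_map()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_taxonomy <- function(tax, path) {
  stopifnot(inherits(tax, "taxonomy_map"))
  out <- data.frame(
    `Feature ID` = tax$feature_id, Taxon = tax$taxon,
    Confidence = ifelse(is.na(tax$confidence), "", format(tax$confidence)),
    check.names = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split lineages into rank-label vectors
#'
#' @param tax A [taxonomy_map()].
#' @return Named list (by feature id) of trimmed rank labels, prefixes
#'   retained.
#' @export
taxonomy_lineages <- function(tax) {
  stopifnot(inherits(tax, "taxonomy_map"))
  lin <- strsplit(tax$taxon, ";", fixed = TRUE)
  lin <- lapply(lin, function(x) trimws(x))
  names(lin) <- tax$feature_id
  lin
}

strip_rank_prefix <- function(x) sub("^[a-z]__", "", x)

# genus label for one split lineage; "" when unresolved at genus level
lineage_genus <- function(ranks) {
  stripped <- strip_rank_prefix(ranks)
  g <- which(startsWith(ranks, "g__"))
  if (length(g)) {
    return(stripped[g[[1L]]])
  }
  # prefix-less lineages: genus is positional (rank 6 of 7)
  if (!any(grepl("^[a-z]__", ranks)) && length(ranks) >= 6L && nzchar(stripped[[6L]])) {
    return(stripped[[6L]])
  }
  ""
}

# label used when the genus rank is empty: Unclassified_<lowest named rank>,
# or "Unassigned" when nothing is named / no record exists
lineage_fallback_label <- function(ranks) {
  stripped <- strip_rank_prefix(ranks)
  named <- stripped[nzchar(stripped)]
  if (!length(named) || identical(tolower(named[[1L]]), "unassigned")) {
    return("Unassigned")
  }
  paste0("Unclassified_", named[[length(named)]])
}

#' Genus labels for features
#'
#' Maps feature ids to genus names, stripping the `g__` prefix. Features
#' resolved only to a higher rank get `Unclassified_<lowest named rank>`;
#' features absent from the map, or assigned the single label `Unassigned`,
#' get `"Unassigned"`.
#'
#' @param tax A [taxonomy_map()].
#' @param feature_ids Character vector of feature ids.
#' @return Character vector of genus labels, same length and order.
#' @export
feature_genus <- function(tax, feature_ids) {
  lin <- taxonomy_lineages(tax)
  vapply(feature_ids, function(f) {
    ranks <- lin[[f]]
    if (is.null(ranks)) {
      return("Unassigned")
    }
    g <- lineage_genus(ranks)
    if (nzchar(g)) g else lineage_fallback_label(ranks)
  }, character(1L), USE.NAMES = FALSE)
}
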