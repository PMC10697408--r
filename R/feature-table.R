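#' Construct a validated ASV feature table
#'
#' A feature table is an integer count matrix with ASVs (features) as rows
#' and samples as columns — the central object of the pipeline. Construction
#' enforces the invariants every downstream stage relies on: non-negative
#' integral counts, unique row and column identifiers, and at least one
#' feature and one sample.
#'
#' @param counts Numeric matrix of counts, features x samples, with
#'   `dimnames` giving feature and sample identifiers.
#' @return A `feature_table` object (a classed integer-valued matrix).
#' @examples
#' ft <- feature_table(matrix(c(10, 5, 0, 7), 2,
#'   dimnames = list(c("ASV1", "ASV2"), c("S1", "S2"))))
#' @export
feature_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    fmt_stop("feature table counts must be a numeric matrix")
  }
  if (nrow(counts) < 1L || ncol(counts) < 1L) {
    fmt_stop("feature table must have at least one feature and one sample")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    fmt_stop("feature table requires feature (row) and sample (column) names")
  }
  if (anyNA(counts) || any(!is.finite(counts))) {
    fmt_stop("feature table contains missing or non-finite counts")
  }
  if (any(counts < 0)) {
    fmt_stop("feature table contains negative counts")
  }
  if (any(counts != round(counts))) {
    fmt_stop("feature table contains non-integer counts")
  }
  dup_f <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup_f)) {
    fmt_stop("duplicate feature id(s): %s", paste(unique(dup_f), collapse = ", "))
  }
  dup_s <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup_s)) {
    fmt_stop("duplicate sample id(s): %s", paste(unique(dup_s), collapse = ", "))
  }
  storage.mode(counts) <- "double" # counts stay integral; double avoids 2^31 overflow
  structure(counts, class = c("feature_table", "matrix", "array"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d features x %d samples; total reads %s\n",
    nrow(x), ncol(x), format(sum(x), big.mark = ",", scientific = FALSE)
  ))
  invisible(x)
}

is_feature_table <- function(x) inherits(x, "feature_table")

# strip the class so base matrix ops behave predictably
unclass_matrix <- function(x) {
  class(x) <- c("matrix", "array")
  x
}

#' Read a feature table from TSV
#'
#' Two dialects are supported. `plain` expects a header whose first column is
#' `feature_id`; `biom_tsv` is the TSV export dialect of BIOM tools: an
#' optional single leading `#`-prefixed comment line (e.g.
#' `# Constructed from biom file`) followed by a header whose first column is
#' `#OTU ID`. Features are rows, samples are columns in both dialects.
#'
#' @param path Path to a tab-separated file.
#' @param dialect `"plain"` or `"biom_tsv"`.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, dialect = c("plain", "biom_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) fmt_stop("feature table file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (dialect == "biom_tsv" && length(lines) &&
      startsWith(lines[[1L]], "#") && !startsWith(lines[[1L]], "#OTU ID")) {
    lines <- lines[-1L]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) fmt_stop("feature table is empty: %s", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  expected_first <- if (dialect == "biom_tsv") "#OTU ID" else "feature_id"
  if (!identical(header[[1L]], expected_first)) {
    fmt_stop(
      "feature table header must start with '%s' (dialect %s); found '%s'",
      expected_first, dialect, header[[1L]]
    )
  }
  sample_ids <- header[-1L]
  if (length(sample_ids) < 1L) fmt_stop("feature table has no sample columns: %s", path)
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) fmt_stop("duplicate sample id(s) in header: %s", paste(dup, collapse = ", "))

  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != length(header))
  if (length(bad)) {
    fmt_stop("row %d has %d fields; expected %d", bad[[1L]] + 1L,
             lengths(rows)[bad[[1L]]], length(header))
  }
  feature_ids <- vapply(rows, `[[`, character(1L), 1L)
  dup <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup)) fmt_stop("duplicate feature id(s): %s", paste(dup, collapse = ", "))
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[-1L]), numeric(length(sample_ids)))
  )
  vals <- matrix(vals, nrow = length(sample_ids)) # vapply gives samples x features
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    fmt_stop(
      "non-numeric count at feature '%s', sample '%s'",
      feature_ids[idx[[2L]]], sample_ids[idx[[1L]]]
    )
  }
  counts <- t(vals)
  dimnames(counts) <- list(feature_ids, sample_ids)
  feature_table(counts)
}

#' Write a feature table as plain-dialect TSV
#'
#' Emits the `plain` dialect accepted by [read_feature_table()]; reading the
#' file back reproduces the table exactly (integer equality). Identifiers
#' must be free of tabs and newlines since the format cannot escape them.
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is_feature_table(table))
  ids <- c(rownames(table), colnames(table))
  bad <- ids[grepl("[\t\n\r]", ids)]
  if (length(bad)) {
    fmt_stop("identifier contains tab/newline and cannot be written: '%s'", bad[[1L]])
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(table)), collapse = "\t"), con)
  body <- apply(unclass_matrix(table), 1L, function(r) {
    paste(format(r, scientific = FALSE, trim = TRUE), collapse = "\t")
  })
  writeLines(paste(rownames(table), body, sep = "\t"), con)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides each sample's column by its total so columns sum to one. Relative
#' tables are a distinct class from count tables so that threshold-based
#' operations (which are only meaningful on fractions) cannot be run on raw
#' counts by mistake.
#'
#' @param table A [feature_table()].
#' @param drop_empty Drop all-zero samples (with a message) instead of
#'   raising an error. All-zero samples usually signal an upstream failure,
#'   so the default is to refuse them.
#' @return A `rel_abundance_table` (classed numeric matrix, columns sum to 1).
#' @export
to_relative <- function(table, drop_empty = FALSE) {
  stopifnot(is_feature_table(table))
  totals <- colSums(table)
  empty <- names(totals)[totals == 0]
  if (length(empty)) {
    if (!drop_empty) {
      fmt_stop("all-zero sample(s): %s (use drop_empty = TRUE to discard)",
               paste(empty, collapse = ", "))
    }
    message("to_relative: dropping all-zero sample(s): ", paste(empty, collapse = ", "))
    keep <- totals > 0
    if (!any(keep)) fmt_stop("all samples are empty")
    table <- feature_table(unclass_matrix(table)[, keep, drop = FALSE])
    totals <- totals[keep]
  }
  rel <- sweep(unclass_matrix(table), 2L, totals, "/")
  structure(rel, class = c("rel_abundance_table", "matrix", "array"))
}

is_rel_table <- function(x) inherits(x, "rel_abundance_table")

#' @export
print.rel_abundance_table <- function(x, ...) {
  cat(sprintf("<rel_abundance_table> %d features x %d samples\n", nrow(x), ncol(x)))
  invisible(x)
}

# internal constructor for matrices already normalised columnwise
rel_abundance_table <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(dimnames(mat)))
  if (any(mat < -1e-12) || any(mat > 1 + 1e-12)) {
    fmt_stop("relative abundances must lie in [0, 1]")
  }
  sums <- colSums(mat)
  if (any(abs(sums - 1) > 1e-9)) {
    fmt_stop("relative abundance columns must sum to 1 (max deviation %.3g)",
             max(abs(sums - 1)))
  }
  structure(mat, class = c("rel_abundance_table", "matrix", "array"))
}
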