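#' Align a feature table, metadata and taxonomy into one dataset
#'
#' Validates cross-references between the three inputs and normalises sample
#' order to `(subject, substrate, day, timepoint)`. Every sample in the
#' table must be described by metadata (an undescribed sample is an error
#' naming it); metadata rows for samples absent from the table are dropped
#' with a warning. Features missing from the taxonomy are retained here and
#' flagged — the organelle/unassigned filter decides their fate.
#'
#' Aligning an already-aligned dataset is a no-op.
#'
#' @param table A [feature_table()].
#' @param meta A [sample_metadata()] data frame.
#' @param tax A [taxonomy_map()].
#' @return An `asv_dataset`: list with elements `table`, `meta`, `tax`,
#'   `unassigned_features` (ids with no taxonomy record).
#' @export
align_dataset <- function(table, meta, tax) {
  stopifnot(is_feature_table(table), inherits(meta, "sample_metadata"),
            inherits(tax, "taxonomy_map"))
  tbl_samples <- colnames(table)
  meta_samples <- meta$sample_id

  missing_meta <- setdiff(tbl_samples, meta_samples)
  if (length(missing_meta)) {
    fmt_stop("sample(s) in table but not in metadata: %s",
             paste(missing_meta, collapse = ", "))
  }
  overlap <- intersect(meta_samples, tbl_samples)
  if (!length(overlap)) fmt_stop("no overlapping samples between table and metadata")
  extra <- setdiff(meta_samples, tbl_samples)
  if (length(extra)) {
    fmt_warn("metadata sample(s) absent from table, ignored: %s",
             paste(extra, collapse = ", "))
  }
  meta <- meta[meta$sample_id %in% overlap, , drop = FALSE]
  ord <- order(meta$subject, meta$substrate, meta$day, meta$timepoint,
               method = "radix")
  meta <- meta[ord, , drop = FALSE]
  rownames(meta) <- NULL
  class(meta) <- c("sample_metadata", "data.frame")

  table <- feature_table(unclass_matrix(table)[, meta$sample_id, drop = FALSE])
  unassigned <- setdiff(rownames(table), tax$feature_id)
  structure(
    list(table = table, meta = meta, tax = tax, unassigned_features = unassigned),
    class = "asv_dataset"
  )
}

#' @export
print.asv_dataset <- function(x, ...) {
  cat(sprintf(
    "<asv_dataset> %d features x %d samples; %d subject(s); %d feature(s) without taxonomy\n",
    nrow(x$table), ncol(x$table), length(unique(x$meta$subject)),
    length(x$unassigned_features)
  ))
  invisible(x)
}
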