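#' Remove chloroplast, mitochondrial and unassigned ASVs
#'
#' 16S rRNA amplicon surveys pick up organelle sequences (chloroplast 16S,
#' mitochondrial 12S-like) that are not part of the bacterial community, and
#' ASVs the classifier could not place at all. Both are excluded before any
#' community-level statistic. Removal rules, first match wins:
#'
#' 1. any lineage rank contains `"chloroplast"` (case-insensitive);
#' 2. else any rank contains `"mitochondri"` (catching both "Mitochondria"
#'    and "Mitochondrial" across database releases);
#' 3. else the feature has no taxonomy record, or its entire lineage is the
#'    single label `Unassigned` (case-insensitive).
#'
#' Lineages resolved only to a higher rank (e.g. domain alone) are kept:
#' "unassigned" means unplaced, not poorly resolved. Set `min_ranks` to also
#' drop lineages with fewer than that many named ranks.
#'
#' @param table A [feature_table()].
#' @param tax A [taxonomy_map()].
#' @param min_ranks Minimum number of named leading ranks required to keep a
#'   feature; `0` (default) disables the rule.
#' @return List with `table` (filtered [feature_table()]) and `report`
#'   (a `filter_report`: removal reasons plus exact per-sample read
#'   accounting, `reads_removed + reads_retained` equalling the original
#'   totals).
#' @export
filter_organelle_unassigned <- function(table, tax, min_ranks = 0L) {
  stopifnot(is_feature_table(table), inherits(tax, "taxonomy_map"))
  lin <- taxonomy_lineages(tax)
  reason <- vapply(rownames(table), function(f) {
    ranks <- lin[[f]]
    if (is.null(ranks)) {
      return("unassigned")
    }
    if (any(grepl("chloroplast", ranks, ignore.case = TRUE))) {
      return("chloroplast")
    }
    if (any(grepl("mitochondri", ranks, ignore.case = TRUE))) {
      return("mitochondria")
    }
    named <- strip_rank_prefix(ranks)
    named <- named[nzchar(named)]
    if (length(named) == 1L && tolower(named) == "unassigned") {
      return("unassigned")
    }
    if (min_ranks > 0L && length(named) < min_ranks) {
      return("unassigned")
    }
    ""
  }, character(1L))

  removed <- reason != ""
  totals <- colSums(table)
  removed_reads <- if (any(removed)) {
    colSums(unclass_matrix(table)[removed, , drop = FALSE])
  } else {
    setNames(numeric(ncol(table)), colnames(table))
  }
  report <- structure(
    list(
      removed = data.frame(
        feature_id = rownames(table)[removed],
        reason = unname(reason[removed]),
        stringsAsFactors = FALSE
      ),
      reads_removed = removed_reads,
      reads_retained = totals - removed_reads
    ),
    class = "filter_report"
  )
  if (all(removed)) {
    fmt_warn("organelle/unassigned filter removed every feature")
    return(list(table = NULL, report = report))
  }
  list(
    table = feature_table(unclass_matrix(table)[!removed, , drop = FALSE]),
    report = report
  )
}

#' @export
print.filter_report <- function(x, ...) {
  tab <- table(x$removed$reason)
  cat(sprintf(
    "<filter_report> %d feature(s) removed (%s); %s reads removed of %s\n",
    nrow(x$removed),
    if (length(tab)) paste(names(tab), tab, sep = ": ", collapse = ", ") else "none",
    format(sum(x$reads_removed), scientific = FALSE),
    format(sum(x$reads_removed + x$reads_retained), scientific = FALSE)
  ))
  invisible(x)
}

#' Serialise a filter report to TSV
#'
#' Writes two files: `<stem>_features.tsv` (feature_id, reason) and
#' `<stem>_reads.tsv` (sample-id, reads_removed, reads_retained).
#'
#' @param report A `filter_report`.
#' @param stem Output path stem.
#' @return Invisibly, the two paths written.
#' @export
write_filter_report <- function(report, stem) {
  stopifnot(inherits(report, "filter_report"))
  p1 <- paste0(stem, "_features.tsv")
  p2 <- paste0(stem, "_reads.tsv")
  utils::write.table(report$removed, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  acc <- data.frame(
    `sample-id` = names(report$reads_removed),
    reads_removed = as.integer(report$reads_removed),
    reads_retained = as.integer(report$reads_retained),
    check.names = FALSE
  )
  utils::write.table(acc, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Collapse a relative-abundance table to genus level
#'
#' Rows are re-keyed by genus name (`g__` prefix stripped). Features whose
#' lineage stops above genus are keyed `Unclassified_<lowest named rank>`;
#' features with no usable lineage fall into `Unassigned`. Each sample's
#' total abundance is preserved.
#'
#' @param rel A `rel_abundance_table` (see [to_relative()]), organelle
#'   filtering already applied.
#' @param tax A [taxonomy_map()].
#' @return A genus x sample `rel_abundance_table`.
#' @export
collapse_genus <- function(rel, tax) {
  stopifnot(is_rel_table(rel), inherits(tax, "taxonomy_map"))
  genus <- feature_genus(tax, rownames(rel))
  out <- rowsum(unclass_matrix(rel), group = genus, reorder = TRUE)
  rel_abundance_table(out)
}

#' Top-N genus summary with a remainder row
#'
#' Ranks genera by their mean relative abundance across all samples of the
#' table (ties broken lexicographically), keeps the top `n` under their own
#' names, and sums everything else into a `remainder` row — the standard
#' stacked-bar composition summary. Column sums are preserved; when `n`
#' covers every genus the remainder row is all zeros.
#'
#' @param genus_table Genus-level `rel_abundance_table` from [collapse_genus()].
#' @param n Number of named genera to keep (default 15).
#' @return A `rel_abundance_table` with at most `n` named rows plus
#'   `remainder`.
#' @export
top_n_summary <- function(genus_table, n = 15L) {
  stopifnot(is_rel_table(genus_table))
  if (!is_count(n) || n < 1) fmt_stop("n must be a positive integer")
  mat <- unclass_matrix(genus_table)
  means <- rowMeans(mat)
  ord <- order(-means, rownames(mat), method = "radix")
  top <- ord[seq_len(min(n, nrow(mat)))]
  rest <- setdiff(seq_len(nrow(mat)), top)
  remainder <- if (length(rest)) {
    colSums(mat[rest, , drop = FALSE])
  } else {
    setNames(numeric(ncol(mat)), colnames(mat))
  }
  out <- rbind(mat[top, , drop = FALSE], remainder = remainder)
  rel_abundance_table(out)
}
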