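#' Build source-sink sample pairs under the study's two pairing rules
#'
#' During the contact phase (days 0-14) each skin sample — including both
#' day-0 timepoints, before (`"0"`) and six hours after (`"0'"`) the first
#' stir — is paired with the same subject's same-day Nukadoko sample. During
#' the no-contact phase (days 15+) each skin sample is paired with that
#' subject's Nukadoko sample from a fixed day, by default 14, the last day
#' the bed was sampled. Skin samples without an available partner are
#' reported as unpaired rows with a reason, never silently dropped.
#'
#' @param meta A [sample_metadata()] data frame containing both substrates.
#' @param source_day Fixed Nukadoko day used for no-contact pairs (default 14).
#' @return A `sample_pairs` data frame: `subject`, `day`, `timepoint`,
#'   `phase`, `source_sample_id`, `sink_sample_id`, `paired`, `reason`.
#' @export
build_pairs <- function(meta, source_day = 14L) {
  stopifnot(inherits(meta, "sample_metadata"))
  if (!is_count(source_day)) fmt_stop("source_day must be a non-negative integer")
  skin <- meta[meta$substrate == "skin", , drop = FALSE]
  nuka <- meta[meta$substrate == "nukadoko", , drop = FALSE]
  if (!nrow(skin) || !nrow(nuka)) {
    fmt_stop("metadata must contain both 'skin' and 'nukadoko' samples")
  }
  res <- lapply(seq_len(nrow(skin)), function(i) {
    row <- skin[i, ]
    want_day <- if (row$phase == "contact") row$day else as.integer(source_day)
    hit <- nuka[nuka$subject == row$subject & nuka$day == want_day, , drop = FALSE]
    if (nrow(hit) == 0L) {
      return(data.frame(
        subject = row$subject, day = row$day, timepoint = row$timepoint,
        phase = row$phase, source_sample_id = NA_character_,
        sink_sample_id = row$sample_id, paired = FALSE,
        reason = sprintf("no nukadoko sample for subject %s on day %d",
                         row$subject, want_day),
        stringsAsFactors = FALSE
      ))
    }
    if (nrow(hit) > 1L) {
      fmt_warn("multiple nukadoko samples for subject %s day %d; using '%s'",
               row$subject, want_day, hit$sample_id[[1L]])
    }
    data.frame(
      subject = row$subject, day = row$day, timepoint = row$timepoint,
      phase = row$phase, source_sample_id = hit$sample_id[[1L]],
      sink_sample_id = row$sample_id, paired = TRUE, reason = NA_character_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("sample_pairs", "data.frame")
  out
}

#' Shared ASVs between one source/sink pair
#'
#' An ASV is *shared* when its relative abundance exceeds the threshold in
#' both samples of the pair. The comparison is strict by default (the
#' statistic is defined with ">"): a feature at exactly the threshold is
#' not shared. `comparison = "ge"` switches to ">=" for sensitivity
#' analysis. The threshold is a fraction (default 0.01 = 1%) in all
#' interfaces; percentages appear only in reports.
#'
#' @param source_rel Named relative-abundance vector for the source sample.
#' @param sink_rel Named relative-abundance vector for the sink sample, over
#'   the same feature universe.
#' @param threshold Abundance threshold as a fraction, in `[0, 1)`.
#' @param comparison `"gt"` (strict, default) or `"ge"`.
#' @return Character vector of shared feature ids (in source order).
#' @export
find_shared_asvs <- function(source_rel, sink_rel, threshold = 0.01,
                             comparison = c("gt", "ge")) {
  comparison <- match.arg(comparison)
  if (is.null(names(source_rel)) || is.null(names(sink_rel))) {
    fmt_stop("abundance vectors must be named by feature id")
  }
  if (length(source_rel) != length(sink_rel) ||
      !setequal(names(source_rel), names(sink_rel))) {
    fmt_stop("source and sink vectors cover different feature universes")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 1) {
    fmt_stop("threshold must be a fraction in [0, 1)")
  }
  sink_rel <- sink_rel[names(source_rel)]
  hit <- if (comparison == "gt") {
    source_rel > threshold & sink_rel > threshold
  } else {
    source_rel >= threshold & sink_rel >= threshold
  }
  names(source_rel)[hit]
}

#' Sink-side shared proportion
#'
#' The summed relative abundance, in the sink (skin) sample, of all shared
#' ASVs, expressed as a percentage. This sink weighting is the statistic
#' plotted over time; for a source-weighted variant sum over the source
#' vector instead.
#'
#' @param sink_rel Named relative-abundance vector for the sink sample.
#' @param shared Character vector of shared feature ids, a subset of
#'   `names(sink_rel)`.
#' @return Percentage in `[0, 100]`.
#' @export
shared_proportion <- function(sink_rel, shared) {
  if (length(shared) == 0L) {
    return(0)
  }
  missing <- setdiff(shared, names(sink_rel))
  if (length(missing)) {
    fmt_stop("shared feature(s) absent from sink vector: %s",
             paste(missing, collapse = ", "))
  }
  100 * sum(sink_rel[shared])
}

#' Shared-ASV timecourse over all pairs
#'
#' Runs [find_shared_asvs()] and [shared_proportion()] over every pair
#' produced by [build_pairs()], in metadata order. Unpaired skin samples are
#' carried as explicit gap rows (`NA` proportion, reason filled). The
#' per-pair shared sets are attached as the `"shared_sets"` attribute,
#' named by sink sample id, for downstream taxonomic breakdowns.
#'
#' @param rel A `rel_abundance_table` over the aligned, organelle-filtered
#'   dataset (see [to_relative()]).
#' @param meta A [sample_metadata()] covering the table's samples.
#' @param threshold Shared-ASV threshold, fraction (default 0.01).
#' @param source_day Fixed source day for no-contact pairs (default 14).
#' @param comparison `"gt"` or `"ge"`, see [find_shared_asvs()].
#' @return A `shared_timecourse` data frame: `subject`, `day`, `timepoint`,
#'   `phase`, `source_sample`, `sink_sample`, `threshold`, `n_shared`,
#'   `shared_proportion_percent`, `reason`.
#' @export
shared_timecourse <- function(rel, meta, threshold = 0.01, source_day = 14L,
                              comparison = c("gt", "ge")) {
  stopifnot(is_rel_table(rel))
  comparison <- match.arg(comparison)
  pairs <- build_pairs(meta, source_day = source_day)
  missing <- setdiff(
    c(pairs$source_sample_id[pairs$paired], pairs$sink_sample_id),
    colnames(rel)
  )
  if (length(missing)) {
    fmt_stop("paired sample(s) absent from abundance table: %s",
             paste(missing, collapse = ", "))
  }
  sets <- vector("list", nrow(pairs))
  n_shared <- integer(nrow(pairs))
  prop <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (!pairs$paired[[i]]) {
      sets[[i]] <- character()
      n_shared[[i]] <- NA_integer_
      next
    }
    src <- unclass_matrix(rel)[, pairs$source_sample_id[[i]]]
    snk <- unclass_matrix(rel)[, pairs$sink_sample_id[[i]]]
    shared <- find_shared_asvs(src, snk, threshold = threshold,
                               comparison = comparison)
    sets[[i]] <- shared
    n_shared[[i]] <- length(shared)
    prop[[i]] <- shared_proportion(snk, shared)
  }
  out <- data.frame(
    subject = pairs$subject, day = pairs$day, timepoint = pairs$timepoint,
    phase = pairs$phase, source_sample = pairs$source_sample_id,
    sink_sample = pairs$sink_sample_id, threshold = threshold,
    n_shared = n_shared, shared_proportion_percent = prop,
    reason = pairs$reason, stringsAsFactors = FALSE
  )
  names(sets) <- pairs$sink_sample_id
  attr(out, "shared_sets") <- sets
  class(out) <- c("shared_timecourse", "data.frame")
  out
}

#' @export
print.shared_timecourse <- function(x, ...) {
  cat(sprintf(
    "<shared_timecourse> %d pair rows (%d paired), threshold %.4g; proportions %.3g-%.3g%%\n",
    nrow(x), sum(!is.na(x$shared_proportion_percent)),
    x$threshold[[1L]],
    suppressWarnings(min(x$shared_proportion_percent, na.rm = TRUE)),
    suppressWarnings(max(x$shared_proportion_percent, na.rm = TRUE))
  ))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Persistence of shared ASVs after contact stops
#'
#' For each subject, the latest no-contact-phase day on which the shared set
#' was non-empty — the observable signature of transferred bacteria still
#' detectable after stirring stopped.
#'
#' @param timecourse A `shared_timecourse` covering the no-contact phase.
#' @return Data frame: `subject`, `last_detected_day` (`NA` when never
#'   detected), `detected` (logical).
#' @export
persistence_summary <- function(timecourse) {
  stopifnot(inherits(timecourse, "shared_timecourse"))
  nc <- timecourse[timecourse$phase == "no_contact" &
                     !is.na(timecourse$shared_proportion_percent), , drop = FALSE]
  subjects <- unique(timecourse$subject)
  last_day <- vapply(subjects, function(s) {
    d <- nc$day[nc$subject == s & nc$shared_proportion_percent > 0]
    if (length(d)) max(d) else NA_integer_
  }, integer(1L))
  data.frame(
    subject = subjects, last_detected_day = last_day,
    detected = !is.na(last_day), row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Genus-level breakdown of shared-ASV contributions
#'
#' Splits each pair's sink-side shared proportion by genus (via
#' [feature_genus()]; features without a taxonomy record fall into the
#' `Unassigned` bucket). Per pair, the genus contributions sum exactly to
#' the pair's shared proportion.
#'
#' @param timecourse A `shared_timecourse` (carries the per-pair shared sets).
#' @param rel The `rel_abundance_table` the timecourse was computed from.
#' @param tax A [taxonomy_map()].
#' @return Data frame: `subject`, `day`, `timepoint`, `genus`,
#'   `contribution_percent`, one row per (pair, genus) with a non-empty
#'   shared set.
#' @export
shared_taxa_breakdown <- function(timecourse, rel, tax) {
  stopifnot(inherits(timecourse, "shared_timecourse"), is_rel_table(rel),
            inherits(tax, "taxonomy_map"))
  sets <- attr(timecourse, "shared_sets")
  rows <- list()
  for (i in seq_len(nrow(timecourse))) {
    shared <- sets[[timecourse$sink_sample[[i]]]]
    if (is.null(shared) || !length(shared)) next
    snk <- unclass_matrix(rel)[, timecourse$sink_sample[[i]]]
    genus <- feature_genus(tax, shared)
    contrib <- tapply(100 * snk[shared], genus, sum)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = timecourse$subject[[i]], day = timecourse$day[[i]],
      timepoint = timecourse$timepoint[[i]], genus = names(contrib),
      contribution_percent = as.numeric(contrib),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(
      subject = character(), day = integer(), timepoint = character(),
      genus = character(), contribution_percent = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
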