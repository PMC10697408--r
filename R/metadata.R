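#' Sample metadata for the paired source/sink study design
#'
#' Metadata drives pairing: each record carries the subject, the substrate
#' (`nukadoko`, the fermented rice-bran source, or `skin`, the palm sink),
#' the study day, a timepoint label, and the study phase. The study
#' convention splits the month into a `contact` phase (days 0-14, daily
#' stirring of the bed by hand) and a `no_contact` phase (days 15-29). Day 0
#' carries two skin timepoints: `"0"` before the first interaction and
#' `"0'"` six hours after it.
#'
#' @param df Data frame with columns `sample_id`, `subject`, `substrate`,
#'   `day`, `timepoint`, `phase`.
#' @return A `sample_metadata` data frame.
#' @export
sample_metadata <- function(df) {
  required <- c("sample_id", "subject", "substrate", "day", "timepoint", "phase")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    fmt_stop("metadata missing column(s): %s", paste(missing, collapse = ", "))
  }
  df <- as.data.frame(df)[required]
  df$sample_id <- as.character(df$sample_id)
  df$subject <- as.character(df$subject)
  df$substrate <- as.character(df$substrate)
  df$timepoint <- as.character(df$timepoint)
  df$phase <- as.character(df$phase)

  bad <- setdiff(unique(df$substrate), c("nukadoko", "skin"))
  if (length(bad)) {
    fmt_stop("unknown substrate value(s): %s (expected nukadoko/skin)",
             paste(bad, collapse = ", "))
  }
  bad <- setdiff(unique(df$phase), c("contact", "no_contact"))
  if (length(bad)) {
    fmt_stop("unknown phase value(s): %s (expected contact/no_contact)",
             paste(bad, collapse = ", "))
  }
  day <- suppressWarnings(as.numeric(df$day))
  if (anyNA(day) || any(day < 0) || any(day != round(day))) {
    fmt_stop("metadata 'day' must be a non-negative integer")
  }
  df$day <- as.integer(day)

  # phase is determined by day under the study convention
  expected <- ifelse(df$day <= 14L, "contact", "no_contact")
  off <- which(df$phase != expected)
  if (length(off)) {
    fmt_stop(
      "phase/day mismatch for sample '%s' (day %d, phase '%s'): contact iff day <= 14",
      df$sample_id[off[[1L]]], df$day[off[[1L]]], df$phase[off[[1L]]]
    )
  }

  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) fmt_stop("duplicate sample id(s): %s", paste(unique(dup), collapse = ", "))
  key <- paste(df$subject, df$substrate, df$timepoint, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    fmt_stop(
      "duplicate (subject, substrate, timepoint): (%s, %s, %s)",
      df$subject[dup[[1L]]], df$substrate[dup[[1L]]], df$timepoint[dup[[1L]]]
    )
  }
  rownames(df) <- NULL
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read sample metadata from TSV
#'
#' Expects a header `sample-id  subject  substrate  day  timepoint  phase`
#' (tab-separated). Vocabulary (`substrate`, `phase`), day/phase consistency
#' and `(subject, substrate, timepoint)` uniqueness are enforced.
#'
#' @param path Path to the metadata TSV.
#' @return A [sample_metadata()] data frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) fmt_stop("metadata file not found: %s", path)
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           comment.char = "")
  required <- c("sample-id", "subject", "substrate", "day", "timepoint", "phase")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    fmt_stop("metadata missing column(s): %s", paste(missing, collapse = ", "))
  }
  names(raw)[names(raw) == "sample-id"] <- "sample_id"
  sample_metadata(raw)
}

#' Write sample metadata as TSV
#'
#' @param meta A [sample_metadata()] data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metadata <- function(meta, path) {
  stopifnot(inherits(meta, "sample_metadata"))
  out <- as.data.frame(meta)
  names(out)[names(out) == "sample_id"] <- "sample-id"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
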