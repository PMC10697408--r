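IUPAC_NT <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")

# normalise a sequence for QC: upper-case, RNA U -> T
normalize_seq <- function(sequence) {
  s <- toupper(sequence)
  chartr("U", "T", s)
}

validate_alphabet <- function(sequence) {
  s <- toupper(sequence)
  bad <- regmatches(s, gregexpr(sprintf("[^%s]", paste(IUPAC_NT, collapse = "")), s))
  offenders <- unique(unlist(bad))
  if (length(offenders)) {
    fmt_stop("non-IUPAC nucleotide character(s): %s",
             paste(sQuote(offenders), collapse = ", "))
  }
  invisible(TRUE)
}

#' Count degenerate (ambiguous) bases in sequences
#'
#' Degenerate bases are all IUPAC nucleotide codes other than A/C/G/T
#' (R, Y, S, W, K, M, B, D, H, V, N). RNA input is tolerated: U is
#' normalised to T and does not count as degenerate. Non-IUPAC characters
#' are an error.
#'
#' @param sequence Character vector of nucleotide sequences.
#' @return Integer vector of degenerate-base counts.
#' @export
count_degenerate_bases <- function(sequence) {
  validate_alphabet(sequence)
  s <- normalize_seq(sequence)
  nchar(s) - nchar(gsub("[^ACGT]", "", s))
}

#' Length of the longest homopolymer run
#'
#' @param sequence Character vector of non-empty sequences.
#' @return Integer vector: for each sequence, the length of its longest run
#'   of one identical character.
#' @export
longest_homopolymer <- function(sequence) {
  if (any(!nzchar(sequence))) fmt_stop("sequences must be non-empty")
  vapply(strsplit(toupper(sequence), "", fixed = TRUE), function(ch) {
    max(rle(ch)$lengths)
  }, integer(1L))
}

#' Construct a reference-sequence collection
#'
#' Candidate sequences for a curated taxonomic reference database, each with
#' an id, an IUPAC nucleotide sequence (upper-cased, U normalised to T on
#' ingest) and an optional lineage string.
#'
#' @param id Character vector of identifiers.
#' @param sequence Character vector of sequences.
#' @param taxon Optional character vector of semicolon-separated lineages.
#' @return A `ref_seqs` data frame with columns `id`, `sequence`, `taxon`.
#' @export
ref_seqs <- function(id, sequence, taxon = NA_character_) {
  if (length(id) != length(sequence)) fmt_stop("id and sequence lengths differ")
  if (any(!nzchar(sequence))) fmt_stop("sequences must be non-empty")
  validate_alphabet(sequence)
  out <- data.frame(
    id = as.character(id),
    sequence = normalize_seq(sequence),
    taxon = rep_len(as.character(taxon), length(id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ref_seqs", "data.frame")
  out
}

#' Read reference sequences from FASTA (plus optional lineage TSV)
#'
#' FASTA parsing is delegated to `Biostrings`; ids are the first whitespace
#' token of each header. Lineages, when given, come from a taxonomy TSV in
#' the same dialect as [read_taxonomy()] and are joined by id.
#'
#' @param fasta_path Path to a FASTA file.
#' @param taxonomy_path Optional path to a lineage TSV.
#' @return A [ref_seqs()] collection.
#' @export
read_ref_seqs <- function(fasta_path, taxonomy_path = NULL) {
  if (!file.exists(fasta_path)) fmt_stop("FASTA file not found: %s", fasta_path)
  set <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(set))
  taxon <- rep(NA_character_, length(ids))
  if (!is.null(taxonomy_path)) {
    tax <- read_taxonomy(taxonomy_path)
    taxon <- tax$taxon[match(ids, tax$feature_id)]
  }
  ref_seqs(ids, as.character(set), taxon)
}

#' Cull low-quality reference sequences
#'
#' Rejects sequences with too many degenerate bases or too long a
#' homopolymer run. Defaults reject at >= 5 degenerate bases or a
#' homopolymer of >= 8 bases; a sequence failing both rules has both
#' reasons recorded. Kept and rejected partition the input exactly.
#'
#' @param seqs A [ref_seqs()] collection.
#' @param degenerate_reject_at Reject when the degenerate-base count is at
#'   least this (default 5).
#' @param homopolymer_reject_at Reject when the longest homopolymer is at
#'   least this (default 8).
#' @return List with `kept` (a `ref_seqs`) and `rejected` (data frame: `id`,
#'   `reason` — comma-joined, `degenerate_bases`, `homopolymer`).
#' @export
cull_seqs <- function(seqs, degenerate_reject_at = 5L, homopolymer_reject_at = 8L) {
  stopifnot(inherits(seqs, "ref_seqs"))
  if (!is_count(degenerate_reject_at) || degenerate_reject_at < 1 ||
      !is_count(homopolymer_reject_at) || homopolymer_reject_at < 1) {
    fmt_stop("culling thresholds must be positive integers")
  }
  deg <- count_degenerate_bases(seqs$sequence)
  hp <- longest_homopolymer(seqs$sequence)
  fail_deg <- deg >= degenerate_reject_at
  fail_hp <- hp >= homopolymer_reject_at
  reject <- fail_deg | fail_hp
  reason <- character(nrow(seqs))
  reason[fail_deg] <- "degenerate_bases"
  reason[fail_hp] <- ifelse(fail_deg[fail_hp], "degenerate_bases,homopolymer",
                            "homopolymer")
  kept <- seqs[!reject, , drop = FALSE]
  class(kept) <- c("ref_seqs", "data.frame")
  list(
    kept = kept,
    rejected = data.frame(
      id = seqs$id[reject], reason = reason[reject],
      degenerate_bases = deg[reject], homopolymer = hp[reject],
      row.names = NULL, stringsAsFactors = FALSE
    )
  )
}

# resolve the domain label used by the length filter from a lineage string
domain_label <- function(taxon) {
  vapply(taxon, function(t) {
    if (is.na(t) || !nzchar(t)) {
      return("unknown")
    }
    first <- tolower(strip_rank_prefix(trimws(strsplit(t, ";", fixed = TRUE)[[1L]][[1L]])))
    switch(first,
      archaea = "archaea_16S",
      bacteria = "bacteria_16S",
      eukaryota = "eukaryote_18S",
      eukaryote = "eukaryote_18S",
      "unknown"
    )
  }, character(1L), USE.NAMES = FALSE)
}

#' Domain-conditional length filter
#'
#' Keeps sequences at least as long as their domain's minimum: 16S rRNA of
#' archaea >= 900 bp, bacteria >= 1200 bp, 18S rRNA of eukaryotes
#' >= 1400 bp. Sequences whose domain cannot be resolved from the lineage
#' are kept with a warning (the conservative choice — there is no rule for
#' them).
#'
#' @param seqs A [ref_seqs()] collection with lineages.
#' @param min_length Named integer vector of per-domain minima.
#' @return List with `kept` (a `ref_seqs`) and `rejected` (data frame: `id`,
#'   `domain`, `length`, `min_length`).
#' @export
filter_by_length_and_taxon <- function(seqs,
                                       min_length = c(archaea_16S = 900L,
                                                      bacteria_16S = 1200L,
                                                      eukaryote_18S = 1400L)) {
  stopifnot(inherits(seqs, "ref_seqs"))
  if (any(min_length < 1)) fmt_stop("length minima must be positive")
  dom <- domain_label(seqs$taxon)
  len <- nchar(seqs$sequence)
  minimum <- unname(min_length[dom]) # NA for unknown domains
  keep <- is.na(minimum) | len >= minimum
  n_unknown <- sum(dom == "unknown")
  if (n_unknown) {
    fmt_warn("%d sequence(s) with unresolved domain kept without length check",
             n_unknown)
  }
  kept <- seqs[keep, , drop = FALSE]
  class(kept) <- c("ref_seqs", "data.frame")
  list(
    kept = kept,
    rejected = data.frame(
      id = seqs$id[!keep], domain = dom[!keep], length = len[!keep],
      min_length = minimum[!keep], row.names = NULL, stringsAsFactors = FALSE
    )
  )
}

#' Uniq-mode dereplication
#'
#' Collapses records with identical (sequence, lineage) to their first
#' occurrence, while retaining identical sequences that carry different
#' lineages — the "uniq" dereplication semantics used when building
#' taxonomy-aware reference databases. Output order is first-occurrence
#' order; the operation is idempotent.
#'
#' @param seqs A [ref_seqs()] collection.
#' @return A deduplicated `ref_seqs`.
#' @export
dereplicate_uniq <- function(seqs) {
  stopifnot(inherits(seqs, "ref_seqs"))
  key <- paste(seqs$sequence,
               ifelse(is.na(seqs$taxon), "\x01NA", seqs$taxon), sep = "\r")
  out <- seqs[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ref_seqs", "data.frame")
  out
}

#' Write reference sequences as FASTA
#' @param seqs A [ref_seqs()] collection.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ref_seqs <- function(seqs, path) {
  stopifnot(inherits(seqs, "ref_seqs"))
  set <- Biostrings::BStringSet(seqs$sequence)
  names(set) <- seqs$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
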