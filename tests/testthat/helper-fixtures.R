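# Fixture builders shared across test files. Everything is generated in
# code; no data files.

tiny_table <- function() {
  feature_table(matrix(
    c(10, 0,
      5, 7),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("ASV1", "ASV2"), c("S1", "S2"))
  ))
}

tiny_meta <- function() {
  sample_metadata(data.frame(
    sample_id = c("S1", "S2"),
    subject = "1",
    substrate = c("nukadoko", "skin"),
    day = 0L,
    timepoint = c("0", "0"),
    phase = "contact"
  ))
}

tiny_tax <- function() {
  taxonomy_map(data.frame(
    feature_id = c("ASV1", "ASV2"),
    taxon = c(
      "d__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; f__Lactobacillaceae; g__Loigolactobacillus",
      "d__Bacteria; p__Firmicutes; c__Bacilli; o__Bacillales; f__Staphylococcaceae; g__Staphylococcus"
    )
  ))
}

# metadata for the full study layout: nukadoko days {0,3,6,9,12,14},
# skin timepoints {0, 0', 3, ..., 14, 15, 18, ..., 29}, n subjects
study_meta_fixture <- function(subjects = c("1", "2", "3")) {
  nuka_days <- c(0L, 3L, 6L, 9L, 12L, 14L)
  skin_tps <- c("0", "0'", "3", "6", "9", "12", "14",
                "15", "18", "21", "24", "27", "29")
  skin_days <- as.integer(sub("'", "", skin_tps, fixed = TRUE))
  rows <- lapply(subjects, function(s) {
    rbind(
      data.frame(
        sample_id = sprintf("nuka%s_d%02d", s, nuka_days), subject = s,
        substrate = "nukadoko", day = nuka_days,
        timepoint = as.character(nuka_days),
        phase = ifelse(nuka_days <= 14L, "contact", "no_contact")
      ),
      data.frame(
        sample_id = sprintf("skin%s_t%s", s, sub("'", "p", skin_tps, fixed = TRUE)),
        subject = s, substrate = "skin", day = skin_days, timepoint = skin_tps,
        phase = ifelse(skin_days <= 14L, "contact", "no_contact")
      )
    )
  })
  sample_metadata(do.call(rbind, rows))
}

# random relative-abundance vector over a shared feature universe
random_rel <- function(ids) {
  x <- stats::rgamma(length(ids), shape = 0.5)
  if (sum(x) == 0) x[1] <- 1
  stats::setNames(x / sum(x), ids)
}

# independent brute-force oracle for the shared-ASV definition: a plain
# double scan over features, no vectorised comparison shared with the
# implementation
shared_oracle <- function(source_rel, sink_rel, threshold) {
  out <- character()
  for (f in names(source_rel)) {
    if (source_rel[[f]] > threshold) {
      if (sink_rel[[f]] > threshold) {
        out <- c(out, f)
      }
    }
  }
  out
}

# write a text fixture by hand (bypassing the package writers)
write_lines_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
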