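test_that("find_shared_asvs applies the dual threshold strictly on both sides", {
  ids <- c("A", "B", "C", "D")
  source_rel <- setNames(c(0.70, 0.05, 0.002, 0.248), ids)
  sink_rel <- setNames(c(0.03, 0.005, 0.065, 0.90), ids)
  # B fails the sink side, C fails both; A and D pass both
  expect_setequal(find_shared_asvs(source_rel, sink_rel), c("A", "D"))

  # strict ">": a feature at exactly the threshold is not shared...
  s1 <- setNames(c(0.01, 0.99), c("X", "Y"))
  s2 <- setNames(c(0.50, 0.50), c("X", "Y"))
  expect_identical(find_shared_asvs(s1, s2, threshold = 0.01), "Y")
  # ...unless the comparison is relaxed to ">="
  expect_setequal(find_shared_asvs(s1, s2, threshold = 0.01, comparison = "ge"),
                  c("X", "Y"))

  # threshold 0 reduces to the support intersection
  expect_setequal(find_shared_asvs(source_rel, sink_rel, threshold = 0), ids)
  z1 <- setNames(c(0.5, 0.5, 0), c("A", "B", "C"))
  z2 <- setNames(c(0, 0.4, 0.6), c("A", "B", "C"))
  expect_identical(find_shared_asvs(z1, z2, threshold = 0), "B")

  # identical vectors: everything above the threshold
  expect_setequal(find_shared_asvs(sink_rel, sink_rel), c("A", "C", "D"))

  # mismatched universes are an alignment error
  expect_error(find_shared_asvs(s1, setNames(0.5, "X")), "universe")
})

test_that("shared membership is symmetric but the proportion is sink-weighted", {
  set.seed(11)
  ids <- sprintf("f%02d", 1:40)
  a <- random_rel(ids)
  b <- random_rel(ids)
  expect_setequal(find_shared_asvs(a, b), find_shared_asvs(b, a))
  sh <- find_shared_asvs(a, b)
  if (length(sh)) {
    expect_equal(shared_proportion(b, sh), 100 * sum(b[sh]))
    # weighting by the other sample generally differs
    expect_false(isTRUE(all.equal(shared_proportion(a, sh), shared_proportion(b, sh))))
  }
})

test_that("raising the threshold never enlarges the shared set or proportion", {
  set.seed(23)
  ids <- sprintf("f%02d", 1:60)
  for (i in 1:25) {
    a <- random_rel(ids)
    b <- random_rel(ids)
    prev_set <- find_shared_asvs(a, b, threshold = 0)
    prev_prop <- shared_proportion(b, prev_set)
    for (thr in c(0.005, 0.01, 0.02, 0.05, 0.2)) {
      cur_set <- find_shared_asvs(a, b, threshold = thr)
      expect_true(all(cur_set %in% prev_set))
      cur_prop <- shared_proportion(b, cur_set)
      expect_lte(cur_prop, prev_prop + 1e-12)
      prev_set <- cur_set
      prev_prop <- cur_prop
    }
  }
})

test_that("disjoint supports share nothing at any positive threshold", {
  ids <- sprintf("f%02d", 1:20)
  a <- setNames(c(random_rel(ids[1:10]), numeric(10)), ids)
  b <- setNames(c(numeric(10), random_rel(ids[11:20])), ids)
  for (thr in c(1e-6, 0.01, 0.1)) {
    expect_length(find_shared_asvs(a, b, threshold = thr), 0)
  }
})

test_that("shared_proportion handles edge cases", {
  sink <- setNames(c(0.03, 0.9, 0.07), c("A", "B", "C"))
  expect_equal(shared_proportion(sink, "A"), 3)
  expect_equal(shared_proportion(sink, character()), 0)
  expect_equal(shared_proportion(sink, names(sink)), 100, tolerance = 1e-7)
  expect_error(shared_proportion(sink, "Z"), "absent")
})

test_that("build_pairs reproduces the study layout: 13 pairs per subject", {
  meta <- study_meta_fixture()
  pairs <- build_pairs(meta)
  expect_true(all(pairs$paired))
  for (s in unique(meta$subject)) {
    p <- pairs[pairs$subject == s, ]
    expect_equal(nrow(p), 13L)
    expect_equal(sum(p$phase == "contact"), 7L) # includes both day-0 timepoints
    expect_setequal(p$timepoint[p$phase == "contact"],
                    c("0", "0'", "3", "6", "9", "12", "14"))
    expect_equal(sum(p$phase == "no_contact"), 6L)
    # all no-contact skin samples map to the day-14 source sample
    expect_true(all(p$source_sample_id[p$phase == "no_contact"] ==
                      sprintf("nuka%s_d14", s)))
    # contact pairs match the same subject's same-day source
    contact <- p[p$phase == "contact", ]
    expect_true(all(contact$source_sample_id ==
                      sprintf("nuka%s_d%02d", s, contact$day)))
  }
})

test_that("build_pairs reports unpaired skin samples instead of dropping them", {
  meta <- study_meta_fixture(subjects = "1")
  # remove the day-3 nukadoko sample
  df <- as.data.frame(meta)
  df <- df[df$sample_id != "nuka1_d03", ]
  meta2 <- sample_metadata(df)
  pairs <- build_pairs(meta2)
  unp <- pairs[!pairs$paired, ]
  expect_equal(nrow(unp), 1L)
  expect_equal(unp$timepoint, "3")
  expect_match(unp$reason, "day 3")
  # with a custom no-contact source day that has no sample, all 6 are unpaired
  pairs12 <- build_pairs(meta2, source_day = 13L)
  expect_equal(sum(!pairs12$paired), 7L) # day 3 + the six no-contact samples
})

test_that("shared_timecourse matches direct per-pair module calls", {
  st <- generate_study(simulation_params(master_seed = 5))
  rel <- to_relative(st$table)
  tc <- shared_timecourse(rel, st$meta)
  expect_equal(nrow(tc), 39L)
  sets <- attr(tc, "shared_sets")
  for (i in sample(seq_len(nrow(tc)), 8)) {
    src <- unclass(rel)[, tc$source_sample[i]]
    snk <- unclass(rel)[, tc$sink_sample[i]]
    direct <- find_shared_asvs(src, snk, threshold = 0.01)
    expect_setequal(sets[[tc$sink_sample[i]]], direct)
    expect_equal(tc$shared_proportion_percent[i], shared_proportion(snk, direct))
  }
  # pairing invariant: source and sink always belong to the same subject
  meta_subject <- setNames(st$meta$subject, st$meta$sample_id)
  expect_equal(unname(meta_subject[tc$source_sample]),
               unname(meta_subject[tc$sink_sample]))
})

test_that("persistence_summary returns the last no-contact detection day or none", {
  st <- generate_study(simulation_params(master_seed = 5))
  rel <- to_relative(st$table)
  tc <- shared_timecourse(rel, st$meta)
  per <- persistence_summary(tc)
  for (s in per$subject) {
    nc <- tc[tc$phase == "no_contact" & tc$subject == s, ]
    pos_days <- nc$day[nc$shared_proportion_percent > 0]
    if (length(pos_days)) {
      expect_equal(per$last_detected_day[per$subject == s], max(pos_days))
    } else {
      expect_true(is.na(per$last_detected_day[per$subject == s]))
    }
  }
  # an all-zero no-contact phase yields 'none'
  st0 <- generate_study(simulation_params(master_seed = 5, transfer_fraction = 0))
  tc0 <- shared_timecourse(to_relative(st0$table), st0$meta)
  per0 <- persistence_summary(tc0)
  expect_true(all(!per0$detected))
})

test_that("shared_taxa_breakdown conserves the proportion and buckets unknowns", {
  # hand-built pair: two shared ASVs of one genus plus one unannotated
  counts <- matrix(
    c(300, 30,
      200, 20,
      400, 25,
      5, 925),  # 'other' stays below 1% in the source, so it is not shared
    nrow = 4, byrow = TRUE,
    dimnames = list(c("l1", "l2", "x1", "other"),
                    c("nuka1_d00", "skin1_t0p"))
  )
  meta <- sample_metadata(data.frame(
    sample_id = c("nuka1_d00", "skin1_t0p"), subject = "1",
    substrate = c("nukadoko", "skin"), day = 0L,
    timepoint = c("0", "0'"), phase = "contact"
  ))
  tax <- taxonomy_map(data.frame(
    feature_id = c("l1", "l2", "other"),
    taxon = c(
      "d__Bacteria; p__P; c__C; o__O; f__F; g__Loigolactibacillus",
      "d__Bacteria; p__P; c__C; o__O; f__F; g__Loigolactibacillus",
      "d__Bacteria; p__P; c__C; o__O; f__F; g__Other"
    )
  ))
  rel <- to_relative(feature_table(counts))
  tc <- shared_timecourse(rel, meta)
  bd <- shared_taxa_breakdown(tc, rel, tax)
  expect_setequal(bd$genus, c("Loigolactibacillus", "Unassigned"))
  expect_equal(bd$contribution_percent[bd$genus == "Loigolactibacillus"], 5)
  expect_equal(bd$contribution_percent[bd$genus == "Unassigned"], 2.5)
  expect_equal(sum(bd$contribution_percent),
               tc$shared_proportion_percent[[1L]], tolerance = 1e-9)
})
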