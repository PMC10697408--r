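test_that("feature table round-trips through TSV with exact integer equality", {
  ft <- tiny_table()
  path <- tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_identical(dimnames(back), dimnames(ft))
  expect_identical(unclass(back), unclass(ft))

  # zero-only sample columns survive the round trip, not silently dropped
  ft0 <- feature_table(matrix(c(3, 1, 0, 0), 2,
    dimnames = list(c("A", "B"), c("S1", "Sempty"))))
  write_feature_table(ft0, path)
  back0 <- read_feature_table(path)
  expect_equal(colnames(back0), c("S1", "Sempty"))
  expect_equal(sum(back0[, "Sempty"]), 0)
})

test_that("feature table construction and parsing reject malformed input", {
  m <- matrix(1:4, 2, dimnames = list(c("A", "B"), c("S1", "S2")))
  expect_error(feature_table(m * -1), "negative")
  expect_error(feature_table(m + 0.5), "non-integer")
  expect_error(feature_table(m[, 0, drop = FALSE]), "at least one")

  dup_header <- write_lines_tsv(c(
    "feature_id\tS1\tS1", "A\t1\t2", "B\t3\t4"
  ))
  expect_error(read_feature_table(dup_header), "S1")

  dup_feature <- write_lines_tsv(c(
    "feature_id\tS1", "A\t1", "A\t2"
  ))
  expect_error(read_feature_table(dup_feature), "A")

  non_numeric <- write_lines_tsv(c(
    "feature_id\tS1", "A\tx"
  ))
  expect_error(read_feature_table(non_numeric), "non-numeric")

  empty <- write_lines_tsv("feature_id\tS1")
  expect_error(read_feature_table(empty), "empty")

  tabbed <- feature_table(matrix(1, 1, dimnames = list("A", "S1")))
  rownames(tabbed) <- "A\tB"
  expect_error(write_feature_table(tabbed, tempfile()), "tab")
})

test_that("biom_tsv dialect skips the comment line and accepts '#OTU ID'", {
  path <- write_lines_tsv(c(
    "# Constructed from biom file",
    "#OTU ID\tS1\tS2",
    "ASV1\t10\t0",
    "ASV2\t5\t7"
  ))
  ft <- read_feature_table(path, dialect = "biom_tsv")
  # hand-parsed expectation
  expect_identical(rownames(ft), c("ASV1", "ASV2"))
  expect_identical(colnames(ft), c("S1", "S2"))
  expect_equal(as.numeric(ft), c(10, 5, 0, 7))
  # plain dialect refuses the biom header rather than guessing
  expect_error(read_feature_table(path, dialect = "plain"), "feature_id")
})

test_that("metadata reader enforces vocabulary, uniqueness and day/phase convention", {
  hdr <- "sample-id\tsubject\tsubstrate\tday\ttimepoint\tphase"
  ok <- read_metadata(write_lines_tsv(c(
    hdr,
    "skin1\t1\tskin\t0\t0'\tcontact",
    "nuka1\t1\tnukadoko\t0\t0\tcontact"
  )))
  expect_s3_class(ok, "sample_metadata")
  expect_equal(ok$timepoint[ok$sample_id == "skin1"], "0'")

  expect_error(read_metadata(write_lines_tsv(c(
    hdr, "s1\t1\tsoil\t0\t0\tcontact"
  ))), "soil")

  expect_error(read_metadata(write_lines_tsv(c(
    hdr,
    "s1\t1\tskin\t3\t3\tcontact",
    "s2\t1\tskin\t3\t3\tcontact"
  ))), "duplicate")

  expect_error(read_metadata(write_lines_tsv(c(
    hdr, "s1\t1\tskin\t20\t20\tcontact"
  ))), "phase")
})

test_that("taxonomy reader parses lineages, genus names and optional confidence", {
  path <- write_lines_tsv(c(
    "Feature ID\tTaxon\tConfidence",
    "ASV1\td__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; f__Lactobacillaceae; g__Loigolactobacillus\t0.99",
    "ASV2\tUnassigned\t",
    "ASV3\td__Bacteria; p__Proteobacteria; c__Alphaproteobacteria; o__Rhizobiales; f__Rhizobiaceae\t0.80"
  ))
  tax <- read_taxonomy(path)
  expect_equal(feature_genus(tax, "ASV1"), "Loigolactobacillus")
  lin <- taxonomy_lineages(tax)
  expect_length(lin[["ASV2"]], 1L)
  expect_equal(lin[["ASV2"]], "Unassigned")
  expect_true(is.na(tax$confidence[tax$feature_id == "ASV2"]))
  expect_equal(tax$confidence[tax$feature_id == "ASV1"], 0.99)
  # resolved only to family
  expect_equal(feature_genus(tax, "ASV3"), "Unclassified_Rhizobiaceae")
  # absent feature
  expect_equal(feature_genus(tax, "ASV999"), "Unassigned")

  no_taxon <- write_lines_tsv(c("Feature ID\tLineage", "A\tx"))
  expect_error(read_taxonomy(no_taxon), "Taxon")
})

test_that("align_dataset intersects samples, errors on gaps, and is idempotent", {
  ft <- tiny_table()
  meta3 <- sample_metadata(rbind(
    as.data.frame(tiny_meta()),
    data.frame(sample_id = "S3", subject = "2", substrate = "skin",
               day = 0L, timepoint = "0", phase = "contact")
  ))
  expect_warning(ds <- align_dataset(ft, meta3, tiny_tax()), "S3")
  expect_setequal(colnames(ds$table), c("S1", "S2"))

  # table sample not described by metadata is an error naming it
  ft4 <- feature_table(matrix(1:4, 2,
    dimnames = list(c("ASV1", "ASV2"), c("S1", "S4"))))
  expect_error(align_dataset(ft4, tiny_meta(), tiny_tax()), "S4")

  # undescribed features are flagged, not dropped
  ftx <- feature_table(matrix(1:6, 3,
    dimnames = list(c("ASV1", "ASV2", "ASVx"), c("S1", "S2"))))
  dsx <- align_dataset(ftx, tiny_meta(), tiny_tax())
  expect_equal(dsx$unassigned_features, "ASVx")
  expect_true("ASVx" %in% rownames(dsx$table))

  ds1 <- align_dataset(ft, tiny_meta(), tiny_tax())
  ds2 <- align_dataset(ds1$table, ds1$meta, ds1$tax)
  expect_identical(unclass(ds1$table), unclass(ds2$table))
  expect_identical(as.data.frame(ds1$meta), as.data.frame(ds2$meta))
})

test_that("to_relative normalises columns, preserves zeros, handles empties", {
  ft <- feature_table(matrix(c(10, 30, 0, 42), 2,
    dimnames = list(c("A", "B"), c("S1", "S2"))))
  rel <- to_relative(ft)
  expect_equal(as.numeric(rel[, "S1"]), c(0.25, 0.75))
  expect_equal(as.numeric(rel[, "S2"]), c(0, 1))
  expect_equal(unname(colSums(rel)), c(1, 1), tolerance = 1e-12)
  # zero pattern preserved exactly
  expect_identical(unclass(rel) == 0, unclass(ft) == 0)

  ft0 <- feature_table(matrix(c(1, 2, 0, 0), 2,
    dimnames = list(c("A", "B"), c("S1", "Sempty"))))
  expect_error(to_relative(ft0), "Sempty")
  expect_message(rel0 <- to_relative(ft0, drop_empty = TRUE), "Sempty")
  expect_equal(colnames(rel0), "S1")
})
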