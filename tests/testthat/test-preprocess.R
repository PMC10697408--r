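organelle_fixture <- function() {
  counts <- matrix(
    c(50, 40,
      10, 0,
      5, 5,
      20, 30,
      1, 2),
    nrow = 5, byrow = TRUE,
    dimnames = list(c("keep1", "chloro", "mito", "keep2", "norec"),
                    c("S1", "S2"))
  )
  tax <- taxonomy_map(data.frame(
    feature_id = c("keep1", "chloro", "mito", "keep2", "unass"),
    taxon = c(
      "d__Bacteria; p__Firmicutes; c__Bacilli; o__Bacillales; f__Staphylococcaceae; g__Staphylococcus",
      "d__Bacteria; p__Cyanobacteria; c__Cyanobacteriia; o__Chloroplast",
      "d__Bacteria; p__Proteobacteria; c__Alphaproteobacteria; o__Rickettsiales; f__Mitochondria",
      "d__Bacteria; p__Proteobacteria",
      "Unassigned"
    )
  ))
  list(table = feature_table(counts), tax = tax)
}

test_that("organelle/unassigned filter applies rules with first-match reasons", {
  fx <- organelle_fixture()
  res <- filter_organelle_unassigned(fx$table, fx$tax)
  expect_setequal(rownames(res$table), c("keep1", "keep2"))
  reasons <- setNames(res$report$removed$reason, res$report$removed$feature_id)
  expect_equal(reasons[["chloro"]], "chloroplast")
  expect_equal(reasons[["mito"]], "mitochondria")
  expect_equal(reasons[["norec"]], "unassigned") # no taxonomy record
  # domain-only lineage is retained: unplaced, not poorly resolved
  expect_true("keep2" %in% rownames(res$table))
})

test_that("single-label Unassigned lineages are removed; min_ranks opts into stricter culling", {
  tax <- taxonomy_map(data.frame(
    feature_id = c("u", "dom"),
    taxon = c("Unassigned", "d__Bacteria")
  ))
  tab <- feature_table(matrix(c(5, 6), 2, 1, dimnames = list(c("u", "dom"), "S1")))
  res <- filter_organelle_unassigned(tab, tax)
  expect_equal(res$report$removed$feature_id, "u")
  expect_equal(rownames(res$table), "dom")

  expect_warning(
    strict <- filter_organelle_unassigned(tab, tax, min_ranks = 2L),
    "every feature"
  )
  expect_null(strict$table) # both lineages fall below the rank requirement
  expect_setequal(strict$report$removed$feature_id, c("u", "dom"))
})

test_that("filter accounting balances exactly and retained counts are untouched", {
  fx <- organelle_fixture()
  totals <- colSums(fx$table)
  res <- filter_organelle_unassigned(fx$table, fx$tax)
  expect_equal(res$report$reads_removed + res$report$reads_retained, totals)
  expect_identical(
    unclass(res$table)["keep1", ],
    unclass(fx$table)["keep1", ]
  )
  # re-running the filter on the filtered table is a no-op
  res2 <- filter_organelle_unassigned(res$table, fx$tax)
  expect_identical(unclass(res2$table), unclass(res$table))
  expect_equal(nrow(res2$report$removed), 0L)
})

test_that("collapse_genus aggregates additively and preserves column mass", {
  counts <- matrix(
    c(40, 10,
      30, 20,
      20, 30,
      10, 40),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("a1", "a2", "b1", "c1"), c("S1", "S2"))
  )
  tax <- taxonomy_map(data.frame(
    feature_id = c("a1", "a2", "b1", "c1"),
    taxon = c(
      "d__Bacteria; p__P; c__C; o__O; f__F; g__Loigolactobacillus",
      "d__Bacteria; p__P; c__C; o__O; f__F; g__Loigolactobacillus",
      "d__Bacteria; p__Proteobacteria; c__Alphaproteobacteria; o__Rhizobiales; f__Rhizobiaceae",
      "d__Bacteria; p__P; c__C; o__O; f__F; g__Pantoea"
    )
  ))
  rel <- to_relative(feature_table(counts))
  g <- collapse_genus(rel, tax)
  expect_equal(g["Loigolactobacillus", "S1"], 0.7)
  expect_equal(g["Unclassified_Rhizobiaceae", "S2"], 0.3)
  expect_equal(unname(colSums(g)), c(1, 1), tolerance = 1e-9)
})

test_that("top_n_summary ranks by mean abundance with a remainder row", {
  mat <- matrix(
    c(0.5, 0.6,
      0.3, 0.2,
      0.2, 0.2),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("GenA", "GenB", "GenC"), c("S1", "S2"))
  )
  rel <- nukasv:::rel_abundance_table(mat)
  top2 <- top_n_summary(rel, n = 2L)
  expect_equal(rownames(top2), c("GenA", "GenB", "remainder"))
  expect_equal(unname(top2["remainder", ]), unname(mat["GenC", ]))
  expect_equal(unname(colSums(top2)), c(1, 1), tolerance = 1e-9)

  # degenerate n: all genera named, remainder all zeros
  top9 <- top_n_summary(rel, n = 9L)
  expect_equal(nrow(top9), 4L)
  expect_equal(unname(top9["remainder", ]), c(0, 0))
})

test_that("top-N selection matches a brute-force sort oracle on random tables", {
  set.seed(42)
  for (rep in 1:20) {
    n_gen <- sample(3:25, 1)
    n_smp <- sample(2:6, 1)
    mat <- matrix(rgamma(n_gen * n_smp, 1), n_gen,
                  dimnames = list(sprintf("G%02d", sample(n_gen)),
                                  sprintf("S%d", seq_len(n_smp))))
    mat <- sweep(mat, 2, colSums(mat), "/")
    rel <- nukasv:::rel_abundance_table(mat)
    n <- sample(1:n_gen, 1)
    got <- top_n_summary(rel, n = n)
    # oracle: independent sort of the row means, lexicographic tie-break
    means <- sort(rowMeans(mat), decreasing = TRUE)
    expected_top <- names(means)[order(-means, names(means))][seq_len(min(n, n_gen))]
    expect_identical(setdiff(rownames(got), "remainder"), expected_top)
    expect_equal(unname(colSums(got)), rep(1, n_smp), tolerance = 1e-9)
  }
})
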