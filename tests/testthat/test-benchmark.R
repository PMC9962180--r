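test_that("the benchmark recovers planted miRNA-term associations in indirect mode", {
  b <- fixtureBundle()
  rec <- runBenchmark(b$gold, b$table, b$network, b$annotations,
                      mode = "indirect", topFraction = 1)
  expect_setequal(rec$mirna, unique(b$gold$mirna))
  expect_true(all(rec$percentile <= 0.05))
  expect_true(all(rec$best_term %in% b$gold$term_id))
  expect_length(attr(rec, "skipped"), 0L)
})

test_that("miRNAs whose known terms were filtered out are skipped and logged", {
  b <- fixtureBundle()
  pairs <- rbind(b$gold[, c("mirna", "term_id")],
                 data.frame(mirna = "hsa-miR-ghost-5p",
                            term_id = "GO:9999999"))
  rec <- suppressWarnings(
    runBenchmark(pairs, b$table, b$network, b$annotations,
                 mode = "indirect"))
  expect_equal(attr(rec, "skipped"), "hsa-miR-ghost-5p")
  expect_false("hsa-miR-ghost-5p" %in% rec$mirna)

  ghostOnly <- data.frame(mirna = "hsa-miR-ghost-5p", term_id = "GO:9999999")
  expect_error(
    suppressWarnings(runBenchmark(ghostOnly, b$table, b$network,
                                  b$annotations)),
    class = "mirtf_data_error")
})

test_that("benchmark runs are deterministic for fixed inputs", {
  b <- fixtureBundle()
  r1 <- runBenchmark(b$gold, b$table, b$network, b$annotations,
                     mode = "indirect")
  r2 <- runBenchmark(b$gold, b$table, b$network, b$annotations,
                     mode = "indirect")
  expect_identical(r1, r2)
})

test_that("percentiles are invariant to annotation row order", {
  b <- fixtureBundle()
  ann1 <- b$annotations
  raw <- utils::read.delim(b$fx$paths$annotations, check.names = FALSE)
  set.seed(8)
  shuffled <- raw[sample(nrow(raw)), ]
  path <- tempfile(fileext = ".tsv")
  utils::write.table(shuffled, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ann2 <- loadAnnotationsBiomart(path)
  r1 <- runBenchmark(b$gold, b$table, b$network, ann1, mode = "indirect")
  r2 <- runBenchmark(b$gold, b$table, b$network, ann2, mode = "indirect")
  expect_equal(r1$percentile, r2$percentile)
})

mkRecords <- function(mirnas, percentiles, mode) {
  data.frame(mirna = mirnas, mode = mode, top_fraction = 1,
             best_term = "GO:0000001", rank = 1L,
             percentile = percentiles, n_terms_tested = 100L)
}

test_that("the paired comparison behaves at its boundaries", {
  mirs <- sprintf("m%02d", 1:20)
  d <- mkRecords(mirs, seq(0.3, 0.8, length.out = 20), "direct")
  i <- mkRecords(mirs, seq(0.3, 0.8, length.out = 20) - 0.2, "indirect")
  got <- pairedComparison(d, i)
  expect_lt(got$p_value, 0.001)
  expect_equal(got$n_pairs, 20L)
  expect_equal(got$statistic, 0)  # no positive differences at all

  expect_error(pairedComparison(d, mkRecords(mirs, d$percentile, "indirect")),
               class = "mirtf_data_error")
  expect_error(pairedComparison(d, i[1:10, ]), class = "mirtf_usage_error")
})

test_that("the signed-rank statistic ranks positive differences by absolute value", {
  d <- mkRecords(c("a", "b", "c"), c(0.5, 0.5, 0.5), "direct")
  i <- mkRecords(c("a", "b", "c"), c(0.5, 0.5, 0.5) + c(-0.3, -0.2, 0.1),
                 "indirect")
  got <- pairedComparison(d, i)
  # |diffs| = 0.1 < 0.2 < 0.3; the sole positive difference has rank 1
  expect_equal(got$statistic, 1)
})

test_that("the signed-rank p-value matches exact sign-flip enumeration", {
  set.seed(17)
  for (rep in 1:6) {
    n <- sample(5:10, 1)
    diffs <- sample(seq_len(30), n) / 30 * sample(c(-1, 1), n, replace = TRUE)
    mirs <- sprintf("m%02d", seq_len(n))
    d <- mkRecords(mirs, rep(0.5, n), "direct")
    i <- mkRecords(mirs, 0.5 + diffs, "indirect")
    got <- pairedComparison(d, i)$p_value
    expect_equal(got, exactSignedRankLessP(diffs), tolerance = 1e-6,
                 info = paste("n =", n))
  }
})

test_that("the fraction sweep summarises every mode-by-fraction cell", {
  b <- fixtureBundle()
  single <- fractionSweep(b$gold, b$table, b$network, b$annotations,
                          fractions = 1)
  expect_equal(nrow(single$summary), 2L)

  sweep <- fractionSweep(b$gold, b$table, b$network, b$annotations)
  expect_equal(nrow(sweep$summary), 10L)
  expect_setequal(unique(sweep$summary$mode), c("direct", "indirect"))
  expect_true(all(is.finite(sweep$summary$se)))
  # SE definition: sd / sqrt(n)
  cell <- sweep$records[["indirect@0.4"]]
  expect_equal(sweep$summary$se[sweep$summary$mode == "indirect" &
                                  sweep$summary$top_fraction == 0.4],
               stats::sd(cell$percentile) / sqrt(nrow(cell)))

  expect_error(fractionSweep(b$gold, b$table, b$network, b$annotations,
                             fractions = c(0.5, 1.5)),
               class = "mirtf_usage_error")
})
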