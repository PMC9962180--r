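mkTerm <- function(id, name, genes) {
  new("GoTerm", termId = id, name = name,
      namespace = "biological_process", genes = genes)
}

test_that("TF density is the TF share of the term's gene set", {
  tfs <- sprintf("TF%d", 1:10)
  allTf <- mkTerm("GO:0000001", "endodermal cell fate specification",
                  tfs[1:5])
  row <- tfDensity(allTf, tfs)
  expect_equal(row$density, 1)
  expect_equal(row$n_tf, 5L)
  expect_true(row$is_development)

  noTf <- mkTerm("GO:0000002", "lipid catabolic process",
                 sprintf("G%d", 1:10))
  expect_equal(tfDensity(noTf, tfs)$density, 0)

  some <- mkTerm("GO:0000003", "some process",
                 c(tfs[1:2], sprintf("G%d", 1:6)))
  expect_equal(tfDensity(some, tfs)$density, 0.25)

  # scale-free: duplicating membership across TF and gene lists in
  # parallel leaves the ratio unchanged
  doubled <- mkTerm("GO:0000004", "some process",
                    c(tfs[1:4], sprintf("G%d", 1:12)))
  expect_equal(tfDensity(doubled, tfs)$density,
               tfDensity(some, tfs)$density)

  expect_error(tfDensity(mkTerm("GO:0000005", "empty", character()), tfs),
               class = "mirtf_usage_error")
})

test_that("development classification is a case-insensitive substring match", {
  expect_true(classifyDevelopment("brain development"))
  expect_true(classifyDevelopment("cardiac ventricle formation"))
  expect_true(classifyDevelopment("Noradrenergic Neuron DIFFERENTIATION"))
  expect_false(classifyDevelopment("lipid catabolic process"))
  # vectorised
  expect_equal(classifyDevelopment(c("stem cell division", "glycolysis")),
               c(TRUE, FALSE))
  # keyword order is irrelevant
  kw <- c("formation", "development")
  expect_equal(classifyDevelopment("bone formation", kw),
               classifyDevelopment("bone formation", rev(kw)))
  expect_error(classifyDevelopment("x", character()),
               class = "mirtf_usage_error")
})

densityRows <- function(devDens, othDens) {
  data.frame(
    term_id = sprintf("GO:%07d", seq_len(length(devDens) + length(othDens))),
    term_name = "x",
    n_tf = 1L,
    n_genes = 10L,
    density = c(devDens, othDens),
    is_development = rep(c(TRUE, FALSE), c(length(devDens), length(othDens))))
}

test_that("density group comparison reports the development-group rank sum", {
  got <- compareDensityGroups(densityRows(c(1, 2, 3) / 10, c(4, 5, 6) / 10))
  expect_equal(got$statistic, 6)
  expect_equal(got$n_development, 3L)
  expect_equal(got$n_other, 3L)
})

test_that("complete separation gives a near-zero one-sided p-value", {
  got <- compareDensityGroups(densityRows(rep(1, 12), rep(0.1, 12)))
  expect_lt(got$p_value, 1e-3)
  # terms without any TF are excluded from the comparison
  rows <- densityRows(rep(1, 12), rep(0.1, 12))
  rows$n_tf[1] <- 0L
  expect_equal(compareDensityGroups(rows)$n_development, 11L)
  # an empty group is an error
  expect_error(compareDensityGroups(densityRows(numeric(), rep(0.1, 5))),
               class = "mirtf_data_error")
})

test_that("the comparison is calibrated under permuted labels", {
  set.seed(99)
  dens <- stats::runif(24)  # tie-free
  ps <- vapply(1:200, function(i) {
    lab <- sample(rep(c(TRUE, FALSE), 12))
    rows <- densityRows(dens[lab], dens[!lab])
    compareDensityGroups(rows)$p_value
  }, numeric(1))
  expect_gte(stats::median(ps), 0.3)
  expect_lte(stats::median(ps), 0.7)
})

test_that("the rank-sum p-value matches exact permutation enumeration", {
  set.seed(3)
  for (rep in 1:6) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    vals <- sample(seq_len(20), n1 + n2)  # distinct -> tie-free
    x <- vals[seq_len(n1)] / 20; y <- vals[-seq_len(n1)] / 20
    got <- compareDensityGroups(densityRows(x, y))$p_value
    expect_equal(got, exactRankSumGreaterP(x, y), tolerance = 1e-6)
  }
  # with ties the tie-corrected normal approximation stays close
  xt <- c(0.2, 0.4, 0.4, 0.9, 1, 1); yt <- c(0.1, 0.2, 0.4, 0.5, 0.6)
  got <- compareDensityGroups(densityRows(xt, yt))$p_value
  expect_lt(abs(got - exactRankSumGreaterP(xt, yt)), 0.02)
})

test_that("tfDensityTable covers every term and flags development names", {
  b <- fixtureBundle()
  rows <- tfDensityTable(b$annotations, tfUniverse(b$network))
  expect_equal(nrow(rows), length(termIds(b$annotations)))
  expect_true(all(rows$n_tf <= rows$n_genes))
  expect_equal(rows$density, rows$n_tf / rows$n_genes)
})
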