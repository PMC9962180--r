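toyTable <- function() {
  # 10 targets with distinct scores; the sort-and-slice oracle is explicit
  TargetTable(mirna = rep("hsa-miR-t-5p", 10),
              gene = sprintf("G%02d", 1:10),
              score = seq(-0.55, -0.145, length.out = 10))
}

test_that("direct targets are the top fraction of the score-sorted list", {
  tab <- toyTable()
  d4 <- directTargets("hsa-miR-t-5p", tab, 0.4)
  # oracle: sort ascending by score, take ceil(0.4 * 10) = 4
  rec <- targetRecords(tab)
  expected <- rec$gene[order(rec$score)][1:4]
  expect_setequal(targetGenes(d4), expected)
  expect_equal(targetingMode(d4), "direct")

  dAll <- directTargets("hsa-miR-t-5p", tab, 1)
  expect_setequal(targetGenes(dAll), rec$gene)

  expect_warning(dNone <- directTargets("absent-miR", tab, 1),
                 "no records")
  expect_length(targetGenes(dNone), 0L)

  expect_error(directTargets("hsa-miR-t-5p", tab, 0),
               class = "mirtf_usage_error")
  expect_error(directTargets("hsa-miR-t-5p", tab, 1.2),
               class = "mirtf_usage_error")
})

test_that("direct target sets nest monotonically in the top fraction", {
  tab <- toyTable()
  fractions <- c(0.1, 0.25, 0.4, 0.5, 0.75, 0.9, 1)
  sets <- lapply(fractions, function(f)
    targetGenes(directTargets("hsa-miR-t-5p", tab, f)))
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  # ceil() semantics: any positive fraction keeps at least one gene
  expect_gte(length(sets[[1]]), 1L)
})

test_that("score ties at the fraction boundary break by gene symbol", {
  tab <- TargetTable(mirna = rep("m", 4), gene = c("ZZ", "AA", "MM", "BB"),
                     score = rep(-0.3, 4))
  d <- directTargets("m", tab, 0.5)
  expect_equal(sort(targetGenes(d)), c("AA", "BB"))
})

test_that("indirect expansion composes one TF layer over the direct set", {
  tab <- TargetTable(mirna = "m", gene = "TF1", score = -0.3)
  net <- TissueNetwork("brain", tf = c("TF1", "TF1", "TF2"),
                       gene = c("g1", "g2", "g3"))
  ind <- indirectTargets("m", tab, net)
  expect_setequal(targetGenes(ind), c("TF1", "G1", "G2"))
  expect_equal(targetingMode(ind), "indirect")
  expect_equal(tissueLabel(ind), "brain")

  # downstream-only variant excludes the direct targets
  only <- indirectTargets("m", tab, net, includeDirect = FALSE)
  expect_setequal(targetGenes(only), c("G1", "G2"))

  # no directly-targeted TF: indirect equals direct
  tab2 <- TargetTable(mirna = "m", gene = "NOTATF", score = -0.3)
  ind2 <- indirectTargets("m", tab2, net)
  expect_setequal(targetGenes(ind2),
                  targetGenes(directTargets("m", tab2)))
})

test_that("direct targets are always a subset of indirect targets", {
  b <- fixtureBundle()
  for (mir in unique(b$gold$mirna)) {
    for (f in c(0.3, 1)) {
      d <- targetGenes(directTargets(mir, b$table, f))
      i <- targetGenes(indirectTargets(mir, b$table, b$network, f))
      expect_true(all(d %in% i))
    }
  }
})

test_that("target-set intersection is a subset of every input and order-invariant", {
  mk <- function(genes, mir) new("TargetSet", mirnas = mir, mode = "direct",
                                 tissue = character(), topFraction = 1,
                                 genes = genes)
  s1 <- mk(c("A", "B", "C"), "m1"); s2 <- mk(c("B", "C", "D"), "m2")
  got <- intersectTargetSets(list(s1, s2))
  expect_setequal(targetGenes(got), c("B", "C"))
  expect_setequal(mirnas(got), c("m1", "m2"))

  expect_equal(targetGenes(intersectTargetSets(list(s1))),
               targetGenes(s1))

  s3 <- mk(c("C", "E"), "m3")
  triple <- intersectTargetSets(list(s1, s2, s3))
  expect_equal(targetGenes(triple), "C")
  reversed <- intersectTargetSets(list(s3, s2, s1))
  expect_equal(targetGenes(reversed), targetGenes(triple))
  for (s in list(s1, s2, s3))
    expect_true(all(targetGenes(triple) %in% targetGenes(s)))

  # union variant is offered but distinct
  expect_setequal(targetGenes(intersectTargetSets(list(s1, s2),
                                                  combine = "union")),
                  c("A", "B", "C", "D"))

  other <- new("TargetSet", mirnas = "m4", mode = "indirect",
               tissue = "brain", topFraction = 1, genes = "A")
  expect_error(intersectTargetSets(list(s1, other)),
               class = "mirtf_usage_error")
})

test_that("term coverage matches the nine-gene toy scenario", {
  toy <- fig1Toy()
  d <- directTargets(toy$mirna, toy$table)
  i <- indirectTargets(toy$mirna, toy$table, toy$network)
  expect_equal(termCoverage(d, toy$term), 1 / 9)
  expect_equal(termCoverage(i, toy$term), 6 / 9)

  disjoint <- new("TargetSet", mirnas = "m", mode = "direct",
                  tissue = character(), topFraction = 1,
                  genes = c("X1", "X2"))
  expect_equal(termCoverage(disjoint, toy$term), 0)

  emptyTerm <- new("GoTerm", termId = "GO:0000009", name = "empty",
                   namespace = "biological_process", genes = character())
  expect_error(termCoverage(d, emptyTerm), class = "mirtf_usage_error")
})
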