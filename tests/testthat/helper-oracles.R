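## Independent oracles, kept deliberately naive: subset enumeration for
## the hypergeometric tail, and full enumeration of sign assignments /
## group assignments for the Wilcoxon tests.

# P(X >= k) by enumerating every size-n subset of an N-element universe
# whose first K elements are marked.
bruteUpperTail <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  marked <- colSums(subsets <= K)
  mean(marked >= k)
}

# One-sided exact signed-rank p-value P(V <= v_obs) by enumerating all
# 2^n sign assignments (diffs must be non-zero with tie-free |diffs|).
exactSignedRankLessP <- function(diffs) {
  r <- rank(abs(diffs))
  obs <- sum(r[diffs > 0])
  n <- length(diffs)
  vals <- vapply(seq_len(2^n) - 1L, function(mask) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0
    sum(r[signs])
  }, numeric(1))
  mean(vals <= obs)
}

# One-sided exact rank-sum p-value P(W1 >= obs) for "first group
# greater", enumerating all group assignments (tie-free values).
exactRankSumGreaterP <- function(x, y) {
  all <- c(x, y)
  r <- rank(all)
  obs <- sum(r[seq_along(x)])
  combos <- utils::combn(length(all), length(x))
  vals <- colSums(matrix(r[combos], nrow = length(x)))
  mean(vals >= obs)
}

# Write a data.frame as the TSV dialect the loaders read.
writeTsvFixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# TargetScan-style target TSV from plain vectors.
writeTargetTsv <- function(mirna, gene, score,
                           path = tempfile(fileext = ".tsv")) {
  df <- data.frame(mirna, gene, score, check.names = FALSE)
  names(df) <- c("miRNA", "Gene Symbol",
                 "Cumulative weighted context++ score")
  writeTsvFixture(df, path)
}

# Biomart-style annotation TSV from a gene/term long frame.
writeAnnotationTsv <- function(gene, term_id, term_name,
                               namespace = "biological_process",
                               path = tempfile(fileext = ".tsv")) {
  df <- data.frame(gene, term_id, term_name, namespace,
                   check.names = FALSE)
  names(df) <- c("Gene name", "GO term accession", "GO term name",
                 "GO domain")
  writeTsvFixture(df, path)
}

# Minimal valid 17-column GAF 2.2 data line.
gafLine <- function(objectId, goId, reference = "PMID:1", evidence = "IDA") {
  paste(c("RNAcentral", objectId, objectId, "involved_in", goId,
          reference, evidence, "", "P", "desc", "", "miRNA",
          "taxon:9606", "20190101", "BHF-UCL", "", ""),
        collapse = "\t")
}

# Shared generated fixture bundle, built once per test run.
fixtureBundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "mirtf-fixture")
      fx <- generateFixture(defaultFixtureSpec(), dir)
      cache <<- list(
        fx = fx,
        table = loadTargetTable(fx$paths$targets),
        network = loadTissueNetworks(fx$paths$network)[[fx$tissue]],
        annotations = loadAnnotationsBiomart(fx$paths$annotations),
        gold = loadGoldStandardTsv(fx$paths$gold_standard))
    }
    cache
  }
})
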