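## Deterministic synthetic inputs: a coherent toy target table, tissue
## network, annotation set and gold standard with a planted
## indirect-enrichment signal, so the whole pipeline is exercisable
## without any external download.

#' Specification for the synthetic fixture generator
#'
#' Describes a coherent synthetic data bundle. For each planted tuple,
#' the miRNA directly targets \code{n_tf_bridges} transcription factors
#' (with the strongest scores in the table, so the bridges survive
#' top-fraction slicing — the planted signal is about the TF layer, not
#' about score ordering) and each bridge TF regulates
#' \code{downstream_per_tf} genes of the planted GO term. The planted
#' term contains only non-TF genes, and every miRNA's remaining direct
#' targets are sampled from non-TF genes outside all planted terms, so
#' the direct-mode signal for planted terms is null by construction.
#'
#' @param seed integer RNG seed; fixed seed implies byte-identical
#'   output files.
#' @param n_genes number of non-TF genes in the synthetic genome.
#' @param n_tfs number of transcription factors.
#' @param n_terms number of GO terms.
#' @param term_size_range integer (min, max) term size.
#' @param n_mirnas number of miRNAs (planted tuples are created for the
#'   first \code{length(planted_terms)} of them).
#' @param targets_per_mirna direct targets per miRNA.
#' @param score_range (low, high) context++ score range, both negative
#'   and below -0.1 so every record passes the default filter.
#' @param n_planted how many miRNAs get a planted indirect signal.
#' @param n_tf_bridges bridge TFs per planted miRNA.
#' @param downstream_per_tf planted-term genes regulated by each bridge.
#' @param background_edge_prob probability of a random TF-gene edge.
#' @param tissue tissue label of the generated network.
#' @return A validated list of class \code{fixture_spec}.
#' @export
fixtureSpec <- function(seed = 1234L, n_genes = 360L, n_tfs = 40L,
                        n_terms = 40L, term_size_range = c(8L, 20L),
                        n_mirnas = 6L, targets_per_mirna = 30L,
                        score_range = c(-0.6, -0.15), n_planted = 6L,
                        n_tf_bridges = 3L, downstream_per_tf = 6L,
                        background_edge_prob = 0.02, tissue = "brain") {
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               n_tfs = as.integer(n_tfs), n_terms = as.integer(n_terms),
               term_size_range = as.integer(term_size_range),
               n_mirnas = as.integer(n_mirnas),
               targets_per_mirna = as.integer(targets_per_mirna),
               score_range = as.numeric(score_range),
               n_planted = as.integer(n_planted),
               n_tf_bridges = as.integer(n_tf_bridges),
               downstream_per_tf = as.integer(downstream_per_tf),
               background_edge_prob = as.numeric(background_edge_prob),
               tissue = as.character(tissue))
  if (spec$n_tfs >= spec$n_genes)
    stopUsage("fixture spec infeasible: need n_tfs < n_genes")
  if (spec$term_size_range[1] < 5L)
    stopUsage("fixture spec infeasible: term sizes must be >= 5")
  if (spec$downstream_per_tf > spec$term_size_range[1])
    stopUsage("fixture spec infeasible: downstream_per_tf (%d) exceeds the minimum planted term size (%d)",
              spec$downstream_per_tf, spec$term_size_range[1])
  if (spec$n_planted > spec$n_mirnas || spec$n_planted > spec$n_terms)
    stopUsage("fixture spec infeasible: n_planted exceeds n_mirnas or n_terms")
  if (spec$n_planted * spec$n_tf_bridges > spec$n_tfs)
    stopUsage("fixture spec infeasible: not enough TFs for disjoint bridges")
  if (any(spec$score_range >= -0.1))
    stopUsage("fixture spec infeasible: score_range must lie below -0.1")
  if (spec$targets_per_mirna < spec$n_tf_bridges)
    stopUsage("fixture spec infeasible: targets_per_mirna < n_tf_bridges")
  class(spec) <- "fixture_spec"
  spec
}

#' The packaged default fixture specification
#'
#' @return The \code{\link{fixtureSpec}} used by the test-bench runs:
#'   360 genes + 40 TFs, 40 terms of 8-20 genes, 6 miRNAs each planted
#'   into a distinct term through 3 bridge TFs regulating 6 term genes
#'   each, 2\% background edge density, one "brain" network.
#' @export
defaultFixtureSpec <- function() fixtureSpec()

withFixtureRng <- function(seed, code) {
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

#' Generate the synthetic fixture files
#'
#' Writes four TSVs into \code{outDir} — \code{targets.tsv}
#' (TargetScan-style), \code{network.tsv} (long TF/gene/tissue),
#' \code{annotations.tsv} (Biomart-style) and \code{gold_standard.tsv}
#' (miRNA/term pairs, the planted associations) — plus
#' \code{manifest.tsv} listing each file with its MD5 checksum. All
#' randomness flows from one seeded Mersenne-Twister stream, so the
#' same spec always produces byte-identical files. Planted downstream
#' genes are taken as prefixes of a full per-TF permutation of the
#' planted term, so raising \code{downstream_per_tf} only ever adds
#' downstream genes while leaving every other draw untouched.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param outDir output directory (created if absent).
#' @return Invisibly, a list with file paths, the manifest data.frame
#'   and the planted (mirna, term_id) pairs.
#' @export
generateFixture <- function(spec = defaultFixtureSpec(), outDir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  withFixtureRng(spec$seed, {
    tfs <- sprintf("TF%03d", seq_len(spec$n_tfs))
    nonTf <- sprintf("GEN%04d", seq_len(spec$n_genes))
    mirs <- sprintf("hsa-miR-%d-5p", seq_len(spec$n_mirnas))
    termIds <- sprintf("GO:%07d", seq_len(spec$n_terms))
    planted <- data.frame(mirna = mirs[seq_len(spec$n_planted)],
                          term_id = termIds[seq_len(spec$n_planted)],
                          stringsAsFactors = FALSE)

    ## GO terms: planted terms draw only non-TF genes; background terms
    ## draw from the whole genome (TFs included, which gives the TF
    ## density statistic something to see).
    sizes <- sample(seq(spec$term_size_range[1], spec$term_size_range[2]),
                    spec$n_terms, replace = TRUE)
    termGenes <- vector("list", spec$n_terms)
    names(termGenes) <- termIds
    for (i in seq_len(spec$n_terms)) {
      pool <- if (i <= spec$n_planted) nonTf else c(tfs, nonTf)
      termGenes[[i]] <- sort(sample(pool, sizes[i]))
    }
    plantedGenes <- unique(unlist(termGenes[seq_len(spec$n_planted)]))

    ## Direct targets: per planted miRNA, bridge TFs get the strongest
    ## scores; background targets are non-TF genes outside all planted
    ## terms with weaker scores.
    lo <- spec$score_range[1]; hi <- spec$score_range[2]
    cut <- lo + 0.3 * (hi - lo)
    bridgePool <- sample(tfs, spec$n_planted * spec$n_tf_bridges)
    bgPool <- setdiff(nonTf, plantedGenes)
    tgt <- list()
    bridges <- vector("list", spec$n_mirnas)
    for (i in seq_len(spec$n_mirnas)) {
      nBridge <- if (i <= spec$n_planted) spec$n_tf_bridges else 0L
      myBridges <- if (nBridge)
        bridgePool[((i - 1L) * spec$n_tf_bridges) + seq_len(nBridge)]
      else character()
      bridges[[i]] <- myBridges
      bg <- sample(bgPool, spec$targets_per_mirna - nBridge)
      tgt[[i]] <- data.frame(
        mirna = mirs[i],
        gene = c(myBridges, bg),
        score = c(stats::runif(nBridge, lo, cut),
                  stats::runif(length(bg), cut, hi)),
        stringsAsFactors = FALSE)
    }
    targets <- do.call(rbind, tgt)

    ## Network: planted edges (bridge TF -> prefix of a permuted planted
    ## term) plus Bernoulli background edges over all TF-gene pairs.
    plantedEdges <- list()
    for (i in seq_len(spec$n_planted)) {
      tGenes <- termGenes[[planted$term_id[i]]]
      for (tf in bridges[[i]]) {
        perm <- sample(tGenes)  # full permutation: RNG use independent of d
        plantedEdges[[length(plantedEdges) + 1L]] <- data.frame(
          tf = tf, gene = perm[seq_len(spec$downstream_per_tf)],
          stringsAsFactors = FALSE)
      }
    }
    allGenes <- c(tfs, nonTf)
    bern <- stats::runif(spec$n_tfs * length(allGenes)) <
      spec$background_edge_prob
    idx <- which(bern) - 1L
    bgEdges <- data.frame(
      tf = tfs[idx %/% length(allGenes) + 1L],
      gene = allGenes[idx %% length(allGenes) + 1L],
      stringsAsFactors = FALSE)
    bgEdges <- bgEdges[bgEdges$tf != bgEdges$gene, , drop = FALSE]
    edges <- unique(rbind(do.call(rbind, plantedEdges), bgEdges))

    ## Serialise in the dialects the loaders read.
    paths <- c(targets = file.path(outDir, "targets.tsv"),
               network = file.path(outDir, "network.tsv"),
               annotations = file.path(outDir, "annotations.tsv"),
               gold_standard = file.path(outDir, "gold_standard.tsv"))
    tdf <- data.frame(targets$mirna, targets$gene,
                      round(targets$score, 6), check.names = FALSE)
    names(tdf) <- c("miRNA", "Gene Symbol",
                    "Cumulative weighted context++ score")
    utils::write.table(tdf, paths[["targets"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ndf <- data.frame(tf = edges$tf, gene = edges$gene,
                      tissue = spec$tissue)
    utils::write.table(ndf, paths[["network"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    adf <- do.call(rbind, lapply(termIds, function(id)
      data.frame(gene = termGenes[[id]], acc = id,
                 name = sprintf("synthetic process %s", sub("GO:", "", id)),
                 ns = "biological_process", stringsAsFactors = FALSE)))
    names(adf) <- c("Gene name", "GO term accession", "GO term name",
                    "GO domain")
    utils::write.table(adf, paths[["annotations"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(planted, paths[["gold_standard"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)

    manifest <- data.frame(file = basename(unname(paths)),
                           md5 = unname(tools::md5sum(unname(paths))),
                           stringsAsFactors = FALSE)
    manifestPath <- file.path(outDir, "manifest.tsv")
    utils::write.table(manifest, manifestPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(list(paths = as.list(paths), manifest = manifest,
                   planted = planted, tissue = spec$tissue))
  })
}

#' The nine-gene toy scenario
#'
#' Builds, fully in memory, the minimal example motivating indirect
#' expansion: a biological-process term of nine genes of which exactly
#' one is a TF; one miRNA whose only direct target is that TF; and a
#' one-tissue network in which the TF regulates five of the eight
#' non-TF pathway genes. Direct targeting covers 1/9 of the pathway
#' (~11\%); indirect targeting covers 6/9 (~67\%).
#'
#' @return List with elements \code{mirna}, \code{table}
#'   (\linkS4class{TargetTable}), \code{network}
#'   (\linkS4class{TissueNetwork}), \code{annotations}
#'   (\linkS4class{AnnotationSet}) and \code{term}
#'   (\linkS4class{GoTerm}).
#' @export
fig1Toy <- function() {
  mirna <- "hsa-miR-toy-5p"
  tf <- "TF1"
  others <- sprintf("G%d", 1:8)
  table <- TargetTable(mirna = mirna, gene = tf, score = -0.5)
  network <- TissueNetwork("brain", tf = rep(tf, 5), gene = others[1:5])
  ann <- AnnotationSet(data.frame(
    gene = c(tf, others), term_id = "GO:0000001",
    term_name = "toy nine-gene pathway", namespace = "biological_process",
    stringsAsFactors = FALSE))
  list(mirna = mirna, table = table, network = network,
       annotations = ann, term = goTerm(ann, "GO:0000001"))
}
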