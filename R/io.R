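## Readers/writers for the four external inputs and the result formats.
## Gene symbols are uppercased on load everywhere so the three sources
## (target table, TF networks, annotations) join on the same key.

readTsv <- function(path, what) {
  if (!file.exists(path))
    stopIO("%s file not found: %s", what, path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "")
}

requireColumns <- function(df, cols, path) {
  missing <- setdiff(unname(cols), names(df))
  if (length(missing))
    stopFormat("file '%s' lacks required column(s): %s", path,
               paste(missing, collapse = ", "))
}

#' Construct a TargetTable from vectors
#'
#' Builds the scored miRNA-target container from parallel vectors,
#' collapsing duplicate (miRNA, gene) pairs to the minimum (strongest)
#' cumulative weighted context++ score. Gene symbols are uppercased.
#'
#' @param mirna,gene,score parallel vectors of miRNA identifier, gene
#'   symbol and context++ score.
#' @return A \linkS4class{TargetTable}.
#' @export
TargetTable <- function(mirna = character(), gene = character(),
                        score = numeric()) {
  df <- data.frame(mirna = as.character(mirna),
                   gene = toupper(as.character(gene)),
                   score = as.numeric(score), stringsAsFactors = FALSE)
  if (nrow(df)) {
    key <- paste(df$mirna, df$gene, sep = "\r")
    df <- df[order(key, df$score), , drop = FALSE]
    df <- df[!duplicated(paste(df$mirna, df$gene, sep = "\r")), , drop = FALSE]
    df <- df[order(df$mirna, df$score, df$gene), , drop = FALSE]
    rownames(df) <- NULL
  }
  new("TargetTable", records = df)
}

#' Load a TargetScan-style miRNA target table
#'
#' Reads a TSV of predicted miRNA targets, keeps high-confidence records
#' with score strictly below \code{scoreThreshold} (default -0.1, the
#' conventional cutoff on the cumulative weighted context++ score), and
#' collapses duplicate (miRNA, gene) pairs to their minimum score.
#'
#' @param path path to the TSV file.
#' @param scoreThreshold keep records with score < this value.
#' @param columns named character vector mapping the internal names
#'   \code{mirna}, \code{gene}, \code{score} to the file's column headers.
#' @return A \linkS4class{TargetTable}.
#' @export
loadTargetTable <- function(path, scoreThreshold = -0.1,
                            columns = c(mirna = "miRNA",
                                        gene = "Gene Symbol",
                                        score = "Cumulative weighted context++ score")) {
  df <- readTsv(path, "target table")
  requireColumns(df, columns, path)
  score_raw <- df[[columns[["score"]]]]
  score <- suppressWarnings(as.numeric(score_raw))
  bad <- which(is.na(score) & !is.na(score_raw))
  if (length(bad))
    stopFormat("non-numeric score '%s' in '%s' at line %d",
               score_raw[bad[1]], path, bad[1] + 1L)  # +1 for header
  keep <- !is.na(score) & score < scoreThreshold
  TargetTable(mirna = df[[columns[["mirna"]]]][keep],
              gene = df[[columns[["gene"]]]][keep],
              score = score[keep])
}

#' Construct a TissueNetwork from edge vectors
#'
#' @param tissue single tissue label.
#' @param tf,gene parallel vectors of regulator and regulated gene
#'   symbols (uppercased; duplicate edges collapsed).
#' @return A \linkS4class{TissueNetwork}.
#' @export
TissueNetwork <- function(tissue, tf = character(), gene = character()) {
  ed <- data.frame(tf = toupper(as.character(tf)),
                   gene = toupper(as.character(gene)),
                   stringsAsFactors = FALSE)
  ed <- ed[!duplicated(paste(ed$tf, ed$gene, sep = "\r")), , drop = FALSE]
  ed <- ed[order(ed$tf, ed$gene), , drop = FALSE]
  rownames(ed) <- NULL
  new("TissueNetwork", tissue = as.character(tissue), edges = ed,
      tfUniverse = sort(unique(ed$tf)))
}

#' Load tissue-specific TF-gene networks from a long-format TSV
#'
#' Reads a PANDA-style long edge list (one row per TF-gene-tissue
#' association, optional edge weight) and returns one network per
#' distinct tissue label. If \code{weightThreshold} is given, only edges
#' with weight >= threshold are kept.
#'
#' @param path path to the TSV file.
#' @param weightThreshold optional minimum edge weight.
#' @param columns named character vector mapping \code{tf}, \code{gene},
#'   \code{tissue} (and optionally \code{weight}) to file headers.
#' @return Named list of \linkS4class{TissueNetwork}, one per tissue.
#' @export
loadTissueNetworks <- function(path, weightThreshold = NULL,
                               columns = c(tf = "tf", gene = "gene",
                                           tissue = "tissue",
                                           weight = "weight")) {
  df <- readTsv(path, "tissue network")
  requireColumns(df, columns[c("tf", "gene", "tissue")], path)
  if (!is.null(weightThreshold)) {
    wcol <- columns[["weight"]]
    if (!wcol %in% names(df))
      stopFormat("weight threshold requested but file '%s' has no '%s' column",
                 path, wcol)
    df <- df[as.numeric(df[[wcol]]) >= weightThreshold, , drop = FALSE]
  }
  tissues <- sort(unique(df[[columns[["tissue"]]]]))
  nets <- lapply(tissues, function(ts) {
    sub <- df[df[[columns[["tissue"]]]] == ts, , drop = FALSE]
    TissueNetwork(ts, tf = sub[[columns[["tf"]]]],
                  gene = sub[[columns[["gene"]]]])
  })
  names(nets) <- tissues
  nets
}

#' Load a location-to-broad-tissue grouping table
#'
#' @param path two-column TSV (\code{location}, \code{broad_tissue}).
#' @return Named character vector: location -> broad tissue.
#' @export
loadTissueGrouping <- function(path) {
  df <- readTsv(path, "tissue grouping")
  requireColumns(df, c("location", "broad_tissue"), path)
  stats::setNames(as.character(df$broad_tissue), as.character(df$location))
}

#' Aggregate tissue-location networks into broad tissues
#'
#' Tissue-location networks (e.g. 38 sampled locations) are merged into
#' broad tissues (e.g. 29) by taking the union of each broad tissue's
#' location edge sets; TF universes are recomputed from the merged edges.
#'
#' @param networks named list of \linkS4class{TissueNetwork} keyed by
#'   location label.
#' @param grouping named character vector (location -> broad tissue), as
#'   from \code{\link{loadTissueGrouping}}.
#' @return Named list of \linkS4class{TissueNetwork}, one per broad tissue.
#' @export
aggregateTissues <- function(networks, grouping) {
  locs <- names(networks)
  unmapped <- setdiff(locs, names(grouping))
  if (length(unmapped))
    stopUsage("tissue location(s) missing from grouping: %s",
              paste(unmapped, collapse = ", "))
  broad <- sort(unique(unname(grouping[locs])))
  out <- lapply(broad, function(b) {
    members <- locs[grouping[locs] == b]
    ed <- do.call(rbind, lapply(networks[members], networkEdges))
    TissueNetwork(b, tf = ed$tf, gene = ed$gene)
  })
  names(out) <- broad
  out
}

#' Construct an AnnotationSet from a long annotation frame
#'
#' @param df data.frame with columns \code{gene}, \code{term_id},
#'   \code{term_name}, \code{namespace}.
#' @param namespace the GO namespace to retain.
#' @param minTermSize terms with fewer (strictly) annotated genes than
#'   this are removed.
#' @return An \linkS4class{AnnotationSet}.
#' @export
AnnotationSet <- function(df, namespace = "biological_process",
                          minTermSize = 5L) {
  df <- df[df$namespace == namespace, , drop = FALSE]
  df$gene <- toupper(df$gene)
  terms <- list()
  if (nrow(df)) {
    split_genes <- split(df$gene, df$term_id)
    split_names <- vapply(split(df$term_name, df$term_id),
                          function(x) x[1], character(1))
    ids <- sort(names(split_genes))
    terms <- lapply(ids, function(id) {
      g <- sort(unique(split_genes[[id]]))
      new("GoTerm", termId = id, name = unname(split_names[id]),
          namespace = namespace, genes = g)
    })
    names(terms) <- ids
    keep <- vapply(terms, function(t) length(t@genes) >= minTermSize,
                   logical(1))
    terms <- terms[keep]
  }
  universe <- sort(unique(unlist(lapply(terms, slot, "genes"),
                                 use.names = FALSE)))
  if (is.null(universe)) universe <- character()
  new("AnnotationSet", terms = terms, universe = universe,
      namespace = namespace, minTermSize = as.integer(minTermSize))
}

#' Load Biomart-style GO annotations
#'
#' Reads a gene/term/name/namespace TSV (as exported by Ensembl
#' Biomart), restricts to one namespace and removes terms annotating
#' fewer than \code{minTermSize} genes (default 5).
#'
#' @param path path to the TSV.
#' @param namespace GO namespace to keep.
#' @param minTermSize minimum retained term size.
#' @param columns named character vector mapping \code{gene},
#'   \code{term_id}, \code{term_name}, \code{namespace} to file headers.
#' @return An \linkS4class{AnnotationSet}.
#' @export
loadAnnotationsBiomart <- function(path, namespace = "biological_process",
                                   minTermSize = 5L,
                                   columns = c(gene = "Gene name",
                                               term_id = "GO term accession",
                                               term_name = "GO term name",
                                               namespace = "GO domain")) {
  df <- readTsv(path, "annotation")
  requireColumns(df, columns, path)
  acc <- df[[columns[["term_id"]]]]
  bad <- which(!grepl(GO_ACCESSION_RE, acc))
  if (length(bad))
    stopFormat("malformed GO accession '%s' in '%s' at line %d",
               acc[bad[1]], path, bad[1] + 1L)
  AnnotationSet(data.frame(gene = df[[columns[["gene"]]]],
                           term_id = acc,
                           term_name = df[[columns[["term_name"]]]],
                           namespace = df[[columns[["namespace"]]]],
                           stringsAsFactors = FALSE),
                namespace = namespace, minTermSize = minTermSize)
}

#' Default generic GO terms excluded from the gold standard
#'
#' Ubiquitous miRNA-machinery terms shared by most miRNAs (miRNA-mediated
#' translational inhibition, gene silencing by miRNA, gene silencing by
#' RNA) carry no miRNA-specific functional signal, so gold-standard
#' pairs annotating them are excluded. Accessions are packaged in
#' \code{extdata/generic_go_terms.tsv} and can be overridden.
#'
#' @return Character vector of GO accessions.
#' @export
defaultGenericTerms <- function() {
  path <- system.file("extdata", "generic_go_terms.tsv",
                      package = "mirTFenrich", mustWork = TRUE)
  readTsv(path, "generic term config")$term_id
}

#' Load a gold-standard GAF 2.x annotation file
#'
#' Parses a GAF 2.1/2.2 file of experimentally supported miRNA-GO
#' associations and applies the high-confidence filters: annotations
#' with ISS, NAS or TAS evidence codes are excluded, annotations with
#' no literature reference are excluded, and generic miRNA-machinery
#' terms are removed. Duplicate (miRNA, term) pairs are collapsed.
#'
#' Only GAF columns 2 (object id), 5 (GO id), 6 (reference) and
#' 7 (evidence code) are consumed.
#'
#' @param path path to the GAF file (comment lines start with '!').
#' @param genericTermIds GO accessions to drop;
#'   default \code{\link{defaultGenericTerms}()}.
#' @param excludeEvidence evidence codes to drop.
#' @return data.frame with columns mirna, term_id, evidence_code,
#'   reference; unique on (mirna, term_id).
#' @export
loadGoldStandard <- function(path, genericTermIds = defaultGenericTerms(),
                             excludeEvidence = c("ISS", "NAS", "TAS")) {
  if (!file.exists(path))
    stopIO("gold standard file not found: %s", path)
  lines <- readLines(path)
  dataIdx <- which(!startsWith(lines, "!") & nzchar(lines))
  dat <- lines[dataIdx]
  ## column count from tab count: strsplit would drop a trailing empty
  ## field, and GAF columns 16/17 are commonly empty
  nf <- nchar(dat) - nchar(gsub("\t", "", dat, fixed = TRUE)) + 1L
  bad <- which(nf != 17L)
  if (length(bad))
    stopFormat("GAF line %d has %d columns (expected 17) in '%s'",
               dataIdx[bad[1]], nf[bad[1]], path)
  fields <- strsplit(dat, "\t", fixed = TRUE)
  m <- do.call(rbind, lapply(fields, function(f) {
    length(f) <- 17L
    f[is.na(f)] <- ""
    f
  }))
  df <- data.frame(mirna = m[, 2], term_id = m[, 5],
                   reference = m[, 6], evidence_code = m[, 7],
                   stringsAsFactors = FALSE)
  df <- df[!df$evidence_code %in% excludeEvidence, , drop = FALSE]
  df <- df[nzchar(df$reference), , drop = FALSE]
  df <- df[!df$term_id %in% genericTermIds, , drop = FALSE]
  df <- df[!duplicated(paste(df$mirna, df$term_id, sep = "\r")), ,
           drop = FALSE]
  rownames(df) <- NULL
  df[, c("mirna", "term_id", "evidence_code", "reference")]
}

#' Load a plain gold-standard pair TSV
#'
#' @param path TSV with columns \code{mirna}, \code{term_id} (extra
#'   columns are kept if present).
#' @return data.frame with at least mirna and term_id, unique pairs.
#' @export
loadGoldStandardTsv <- function(path) {
  df <- readTsv(path, "gold standard")
  requireColumns(df, c("mirna", "term_id"), path)
  df <- df[!duplicated(paste(df$mirna, df$term_id, sep = "\r")), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write an EnrichmentResult as TSV
#'
#' Writes the ranked result table (term_id, term_name, k, K, n, N,
#' pvalue, fdr, rank, percentile_rank) in rank order.
#'
#' @param result an \linkS4class{EnrichmentResult}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeEnrichmentTsv <- function(result, path) {
  stopifnot(is(result, "EnrichmentResult"))
  ok <- tryCatch({
    utils::write.table(enrichTable(result)[, ENRICH_COLS, drop = FALSE],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopIO("cannot write enrichment TSV to '%s'", path)
  invisible(path)
}

#' Read back an enrichment TSV
#'
#' Inverse of \code{\link{writeEnrichmentTsv}}; mainly for round-trip
#' checks and for consuming previously written runs.
#'
#' @param path path to a file written by \code{writeEnrichmentTsv}.
#' @param parameters optional provenance list.
#' @return An \linkS4class{EnrichmentResult}.
#' @export
readEnrichmentTsv <- function(path, parameters = list()) {
  df <- readTsv(path, "enrichment result")
  requireColumns(df, ENRICH_COLS, path)
  n <- if (nrow(df)) df$n[1] else 0L
  N <- if (nrow(df)) df$N[1] else 0L
  df$k <- as.integer(df$k); df$K <- as.integer(df$K)
  df$n <- as.integer(df$n); df$N <- as.integer(df$N)
  df$rank <- as.integer(df$rank)
  new("EnrichmentResult", table = df, universeSize = as.integer(N),
      targetSize = as.integer(n), parameters = parameters)
}

#' Export a TargetSet as a one-line GMT gene set
#'
#' @param targetSet a \linkS4class{TargetSet}.
#' @param path output path.
#' @param name gene-set name; defaults to miRNAs/mode/tissue provenance.
#' @return Invisibly, the path.
#' @export
writeGmt <- function(targetSet, path, name = NULL) {
  stopifnot(is(targetSet, "TargetSet"))
  if (is.null(name)) {
    tis <- if (length(tissueLabel(targetSet))) tissueLabel(targetSet) else "any"
    name <- paste(paste(mirnas(targetSet), collapse = "|"),
                  targetingMode(targetSet), tis, sep = "_")
  }
  desc <- sprintf("top_fraction=%g", topFraction(targetSet))
  line <- paste(c(name, desc, sort(targetGenes(targetSet))), collapse = "\t")
  writeLines(line, path)
  invisible(path)
}
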