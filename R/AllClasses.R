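#' @import methods
NULL

GO_ACCESSION_RE <- "^GO:[0-9]{7}$"

#' TargetTable: scored miRNA-to-gene target records
#'
#' Container for TargetScan-style miRNA target predictions after score
#' filtering. One row per (miRNA, gene) pair; duplicates present in the
#' source file (multiple sites or transcripts) are collapsed to the
#' minimum, i.e. strongest, cumulative weighted context++ score. More
#' negative scores mean stronger predicted repression.
#'
#' @slot records data.frame with columns \code{mirna}, \code{gene},
#'   \code{score}; unique on (mirna, gene).
#' @exportClass TargetTable
setClass("TargetTable", representation(records = "data.frame"))

setValidity("TargetTable", function(object) {
  rec <- object@records
  msgs <- character()
  if (!all(c("mirna", "gene", "score") %in% names(rec)))
    return("records must have columns mirna, gene, score")
  if (nrow(rec)) {
    if (!is.numeric(rec$score) || any(!is.finite(rec$score)))
      msgs <- c(msgs, "scores must be finite numbers")
    if (any(!nzchar(rec$mirna)) || any(!nzchar(rec$gene)))
      msgs <- c(msgs, "mirna and gene must be non-empty strings")
    if (anyDuplicated(paste(rec$mirna, rec$gene, sep = "\r")))
      msgs <- c(msgs, "duplicate (mirna, gene) pairs present")
  }
  if (length(msgs)) msgs else TRUE
})

#' TissueNetwork: TF-to-gene regulatory edges for one tissue
#'
#' A set of transcription-factor-to-gene edges for a single tissue,
#' e.g. one tissue of a PANDA-style network collection. The TF universe
#' is the set of all regulator symbols and is what defines "being a TF"
#' downstream (target expansion, TF density).
#'
#' @slot tissue single tissue label.
#' @slot edges data.frame with columns \code{tf}, \code{gene}; a set
#'   (no duplicate rows).
#' @slot tfUniverse character vector of all TF symbols.
#' @exportClass TissueNetwork
setClass("TissueNetwork", representation(
  tissue = "character", edges = "data.frame", tfUniverse = "character"))

setValidity("TissueNetwork", function(object) {
  msgs <- character()
  if (length(object@tissue) != 1L || !nzchar(object@tissue))
    msgs <- c(msgs, "tissue must be a single non-empty label")
  ed <- object@edges
  if (!all(c("tf", "gene") %in% names(ed)))
    return("edges must have columns tf, gene")
  if (nrow(ed)) {
    if (any(!nzchar(ed$tf)) || any(!nzchar(ed$gene)))
      msgs <- c(msgs, "tf and gene must be non-empty")
    if (anyDuplicated(paste(ed$tf, ed$gene, sep = "\r")))
      msgs <- c(msgs, "duplicate (tf, gene) edges present")
    if (!all(unique(ed$tf) %in% object@tfUniverse))
      msgs <- c(msgs, "every edge tf must be in tfUniverse")
  }
  if (length(msgs)) msgs else TRUE
})

#' GoTerm: a single GO term with its annotated gene set
#'
#' @slot termId GO accession ("GO:NNNNNNN").
#' @slot name human-readable term label.
#' @slot namespace one of biological_process, molecular_function,
#'   cellular_component.
#' @slot genes set (character vector, unique) of annotated gene symbols.
#' @exportClass GoTerm
setClass("GoTerm", representation(
  termId = "character", name = "character",
  namespace = "character", genes = "character"))

setValidity("GoTerm", function(object) {
  msgs <- character()
  if (length(object@termId) != 1L || !grepl(GO_ACCESSION_RE, object@termId))
    msgs <- c(msgs, "termId must match GO:NNNNNNN")
  if (!object@namespace %in%
      c("biological_process", "molecular_function", "cellular_component"))
    msgs <- c(msgs, "invalid namespace")
  if (anyDuplicated(object@genes))
    msgs <- c(msgs, "genes must be unique")
  if (length(msgs)) msgs else TRUE
})

#' AnnotationSet: size-filtered GO term-to-gene map for one namespace
#'
#' Flat GO annotations (no ontology-graph propagation) restricted to one
#' namespace, with terms below the minimum size removed. The gene
#' universe is the union of all retained terms' gene sets and is the
#' population used by the hypergeometric test.
#'
#' @slot terms named list of \linkS4class{GoTerm} (names = accessions).
#' @slot universe union of all retained terms' genes.
#' @slot namespace the GO namespace the set was restricted to.
#' @slot minTermSize the size filter that was applied.
#' @exportClass AnnotationSet
setClass("AnnotationSet", representation(
  terms = "list", universe = "character",
  namespace = "character", minTermSize = "integer"))

setValidity("AnnotationSet", function(object) {
  msgs <- character()
  if (length(object@terms)) {
    if (!all(vapply(object@terms, is, logical(1), "GoTerm")))
      return("terms must be a list of GoTerm objects")
    ids <- vapply(object@terms, slot, character(1), "termId")
    if (!identical(unname(ids), names(object@terms)))
      msgs <- c(msgs, "term list names must equal term accessions")
    sizes <- vapply(object@terms, function(t) length(t@genes), integer(1))
    if (any(sizes < object@minTermSize))
      msgs <- c(msgs, "a term is smaller than minTermSize")
    uni <- sort(unique(unlist(lapply(object@terms, slot, "genes"),
                              use.names = FALSE)))
    if (!setequal(uni, object@universe))
      msgs <- c(msgs, "universe must equal the union of term gene sets")
  }
  if (length(msgs)) msgs else TRUE
})

#' TargetSet: a resolved miRNA target gene set with provenance
#'
#' The outcome of target resolution: the gene set plus how it was made
#' (which miRNAs, direct or indirect mode, tissue for indirect mode, and
#' the top fraction of the score-sorted target list used).
#'
#' @slot mirnas miRNA identifiers the set was derived from.
#' @slot mode "direct" or "indirect".
#' @slot tissue tissue label (length 0 for direct mode).
#' @slot topFraction fraction in (0, 1] of the score-sorted target list.
#' @slot genes the resolved gene set.
#' @exportClass TargetSet
setClass("TargetSet", representation(
  mirnas = "character", mode = "character", tissue = "character",
  topFraction = "numeric", genes = "character"))

setValidity("TargetSet", function(object) {
  msgs <- character()
  if (!object@mode %in% c("direct", "indirect"))
    msgs <- c(msgs, "mode must be 'direct' or 'indirect'")
  if (object@mode == "indirect" && length(object@tissue) != 1L)
    msgs <- c(msgs, "indirect mode requires a tissue label")
  if (length(object@topFraction) != 1L || object@topFraction <= 0 ||
      object@topFraction > 1)
    msgs <- c(msgs, "topFraction must lie in (0, 1]")
  if (anyDuplicated(object@genes))
    msgs <- c(msgs, "genes must be unique")
  if (length(msgs)) msgs else TRUE
})

#' EnrichmentResult: ranked GO over-representation results
#'
#' One row per tested term with hypergeometric counts (k of n target
#' genes in a term of size K, universe N), the upper-tail p-value,
#' Benjamini-Hochberg FDR, the p-value rank (ties broken by accession)
#' and the percentile rank (rank divided by number of terms tested).
#'
#' @slot table data.frame sorted by rank with columns term_id,
#'   term_name, k, K, n, N, pvalue, fdr, rank, percentile_rank.
#' @slot universeSize N.
#' @slot targetSize n (target genes inside the universe).
#' @slot parameters list recording mode/tissue/fraction provenance.
#' @exportClass EnrichmentResult
setClass("EnrichmentResult", representation(
  table = "data.frame", universeSize = "integer",
  targetSize = "integer", parameters = "list"))

ENRICH_COLS <- c("term_id", "term_name", "k", "K", "n", "N",
                 "pvalue", "fdr", "rank", "percentile_rank")

setValidity("EnrichmentResult", function(object) {
  tab <- object@table
  if (!all(ENRICH_COLS %in% names(tab)))
    return(paste("table must have columns:", paste(ENRICH_COLS, collapse = ", ")))
  msgs <- character()
  if (nrow(tab)) {
    if (!identical(tab$rank, seq_len(nrow(tab))))
      msgs <- c(msgs, "rows must be sorted by rank 1..T")
    if (is.unsorted(tab$pvalue))
      msgs <- c(msgs, "pvalues must be non-decreasing along rank order")
    if (any(tab$k > pmin(tab$n, tab$K)) || any(tab$K > tab$N))
      msgs <- c(msgs, "inconsistent hypergeometric counts")
  }
  if (length(msgs)) msgs else TRUE
})
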