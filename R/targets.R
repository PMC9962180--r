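## Target resolution: direct target slicing, one-hop TF expansion,
## multi-miRNA intersection, and term coverage.

#' Direct targets of a miRNA
#'
#' Returns the miRNA's predicted target genes, restricted to the top
#' fraction of its score-sorted list: records are sorted ascending by
#' context++ score (most negative, i.e. strongest, first; ties broken
#' by gene symbol so runs are reproducible) and the first
#' \code{ceiling(topFraction * count)} genes are kept.
#'
#' A miRNA absent from the table yields an empty set with a warning
#' (not an error), so batch runs over gold-standard lists proceed.
#'
#' @param mirna miRNA identifier.
#' @param table a \linkS4class{TargetTable}.
#' @param topFraction fraction in (0, 1] of the sorted target list.
#' @return A \linkS4class{TargetSet} with mode "direct".
#' @export
directTargets <- function(mirna, table, topFraction = 1) {
  stopifnot(is(table, "TargetTable"))
  if (!is.numeric(topFraction) || length(topFraction) != 1L ||
      topFraction <= 0 || topFraction > 1)
    stopUsage("topFraction must be a single number in (0, 1]")
  rec <- targetRecords(table)
  rec <- rec[rec$mirna == mirna, , drop = FALSE]
  if (!nrow(rec)) {
    warning(sprintf("miRNA '%s' has no records in the target table", mirna))
    genes <- character()
  } else {
    rec <- rec[order(rec$score, rec$gene), , drop = FALSE]
    genes <- rec$gene[seq_len(ceiling(topFraction * nrow(rec)))]
  }
  new("TargetSet", mirnas = mirna, mode = "direct", tissue = character(),
      topFraction = topFraction, genes = sort(genes))
}

#' Indirect targets of a miRNA through a tissue TF network
#'
#' Expands the miRNA's direct target set through one layer of
#' transcriptional regulation: every direct target that is a TF in the
#' tissue network contributes its regulated genes. By default the
#' returned set is the union of direct targets and TF-downstream genes
#' (the combined set used for enrichment); \code{includeDirect = FALSE}
#' gives the downstream-only variant.
#'
#' Top-fraction slicing is applied to the miRNA's full target list
#' before the TF intersection, not to the TF subset.
#'
#' @param mirna miRNA identifier.
#' @param table a \linkS4class{TargetTable}.
#' @param network a \linkS4class{TissueNetwork}.
#' @param topFraction fraction in (0, 1] of the sorted target list.
#' @param includeDirect include the direct targets in the result
#'   (default TRUE).
#' @return A \linkS4class{TargetSet} with mode "indirect".
#' @export
indirectTargets <- function(mirna, table, network, topFraction = 1,
                            includeDirect = TRUE) {
  stopifnot(is(network, "TissueNetwork"))
  direct <- directTargets(mirna, table, topFraction)
  d <- targetGenes(direct)
  tfs <- intersect(d, tfUniverse(network))
  ed <- networkEdges(network)
  downstream <- unique(ed$gene[ed$tf %in% tfs])
  genes <- if (includeDirect) union(d, downstream) else setdiff(downstream, d)
  new("TargetSet", mirnas = mirna, mode = "indirect",
      tissue = networkTissue(network), topFraction = topFraction,
      genes = sort(genes))
}

#' Intersect target sets from several miRNAs
#'
#' For multiple input miRNAs the canonical combined set is the
#' intersection of the per-miRNA target sets (genes co-targeted by all
#' of them). All sets must share mode and tissue. A union variant is
#' offered for exploration but is not the canonical combination.
#'
#' @param sets list of \linkS4class{TargetSet} (at least one).
#' @param combine "intersection" (canonical) or "union".
#' @return A \linkS4class{TargetSet} covering all input miRNAs.
#' @export
intersectTargetSets <- function(sets, combine = c("intersection", "union")) {
  combine <- match.arg(combine)
  if (!length(sets) || !all(vapply(sets, is, logical(1), "TargetSet")))
    stopUsage("sets must be a non-empty list of TargetSet objects")
  modes <- unique(vapply(sets, targetingMode, character(1)))
  if (length(modes) != 1L)
    stopUsage("cannot combine target sets with mixed modes: %s",
              paste(modes, collapse = ", "))
  tissues <- unique(unlist(lapply(sets, tissueLabel)))
  if (length(tissues) > 1L)
    stopUsage("cannot combine target sets from different tissues: %s",
              paste(tissues, collapse = ", "))
  geneSets <- lapply(sets, targetGenes)
  genes <- Reduce(if (combine == "intersection") intersect else union,
                  geneSets)
  new("TargetSet",
      mirnas = unlist(lapply(sets, mirnas)),
      mode = modes, tissue = tissueLabel(sets[[1]]),
      topFraction = topFraction(sets[[1]]), genes = sort(genes))
}

#' Fraction of a GO term's genes covered by a target set
#'
#' The coverage of a term is |target genes in the term| / |term size| —
#' the quantity that motivates indirect expansion: a pathway regulated
#' mostly through one targeted TF has low direct coverage but high
#' indirect coverage.
#'
#' @param targetSet a \linkS4class{TargetSet}.
#' @param term a \linkS4class{GoTerm} with a non-empty gene set.
#' @return Fraction in [0, 1].
#' @export
termCoverage <- function(targetSet, term) {
  stopifnot(is(targetSet, "TargetSet"), is(term, "GoTerm"))
  tg <- targetGenes(term)
  if (!length(tg))
    stopUsage("term '%s' has an empty gene set", term@termId)
  length(intersect(targetGenes(targetSet), tg)) / length(tg)
}
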