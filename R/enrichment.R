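## Hypergeometric over-representation of a target set against GO terms,
## with p-value ranking, BH FDR and percentile ranks.

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X hypergeometric with population size N, K marked
#' elements and n draws — the one-sided over-representation p-value for
#' observing at least k annotated genes among the n target genes.
#' Computed with \code{stats::phyper}, which works on log scale
#' internally and is numerically stable in the far tail.
#'
#' @param k observed overlap (integer >= 0).
#' @param K number of marked elements (term size within universe).
#' @param n number of draws (target-set size within universe).
#' @param N population (universe) size.
#' @return Probability in [0, 1]; 1 when k = 0, 0 when k > min(n, K).
#' @export
hypergeomUpperTail <- function(k, K, n, N) {
  if (any(K < 0) || any(n < 0) || any(k < 0) || any(K > N) || any(n > N))
    stopUsage("invalid hypergeometric parameters: need 0 <= K <= N, 0 <= n <= N, k >= 0")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' GO over-representation of a target set
#'
#' Tests every annotation term of size K >= \code{minTermSize} (sizes
#' taken within the universe) for over-representation in the target set
#' with the upper-tail hypergeometric test. The universe N is the set
#' of all genes annotated to at least one retained term; the target
#' size n counts only target genes inside that universe. Rows are
#' ranked by p-value ascending with ties broken by accession, FDR is
#' Benjamini-Hochberg across all tested terms, and each term's
#' percentile rank is rank / number of terms tested. Ranking uses raw
#' p-values; the FDR column is reported alongside.
#'
#' @param targetSet a \linkS4class{TargetSet}.
#' @param annotations an \linkS4class{AnnotationSet}.
#' @param minTermSize minimum within-universe term size to test.
#' @return An \linkS4class{EnrichmentResult}.
#' @export
enrich <- function(targetSet, annotations, minTermSize = 5L) {
  stopifnot(is(targetSet, "TargetSet"), is(annotations, "AnnotationSet"))
  universe <- annotationUniverse(annotations)
  N <- length(universe)
  tg <- intersect(targetGenes(targetSet), universe)
  n <- length(tg)
  if (n == 0L)
    stopData(paste("no target gene is in the annotation universe;",
                   "check that the gene symbol namespaces of the target",
                   "table and the annotations overlap"))
  ids <- termIds(annotations)
  rows <- lapply(ids, function(id) {
    genes <- targetGenes(goTerm(annotations, id))
    K <- length(genes)  # terms are already within-universe by construction
    if (K < minTermSize) return(NULL)
    k <- length(intersect(tg, genes))
    data.frame(term_id = id, term_name = goTerm(annotations, id)@name,
               k = k, K = K, n = n, N = N, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab))
    stopData("no term passed the size filter (minTermSize = %d)", minTermSize)
  tab$pvalue <- hypergeomUpperTail(tab$k, tab$K, tab$n, tab$N)
  ord <- order(tab$pvalue, tab$term_id)
  tab <- tab[ord, , drop = FALSE]
  tab$fdr <- stats::p.adjust(tab$pvalue, method = "BH")
  tab$rank <- seq_len(nrow(tab))
  tab$percentile_rank <- tab$rank / nrow(tab)
  rownames(tab) <- NULL
  new("EnrichmentResult", table = tab, universeSize = as.integer(N),
      targetSize = as.integer(n),
      parameters = list(mirnas = mirnas(targetSet),
                        mode = targetingMode(targetSet),
                        tissue = tissueLabel(targetSet),
                        top_fraction = topFraction(targetSet),
                        min_term_size = as.integer(minTermSize)))
}

#' Best percentile rank among a set of known terms
#'
#' Given an enrichment result and a set of terms known to be associated
#' with the miRNA, picks the known term with the smallest p-value
#' (smallest rank) and returns its accession and percentile rank — the
#' per-miRNA score of the benchmark protocol.
#'
#' @param result an \linkS4class{EnrichmentResult}.
#' @param termIds character vector of GO accessions.
#' @return List with elements \code{term_id}, \code{rank},
#'   \code{percentile}, \code{pvalue}.
#' @export
percentileRankOf <- function(result, termIds) {
  stopifnot(is(result, "EnrichmentResult"))
  tab <- enrichTable(result)
  hit <- tab[tab$term_id %in% termIds, , drop = FALSE]
  if (!nrow(hit))
    stopUsage("none of the terms were tested: %s",
              paste(termIds, collapse = ", "))
  best <- hit[which.min(hit$rank), , drop = FALSE]
  list(term_id = best$term_id, rank = best$rank,
       percentile = best$percentile_rank, pvalue = best$pvalue)
}
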