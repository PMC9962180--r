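#' Accessors for mirTFenrich classes
#'
#' Small accessor generics so downstream code never touches slots.
#'
#' @param x an object of the class named in the method.
#' @param ... unused.
#' @return The corresponding component (see each method).
#' @name accessors
#' @aliases targetRecords tfUniverse networkEdges networkTissue termIds
#'   goTerm termNames termSizes annotationUniverse targetGenes mirnas
#'   targetingMode tissueLabel topFraction enrichTable universeSize
#'   targetSize
NULL

#' @rdname accessors
#' @export
setGeneric("targetRecords", function(x) standardGeneric("targetRecords"))
#' @rdname accessors
#' @export
setGeneric("tfUniverse", function(x) standardGeneric("tfUniverse"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("networkTissue", function(x) standardGeneric("networkTissue"))
#' @rdname accessors
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))
#' @rdname accessors
#' @param id a single GO accession.
#' @export
setGeneric("goTerm", function(x, id) standardGeneric("goTerm"))
#' @rdname accessors
#' @export
setGeneric("termNames", function(x) standardGeneric("termNames"))
#' @rdname accessors
#' @export
setGeneric("termSizes", function(x) standardGeneric("termSizes"))
#' @rdname accessors
#' @export
setGeneric("annotationUniverse", function(x) standardGeneric("annotationUniverse"))
#' @rdname accessors
#' @export
setGeneric("targetGenes", function(x) standardGeneric("targetGenes"))
#' @rdname accessors
#' @export
setGeneric("mirnas", function(x) standardGeneric("mirnas"))
#' @rdname accessors
#' @export
setGeneric("targetingMode", function(x) standardGeneric("targetingMode"))
#' @rdname accessors
#' @export
setGeneric("tissueLabel", function(x) standardGeneric("tissueLabel"))
#' @rdname accessors
#' @export
setGeneric("topFraction", function(x) standardGeneric("topFraction"))
#' @rdname accessors
#' @export
setGeneric("enrichTable", function(x) standardGeneric("enrichTable"))
#' @rdname accessors
#' @export
setGeneric("universeSize", function(x) standardGeneric("universeSize"))
#' @rdname accessors
#' @export
setGeneric("targetSize", function(x) standardGeneric("targetSize"))

setMethod("targetRecords", "TargetTable", function(x) x@records)
setMethod("tfUniverse", "TissueNetwork", function(x) x@tfUniverse)
setMethod("networkEdges", "TissueNetwork", function(x) x@edges)
setMethod("networkTissue", "TissueNetwork", function(x) x@tissue)
setMethod("termIds", "AnnotationSet", function(x) names(x@terms))
setMethod("goTerm", "AnnotationSet", function(x, id) {
  if (!id %in% names(x@terms))
    stopUsage("term '%s' is not in the annotation set", id)
  x@terms[[id]]
})
setMethod("termNames", "AnnotationSet", function(x)
  vapply(x@terms, slot, character(1), "name"))
setMethod("termSizes", "AnnotationSet", function(x)
  vapply(x@terms, function(t) length(t@genes), integer(1)))
setMethod("annotationUniverse", "AnnotationSet", function(x) x@universe)
setMethod("targetGenes", "TargetSet", function(x) x@genes)
setMethod("targetGenes", "GoTerm", function(x) x@genes)
setMethod("mirnas", "TargetSet", function(x) x@mirnas)
setMethod("targetingMode", "TargetSet", function(x) x@mode)
setMethod("tissueLabel", "TargetSet", function(x) x@tissue)
setMethod("topFraction", "TargetSet", function(x) x@topFraction)
setMethod("enrichTable", "EnrichmentResult", function(x) x@table)
setMethod("universeSize", "EnrichmentResult", function(x) x@universeSize)
setMethod("targetSize", "EnrichmentResult", function(x) x@targetSize)

setMethod("show", "TargetTable", function(object) {
  rec <- object@records
  cat(sprintf("TargetTable: %d records, %d miRNAs, %d genes\n",
              nrow(rec), length(unique(rec$mirna)),
              length(unique(rec$gene))))
  if (nrow(rec))
    cat(sprintf("  score range: [%.3f, %.3f]\n",
                min(rec$score), max(rec$score)))
})

setMethod("show", "TissueNetwork", function(object) {
  cat(sprintf("TissueNetwork '%s': %d edges, %d TFs, %d regulated genes\n",
              object@tissue, nrow(object@edges),
              length(object@tfUniverse),
              length(unique(object@edges$gene))))
})

setMethod("show", "GoTerm", function(object) {
  cat(sprintf("GoTerm %s '%s' (%s): %d genes\n", object@termId,
              object@name, object@namespace, length(object@genes)))
})

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet (%s): %d terms (size >= %d), universe %d genes\n",
              object@namespace, length(object@terms),
              object@minTermSize, length(object@universe)))
})

setMethod("show", "TargetSet", function(object) {
  tis <- if (length(object@tissue)) object@tissue else "<none>"
  cat(sprintf(
    "TargetSet: %d genes | miRNAs: %s | mode: %s | tissue: %s | top fraction: %g\n",
    length(object@genes), paste(object@mirnas, collapse = ","),
    object@mode, tis, object@topFraction))
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult: %d terms tested, n = %d of N = %d\n",
              nrow(object@table), object@targetSize, object@universeSize))
  if (nrow(object@table)) {
    cat("  top terms:\n")
    top <- utils::head(object@table, 3L)
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %d. %s %s (k=%d/K=%d, p=%.3g)\n", top$rank[i],
                  top$term_id[i], top$term_name[i], top$k[i], top$K[i],
                  top$pvalue[i]))
  }
})
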