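## TF density per GO term and the development-vs-other group comparison.

DEVELOPMENT_KEYWORDS <- c("development", "cell fate", "differentiation",
                          "stem cell", "morphogenesis",
                          "cell specification", "formation")

#' TF density of a GO term
#'
#' TF density = (number of TFs in the term) / (term size). Terms made
#' up mostly of transcription factors — typically developmental cell
#' fate / differentiation terms — are the ones most amplified by
#' indirect targeting, which is what this statistic quantifies.
#'
#' @param term a \linkS4class{GoTerm} with a non-empty gene set.
#' @param tfUniverse character vector of TF symbols (by default take
#'   the regulator set of the aggregated tissue networks).
#' @param keywords keywords for the development classification.
#' @return One-row data.frame: term_id, term_name, n_tf, n_genes,
#'   density, is_development.
#' @export
tfDensity <- function(term, tfUniverse, keywords = DEVELOPMENT_KEYWORDS) {
  stopifnot(is(term, "GoTerm"))
  genes <- targetGenes(term)
  if (!length(genes))
    stopUsage("term '%s' has an empty gene set", term@termId)
  nTf <- length(intersect(genes, tfUniverse))
  data.frame(term_id = term@termId, term_name = term@name,
             n_tf = nTf, n_genes = length(genes),
             density = nTf / length(genes),
             is_development = classifyDevelopment(term@name, keywords),
             stringsAsFactors = FALSE)
}

#' TF density for every term of an annotation set
#'
#' @param annotations an \linkS4class{AnnotationSet}.
#' @param tfUniverse character vector of TF symbols.
#' @param keywords keywords for the development classification.
#' @return data.frame, one row per term (columns as \code{\link{tfDensity}}).
#' @export
tfDensityTable <- function(annotations, tfUniverse,
                           keywords = DEVELOPMENT_KEYWORDS) {
  stopifnot(is(annotations, "AnnotationSet"))
  out <- do.call(rbind, lapply(termIds(annotations), function(id)
    tfDensity(goTerm(annotations, id), tfUniverse, keywords)))
  if (is.null(out))
    out <- data.frame(term_id = character(), term_name = character(),
                      n_tf = integer(), n_genes = integer(),
                      density = numeric(), is_development = logical())
  rownames(out) <- NULL
  out
}

#' Classify a term name as development-related
#'
#' A term is development-related if any keyword occurs as a
#' case-insensitive substring of its name. The default keywords are
#' development, cell fate, differentiation, stem cell, morphogenesis,
#' cell specification and formation; matching is substring rather than
#' word-boundary so that e.g. "cardiac ventricle formation" is caught.
#'
#' @param termName term label (vectorised).
#' @param keywords non-empty character vector of keywords.
#' @return Logical vector.
#' @export
classifyDevelopment <- function(termName, keywords = DEVELOPMENT_KEYWORDS) {
  if (!length(keywords))
    stopUsage("keywords must be non-empty")
  hit <- rep(FALSE, length(termName))
  low <- tolower(termName)
  for (kw in tolower(keywords))
    hit <- hit | grepl(kw, low, fixed = TRUE)
  hit
}

#' Compare TF density between development and other terms
#'
#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test of the hypothesis
#' that development-related terms have higher TF density than other
#' terms, restricted to terms containing at least one TF. The reported
#' statistic is the rank sum of the development group. Small tie-free
#' samples are tested exactly; otherwise a tie-corrected normal
#' approximation is used.
#'
#' @param rows data.frame as from \code{\link{tfDensityTable}}.
#' @param alternative "greater" (development group stochastically
#'   greater, the default) or "two.sided".
#' @return List: n_development, n_other, statistic (development-group
#'   rank sum), p_value.
#' @export
compareDensityGroups <- function(rows, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  rows <- rows[rows$n_tf >= 1L, , drop = FALSE]
  dev <- rows$density[rows$is_development]
  oth <- rows$density[!rows$is_development]
  if (!length(dev) || !length(oth))
    stopData("both groups must be non-empty after the >=1 TF restriction (development: %d, other: %d)",
             length(dev), length(oth))
  ## ties are the norm for density data; the tie-corrected normal
  ## approximation is intended, so the exact-test warning is noise
  wt <- suppressWarnings(stats::wilcox.test(dev, oth,
                                            alternative = alternative))
  rankSum <- sum(rank(c(dev, oth))[seq_along(dev)])
  list(n_development = length(dev), n_other = length(oth),
       statistic = rankSum, p_value = unname(wt$p.value))
}
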