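#' Call cell-type-specific genes by the fold-change specificity rule
#'
#' For each gene, entities are ranked by expression; a gene is specific to
#' its top entity when that expression is strictly greater than
#' `foldThreshold` times the expression in every other entity (i.e. than the
#' runner-up), and at least `minTopExpression`. Ties for the top entity
#' yield no call, since the rule requires a unique top entity. The default
#' threshold of 20 is the standard atlas-based specificity rule for
#' tissue-of-origin work.
#'
#' @param reference a [ReferenceMatrix-class] (or entity x gene matrix) with
#'   at least two entities.
#' @param foldThreshold unitless fold threshold, strict `>` (default 20).
#' @param minTopExpression expression floor (TPM) on the top entity; genes
#'   expressed below it everywhere give no call (default 1).
#' @return A `DataFrame` with one row per specific gene: `gene`,
#'   `topEntity`, `topValue`, `runnerUpValue`, `fold` (`Inf` when the
#'   runner-up is exactly 0).
#' @examples
#' ref <- generateReference(simulationConfig(nGenes = 60, nCelltypes = 3,
#'                                           markersPerType = 5, seed = 1))
#' calls <- callSpecificGenes(ref)
#' table(calls$topEntity)
#' @export
callSpecificGenes <- function(reference, foldThreshold = 20,
                              minTopExpression = 1) {
  v <- if (is(reference, "ReferenceMatrix")) refValues(reference)
       else reference
  if (nrow(v) < 2L)
    stop("the specificity rule is undefined for a single-entity reference")
  if (foldThreshold <= 1) stop("foldThreshold must be > 1")
  topIdx <- apply(v, 2L, which.max)
  topVal <- v[cbind(topIdx, seq_len(ncol(v)))]
  runnerUp <- vapply(seq_len(ncol(v)), function(j)
    max(v[-topIdx[j], j]), numeric(1))
  fold <- ifelse(runnerUp == 0 & topVal > 0, Inf, topVal / runnerUp)
  tie <- vapply(seq_len(ncol(v)), function(j)
    sum(v[, j] == topVal[j]) > 1L, logical(1))
  # the strict fold comparison is done in product form: top > thr * runnerUp
  # avoids the rounding wobble of the division at exact-fold boundaries
  pass <- topVal > foldThreshold * runnerUp
  keep <- !tie & pass & topVal >= minTopExpression
  S4Vectors::DataFrame(
    gene = colnames(v)[keep],
    topEntity = rownames(v)[topIdx[keep]],
    topValue = unname(topVal[keep]),
    runnerUpValue = unname(runnerUp[keep]),
    fold = unname(fold[keep])
  )
}

#' Call pairwise-enriched genes between two transcriptomes
#'
#' Compares two expression vectors over the same gene universe (for example
#' bone marrow vs whole blood) and returns the genes enriched in each:
#' a gene is A-enriched when `(a + pc) / (b + pc) > foldThreshold`, and
#' symmetrically for B. The two sets are disjoint by construction. The
#' default 5-fold threshold is the conventional cut for marrow/blood
#' enrichment panels; with `pseudocount = 0` zero denominators give an
#' infinite ratio (strict behavior).
#'
#' @param exprA,exprB named numeric vectors of expression (TPM) over an
#'   identical gene universe.
#' @param foldThreshold unitless, strict `>` (default 5).
#' @param pseudocount TPM added to both sides of each ratio (default 0.1).
#' @return A list with character vectors `aEnriched` and `bEnriched`.
#' @export
callEnrichedGenes <- function(exprA, exprB, foldThreshold = 5,
                              pseudocount = 0.1) {
  if (is.null(names(exprA)) || is.null(names(exprB)) ||
      !identical(sort(names(exprA)), sort(names(exprB))))
    stop("exprA and exprB must be named over an identical gene universe")
  exprB <- exprB[names(exprA)]
  a <- exprA + pseudocount; b <- exprB + pseudocount
  list(aEnriched = names(exprA)[a > foldThreshold * b],
       bEnriched = names(exprA)[b > foldThreshold * a])
}

#' Build a signature matrix from specificity calls
#'
#' Restricts a reference to the genes called specific, giving the
#' entity x gene design matrix used by [estimateFractions()].
#'
#' @param reference a [ReferenceMatrix-class].
#' @param calls result of [callSpecificGenes()]; computed with defaults when
#'   missing.
#' @return An entity x gene matrix over the specific genes.
#' @export
signatureMatrix <- function(reference, calls = callSpecificGenes(reference)) {
  refValues(reference)[, calls$gene, drop = FALSE]
}
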