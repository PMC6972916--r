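#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Reports both the raw Mann-Whitney `U` of the first group and the signed
#' standardized statistic `z = (U - n1*n2/2) / sd` with the tie-corrected
#' variance and a 0.5 continuity correction (the standardized value is the
#' headline number; compartment-comparison figures in this field
#' conventionally print values on that scale, e.g. 3.22 or -3.40).
#' When both groups have at most `exactMax` observations the two-sided
#' p-value is computed by exact enumeration of all rank assignments
#' (conditional on the observed values, so ties are handled exactly):
#' `p = P(|W - E[W]| >= |w - E[W]|)` over all `choose(n1+n2, n1)` subsets.
#' Larger groups use the tie-corrected normal approximation.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param exactMax exact-enumeration path is used when
#'   `max(length(x), length(y)) <= exactMax` (default 8).
#' @return A list: `statistic` (signed standardized z), `U` (Mann-Whitney U
#'   of `x`), `pValue` (two-sided), `method` (`"exact"` or `"normal"`),
#'   `n1`, `n2`.
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))$pValue  # exact: 0.1
#' @export
rankSumTest <- function(x, y, exactMax = 8L) {
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  U <- w - n1 * (n1 + 1) / 2
  muU <- n1 * n2 / 2
  N <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 > 0) {
    cc <- min(abs(U - muU), 0.5)
    z <- sign(U - muU) * (abs(U - muU) - cc) / sqrt(sigma2)
  } else z <- 0
  if (max(n1, n2) <= exactMax) {
    muW <- n1 * (N + 1) / 2
    dev <- abs(w - muW)
    combs <- utils::combn(N, n1)
    sums <- colSums(matrix(r[combs], nrow = n1))
    p <- mean(abs(sums - muW) >= dev - 1e-9)
    method <- "exact"
  } else {
    p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(z)) else 1
    method <- "normal"
  }
  list(statistic = z, U = U, pValue = min(p, 1), method = method,
       n1 = n1, n2 = n2)
}

# Shared validation for paired-compartment inputs.
.checkPaired <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("compartment matrices must have identical dimensions")
  if (!identical(rownames(a), rownames(b)))
    stop("compartment matrices must share the same gene universe")
  if (!identical(colnames(a), colnames(b)))
    stop("compartment matrices must have matched subject columns")
  invisible(TRUE)
}

#' Per-gene average fold change between paired compartments
#'
#' For matched subjects measured in two compartments (for example cf-mRNA
#' vs whole blood), computes per subject the ratio
#' `(a + pc) / (b + pc)` and per gene the mean over subjects. Genes below
#' the detectability floor in every subject of both compartments are
#' excluded and listed.
#'
#' @param a,b gene x subject TPM matrices with identical gene and subject
#'   sets (`a` is the numerator compartment).
#' @param geneSet genes to evaluate (default: all shared genes).
#' @param detectabilityFloor TPM a gene must reach in at least one subject
#'   of either compartment to count as detectable (default 1).
#' @param pseudocount TPM added to both sides of each ratio (default 0.1).
#' @return A data.frame with `gene` and `foldChange` (mean over subjects);
#'   per-subject ratios as attribute `"perSubject"`, excluded genes as
#'   `"excluded"`.
#' @export
pairedFoldChange <- function(a, b, geneSet = rownames(a),
                             detectabilityFloor = 1, pseudocount = 0.1) {
  .checkPaired(a, b)
  geneSet <- intersect(geneSet, rownames(a))
  if (!length(geneSet)) stop("empty gene set")
  aS <- a[geneSet, , drop = FALSE]; bS <- b[geneSet, , drop = FALSE]
  detectable <- .rowMax(aS) >= detectabilityFloor |
                .rowMax(bS) >= detectabilityFloor
  excluded <- geneSet[!detectable]
  if (!any(detectable)) stop("no gene passes the detectability floor")
  aS <- aS[detectable, , drop = FALSE]; bS <- bS[detectable, , drop = FALSE]
  ratios <- (aS + pseudocount) / (bS + pseudocount)
  out <- data.frame(gene = rownames(aS), foldChange = rowMeans(ratios),
                    row.names = NULL)
  attr(out, "perSubject") <- ratios
  attr(out, "excluded") <- excluded
  out
}

#' Compare two gene populations by their compartment log-ratios
#'
#' Computes each gene's mean log-ratio between compartments across
#' subjects, then tests the ratios of `setA` against those of `setB` with
#' [rankSumTest()]. Marrow-specific and circulating-cell-specific gene sets
#' separate into two populations with opposite-signed ratios; the signed
#' standardized statistic captures that separation.
#'
#' @param a,b gene x subject TPM matrices (as in [pairedFoldChange()]).
#' @param setA,setB disjoint, non-empty gene sets.
#' @param pseudocount TPM added before taking ratios (default 0.1).
#' @return A list: `logRatios` (named per-gene mean log2 ratios over both
#'   sets), `test` (the [rankSumTest()] result of set A vs set B).
#' @export
twoPopulationSeparation <- function(a, b, setA, setB, pseudocount = 0.1) {
  if (!length(setA) || !length(setB)) stop("gene sets must be non-empty")
  if (length(intersect(setA, setB)))
    stop("gene sets must be disjoint")
  .checkPaired(a, b)
  genes <- c(setA, setB)
  missing <- setdiff(genes, rownames(a))
  if (length(missing))
    stop("gene(s) absent from matrices: ", paste(missing, collapse = ", "))
  lr <- rowMeans(log2((a[genes, , drop = FALSE] + pseudocount) /
                      (b[genes, , drop = FALSE] + pseudocount)))
  list(logRatios = lr,
       test = rankSumTest(lr[setA], lr[setB]))
}
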