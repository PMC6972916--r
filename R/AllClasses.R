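#' @import methods
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic cf-mRNA generators. One `SimulationConfig`
#' drives the whole synthetic family: a cell-type reference, TPM mixtures,
#' ablation/reconstitution time courses, immunoglobulin count tables and
#' SNP allele-count series. The single `seed` is expanded into per-operation
#' substreams so stages can be regenerated independently.
#'
#' @slot nGenes number of genes in the synthetic universe.
#' @slot nCelltypes number of cell types / tissues.
#' @slot markersPerType planted marker genes per cell type.
#' @slot markerFold fold-change of a marker in its own type over its maximum
#'   in every other type (unitless, must exceed 1).
#' @slot backgroundLevel baseline expression on the TPM scale from which
#'   non-marker values are drawn.
#' @slot logSigma standard deviation of the log-normal background on the
#'   natural-log scale.
#' @slot noiseModel one of `"none"`, `"multinomial"`, `"lognormal"`.
#' @slot readDepth total simulated reads per sample for count-level noise.
#' @slot seed integer random seed.
#' @slot timeGrid integer days relative to transplant day 0, strictly
#'   increasing.
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nGenes = "integer",
    nCelltypes = "integer",
    markersPerType = "integer",
    markerFold = "numeric",
    backgroundLevel = "numeric",
    logSigma = "numeric",
    noiseModel = "character",
    readDepth = "numeric",
    seed = "integer",
    timeGrid = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@nCelltypes < 2L) msg <- c(msg, "nCelltypes must be >= 2")
  if (object@markersPerType < 1L) msg <- c(msg, "markersPerType must be >= 1")
  if (object@markersPerType * object@nCelltypes > object@nGenes)
    msg <- c(msg, "markersPerType * nCelltypes exceeds nGenes")
  if (!is.finite(object@markerFold) || object@markerFold <= 1)
    msg <- c(msg, "markerFold must be > 1")
  if (object@backgroundLevel <= 0) msg <- c(msg, "backgroundLevel must be > 0")
  if (object@logSigma < 0) msg <- c(msg, "logSigma must be >= 0")
  if (!object@noiseModel %in% c("none", "multinomial", "lognormal"))
    msg <- c(msg, "noiseModel must be one of none/multinomial/lognormal")
  if (object@readDepth < 1) msg <- c(msg, "readDepth must be >= 1")
  if (length(object@timeGrid) && any(diff(object@timeGrid) <= 0L))
    msg <- c(msg, "timeGrid must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param nGenes,nCelltypes,markersPerType,markerFold,backgroundLevel,logSigma
#'   see the class slots.
#' @param noiseModel `"none"`, `"multinomial"` or `"lognormal"`.
#' @param readDepth total simulated reads per sample.
#' @param seed integer random seed.
#' @param timeGrid integer days relative to transplant (day 0).
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' simulationConfig(nGenes = 100, nCelltypes = 3, markersPerType = 5)
#' @export
simulationConfig <- function(nGenes = 1000L, nCelltypes = 6L,
                             markersPerType = 30L, markerFold = 50,
                             backgroundLevel = 10, logSigma = 0.5,
                             noiseModel = "none", readDepth = 1e6,
                             seed = 1L, timeGrid = integer()) {
  new("SimulationConfig",
    nGenes = as.integer(nGenes), nCelltypes = as.integer(nCelltypes),
    markersPerType = as.integer(markersPerType), markerFold = markerFold,
    backgroundLevel = backgroundLevel, logSigma = logSigma,
    noiseModel = noiseModel, readDepth = readDepth,
    seed = as.integer(seed), timeGrid = as.integer(timeGrid))
}

#' Reference expression matrix
#'
#' A tissue/cell-type-by-gene expression table (GTEx/Blueprint style,
#' TPM scale) used to derive cell-type-specific signatures and to annotate
#' deconvolution components. Rows are entities (tissues or cell types),
#' columns are genes.
#'
#' @slot values non-negative entity x gene matrix with unique dimnames.
#' @slot metadata list of free-form annotations (the synthetic generator
#'   stores its ground truth here).
#'
#' @exportClass ReferenceMatrix
setClass("ReferenceMatrix",
  representation(values = "matrix", metadata = "list")
)

setValidity("ReferenceMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry entity rownames and gene colnames")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "entity names must be unique")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "gene names must be unique")
  }
  if (any(v < 0)) msg <- c(msg, "expression values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a ReferenceMatrix
#'
#' @param values non-negative entity x gene matrix; rownames are
#'   tissue/cell-type names, colnames are gene identifiers.
#' @param metadata optional list of annotations.
#' @return A [ReferenceMatrix-class].
#' @export
ReferenceMatrix <- function(values, metadata = list()) {
  new("ReferenceMatrix", values = values, metadata = metadata)
}

#' Non-negative matrix factorization of a cf-mRNA profile set
#'
#' Result of decomposing a max-normalized gene x sample matrix into
#' non-negative `loadings` (gene x component) and `activities`
#' (component x sample), with optional per-component cell-type annotations.
#'
#' @slot loadings gene x component matrix, non-negative.
#' @slot activities component x sample matrix, non-negative.
#' @slot annotations character vector, one label per component
#'   (`"unannotated"` when no call was made).
#' @slot objective Frobenius objective value per iteration (monotone
#'   non-increasing).
#' @slot converged logical convergence flag.
#' @slot seed integer seed used for initialization fallback.
#'
#' @exportClass NmfDecomposition
setClass("NmfDecomposition",
  representation(
    loadings = "matrix", activities = "matrix",
    annotations = "character", objective = "numeric",
    converged = "logical", seed = "integer"
  )
)

setValidity("NmfDecomposition", function(object) {
  msg <- character()
  if (any(object@loadings < 0) || any(object@activities < 0))
    msg <- c(msg, "loadings and activities must be non-negative")
  if (ncol(object@loadings) != nrow(object@activities))
    msg <- c(msg, "loadings columns must match activities rows")
  if (length(object@annotations) &&
      length(object@annotations) != ncol(object@loadings))
    msg <- c(msg, "annotations must have one entry per component")
  if (length(msg)) msg else TRUE
})

#' Tissue-fraction estimates for a set of samples
#'
#' Per-sample non-negative proportions over reference entities, summing to 1,
#' as returned by [estimateFractions()] or [componentFractions()].
#'
#' @slot fractions entity x sample matrix of proportions.
#' @slot residualNorm per-sample residual norm of the least-squares fit
#'   (`NA` for fraction sets not produced by a fit).
#' @slot rankDeficient logical; `TRUE` when the signature matrix was
#'   numerically rank-deficient and the estimate is not unique.
#'
#' @exportClass FractionEstimate
setClass("FractionEstimate",
  representation(fractions = "matrix", residualNorm = "numeric",
                 rankDeficient = "logical")
)

setValidity("FractionEstimate", function(object) {
  f <- object@fractions
  msg <- character()
  if (any(f < -1e-12)) msg <- c(msg, "fractions must be non-negative")
  cs <- colSums(f)
  if (any(abs(cs - 1) > 1e-6))
    msg <- c(msg, "each sample's fractions must sum to 1 within 1e-6")
  if (length(object@residualNorm) != ncol(f))
    msg <- c(msg, "residualNorm must have one entry per sample")
  if (length(msg)) msg else TRUE
})

#' Immunoglobulin segment read-count table
#'
#' Read counts per Ig gene segment per sample/day, with each segment assigned
#' to one of the six Ig classes (heavy/kappa/lambda x variable/constant).
#'
#' @slot counts non-negative integer segment x sample matrix.
#' @slot segmentClass character vector, one class label per segment.
#' @slot days numeric day (relative to transplant) per sample column.
#' @slot metadata list; the synthetic generator stores ground truth here.
#'
#' @exportClass IgCountTable
setClass("IgCountTable",
  representation(counts = "matrix", segmentClass = "character",
                 days = "numeric", metadata = "list")
)

.IG_CLASSES <- c("heavy-variable", "heavy-constant", "kappa-variable",
                 "kappa-constant", "lambda-variable", "lambda-constant")

setValidity("IgCountTable", function(object) {
  msg <- character()
  cts <- object@counts
  if (any(cts < 0) || any(cts != round(cts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (is.null(rownames(cts))) msg <- c(msg, "counts must have segment rownames")
  if (length(object@segmentClass) != nrow(cts))
    msg <- c(msg, "segmentClass must have one entry per segment")
  if (!all(object@segmentClass %in% .IG_CLASSES))
    msg <- c(msg, "segmentClass entries must be one of the six Ig classes")
  if (length(object@days) != ncol(cts))
    msg <- c(msg, "days must have one entry per sample column")
  for (cl in unique(object@segmentClass)) {
    nm <- rownames(cts)[object@segmentClass == cl]
    if (anyDuplicated(nm))
      msg <- c(msg, sprintf("segment names must be unique within class %s", cl))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an IgCountTable
#'
#' @param counts non-negative integer segment x sample matrix with segment
#'   rownames.
#' @param segmentClass Ig class per segment; when `NULL` it is inferred from
#'   IMGT-style segment names (`IGHV...` is heavy-variable, `IGKC...`
#'   kappa-constant, and so on).
#' @param days day per sample column; defaults to column names parsed as
#'   numbers, else `seq_len(ncol(counts))`.
#' @param metadata optional list.
#' @return An [IgCountTable-class].
#' @export
IgCountTable <- function(counts, segmentClass = NULL, days = NULL,
                         metadata = list()) {
  storage.mode(counts) <- "double"
  if (is.null(segmentClass))
    segmentClass <- inferIgClass(rownames(counts))
  if (is.null(days)) {
    days <- suppressWarnings(as.numeric(colnames(counts)))
    if (anyNA(days)) days <- as.numeric(seq_len(ncol(counts)))
  }
  new("IgCountTable", counts = counts, segmentClass = segmentClass,
      days = days, metadata = metadata)
}

#' Infer Ig class from IMGT-style segment names
#'
#' @param segments character vector of segment names such as `"IGHV3-15"`,
#'   `"IGKC"`, `"IGLV1-40"`.
#' @return Character vector of class labels (heavy/kappa/lambda x
#'   variable/constant).
#' @export
inferIgClass <- function(segments) {
  chain <- substr(segments, 3, 3)
  kind <- substr(segments, 4, 4)
  chainLab <- c(H = "heavy", K = "kappa", L = "lambda")[chain]
  kindLab <- ifelse(kind == "V", "variable", "constant")
  bad <- is.na(chainLab) | substr(segments, 1, 2) != "IG"
  if (any(bad))
    stop("cannot infer Ig class for segment(s): ",
         paste(segments[bad], collapse = ", "))
  paste(chainLab, kindLab, sep = "-")
}

#' Expressed-SNP allele-count table
#'
#' Reference/alternative allele read counts per SNP per day, relative to a
#' transplant day, for chimerism monitoring.
#'
#' @slot ref non-negative integer SNP x day matrix of reference-allele reads.
#' @slot alt non-negative integer SNP x day matrix of alternative-allele
#'   reads (same dimnames as `ref`).
#' @slot days integer day per column.
#' @slot transplantDay integer, day of transplant (0 by convention).
#' @slot metadata list; the synthetic generator stores ground truth here.
#'
#' @exportClass SnpCountTable
setClass("SnpCountTable",
  representation(ref = "matrix", alt = "matrix", days = "integer",
                 transplantDay = "integer", metadata = "list")
)

setValidity("SnpCountTable", function(object) {
  msg <- character()
  if (!identical(dim(object@ref), dim(object@alt)))
    msg <- c(msg, "ref and alt matrices must have identical dimensions")
  if (any(object@ref < 0) || any(object@alt < 0))
    msg <- c(msg, "allele counts must be non-negative")
  if (any(object@ref != round(object@ref)) || any(object@alt != round(object@alt)))
    msg <- c(msg, "allele counts must be integers")
  if (length(object@days) != ncol(object@ref))
    msg <- c(msg, "days must have one entry per column")
  if (is.null(rownames(object@ref)))
    msg <- c(msg, "ref must carry SNP rownames")
  else if (anyDuplicated(rownames(object@ref)))
    msg <- c(msg, "SNP identifiers must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a SnpCountTable
#'
#' @param ref,alt SNP x day matrices of reference / alternative allele read
#'   counts with SNP rownames.
#' @param days integer day per column; defaults to column names parsed as
#'   integers.
#' @param transplantDay integer day of transplant (default 0).
#' @param metadata optional list.
#' @return A [SnpCountTable-class].
#' @export
SnpCountTable <- function(ref, alt, days = NULL, transplantDay = 0L,
                          metadata = list()) {
  storage.mode(ref) <- "double"
  storage.mode(alt) <- "double"
  if (is.null(days)) days <- as.integer(colnames(ref))
  new("SnpCountTable", ref = ref, alt = alt, days = as.integer(days),
      transplantDay = as.integer(transplantDay), metadata = metadata)
}
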