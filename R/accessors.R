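#' Accessors for cfmarrow classes
#'
#' Small accessor generics so slot layout stays private: `refValues` /
#' `entityNames` / `geneNames` for [ReferenceMatrix-class]; `loadings` /
#' `activities` / `annotations` for [NmfDecomposition-class]; `fractions` /
#' `residualNorm` for [FractionEstimate-class]; `igCounts` / `segmentClasses`
#' for [IgCountTable-class]; `refCounts` / `altCounts` for
#' [SnpCountTable-class]; `sampleDays` for both longitudinal tables.
#'
#' @param x an object of the matching class.
#' @return The requested component (matrix, character or numeric vector).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("refValues", function(x) standardGeneric("refValues"))
#' @rdname accessors
#' @export
setMethod("refValues", "ReferenceMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("entityNames", function(x) standardGeneric("entityNames"))
#' @rdname accessors
#' @export
setMethod("entityNames", "ReferenceMatrix", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))
#' @rdname accessors
#' @export
setMethod("geneNames", "ReferenceMatrix", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setGeneric("loadings", function(x) standardGeneric("loadings"))
#' @rdname accessors
#' @export
setMethod("loadings", "NmfDecomposition", function(x) x@loadings)

#' @rdname accessors
#' @export
setGeneric("activities", function(x) standardGeneric("activities"))
#' @rdname accessors
#' @export
setMethod("activities", "NmfDecomposition", function(x) x@activities)

#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname accessors
#' @export
setMethod("annotations", "NmfDecomposition", function(x) x@annotations)

#' Reconstruction error of an NMF decomposition
#'
#' Frobenius norm of `X - loadings %*% activities` at the final iteration
#' (the square root of the final objective value).
#'
#' @param x an [NmfDecomposition-class].
#' @return Numeric scalar.
#' @export
setGeneric("reconstructionError", function(x) standardGeneric("reconstructionError"))
#' @rdname reconstructionError
#' @export
setMethod("reconstructionError", "NmfDecomposition", function(x)
  sqrt(max(0, x@objective[length(x@objective)])))

#' @rdname accessors
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))
#' @rdname accessors
#' @export
setMethod("fractions", "FractionEstimate", function(x) x@fractions)

#' @rdname accessors
#' @export
setGeneric("residualNorm", function(x) standardGeneric("residualNorm"))
#' @rdname accessors
#' @export
setMethod("residualNorm", "FractionEstimate", function(x) x@residualNorm)

#' @rdname accessors
#' @export
setGeneric("igCounts", function(x) standardGeneric("igCounts"))
#' @rdname accessors
#' @export
setMethod("igCounts", "IgCountTable", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("segmentClasses", function(x) standardGeneric("segmentClasses"))
#' @rdname accessors
#' @export
setMethod("segmentClasses", "IgCountTable", function(x)
  stats::setNames(x@segmentClass, rownames(x@counts)))

#' @rdname accessors
#' @export
setGeneric("sampleDays", function(x) standardGeneric("sampleDays"))
#' @rdname accessors
#' @export
setMethod("sampleDays", "IgCountTable", function(x) x@days)
#' @rdname accessors
#' @export
setMethod("sampleDays", "SnpCountTable", function(x) x@days)

#' @rdname accessors
#' @export
setGeneric("refCounts", function(x) standardGeneric("refCounts"))
#' @rdname accessors
#' @export
setMethod("refCounts", "SnpCountTable", function(x) x@ref)

#' @rdname accessors
#' @export
setGeneric("altCounts", function(x) standardGeneric("altCounts"))
#' @rdname accessors
#' @export
setMethod("altCounts", "SnpCountTable", function(x) x@alt)

#' Ground truth attached to a synthetic object
#'
#' The synthetic generators record their ground truth (planted marker map,
#' true mixture proportions, lineage trajectories, clone fractions, mixing
#' fraction, genotypes) in the object's metadata under `"groundTruth"`.
#'
#' @param x a synthetic [ReferenceMatrix-class], [IgCountTable-class],
#'   [SnpCountTable-class] or `SummarizedExperiment`.
#' @return A named list, or `NULL` when no ground truth is attached.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname groundTruth
#' @export
setMethod("groundTruth", "ReferenceMatrix", function(x) x@metadata$groundTruth)
#' @rdname groundTruth
#' @export
setMethod("groundTruth", "IgCountTable", function(x) x@metadata$groundTruth)
#' @rdname groundTruth
#' @export
setMethod("groundTruth", "SnpCountTable", function(x) x@metadata$groundTruth)
#' @rdname groundTruth
#' @export
setMethod("groundTruth", "SummarizedExperiment", function(x)
  S4Vectors::metadata(x)$groundTruth)

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nGenes, "genes,",
      object@nCelltypes, "cell types,",
      object@markersPerType, "markers/type (fold", object@markerFold, ")\n")
  cat("  noise:", object@noiseModel, " depth:", object@readDepth,
      " seed:", object@seed, "\n")
  if (length(object@timeGrid))
    cat("  time grid: days", object@timeGrid[1], "..",
        object@timeGrid[length(object@timeGrid)],
        sprintf("(%d points)\n", length(object@timeGrid)))
})

setMethod("show", "ReferenceMatrix", function(object) {
  cat("ReferenceMatrix:", nrow(object@values), "entities x",
      ncol(object@values), "genes\n")
  cat("  entities:", paste(utils::head(rownames(object@values), 4),
                           collapse = ", "),
      if (nrow(object@values) > 4) "..." else "", "\n")
})

setMethod("show", "NmfDecomposition", function(object) {
  cat("NmfDecomposition:", nrow(object@loadings), "genes x",
      ncol(object@loadings), "components x", ncol(object@activities),
      "samples\n")
  cat("  reconstruction error:",
      format(reconstructionError(object), digits = 4),
      if (object@converged) "(converged)\n" else "(not converged)\n")
  if (length(object@annotations))
    cat("  annotations:", paste(object@annotations, collapse = ", "), "\n")
})

setMethod("show", "FractionEstimate", function(object) {
  cat("FractionEstimate:", nrow(object@fractions), "entities x",
      ncol(object@fractions), "samples\n")
  if (ncol(object@fractions) >= 1) {
    cat("  mean fractions:\n")
    print(round(rowMeans(object@fractions), 4))
  }
})

setMethod("show", "IgCountTable", function(object) {
  cat("IgCountTable:", nrow(object@counts), "segments x",
      ncol(object@counts), "samples;",
      length(unique(object@segmentClass)), "Ig classes\n")
})

setMethod("show", "SnpCountTable", function(object) {
  cat("SnpCountTable:", nrow(object@ref), "SNPs x", ncol(object@ref),
      "days (transplant day", object@transplantDay, ")\n")
})
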