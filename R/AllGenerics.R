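#' @importFrom BiocGenerics counts
NULL

#' Extract the count assay
#'
#' @param object an [AmpliconExperiment-class]
#' @return integer matrix, ASVs (rows) by samples (columns)
#' @export
setMethod("counts", "AmpliconExperiment", function(object) {
  assay(object, "counts")
})

#' Accessors for dissimilarity objects
#'
#' `dissMatrix` returns the symmetric sample-by-sample dissimilarity
#' matrix, `hillOrder` the diversity order q, `hillVariant` the overlap
#' variant used.
#'
#' @param x a [HillDissimilarity-class]
#' @return matrix, numeric, or character respectively
#' @export
setGeneric("dissMatrix", function(x) standardGeneric("dissMatrix"))

#' @rdname dissMatrix
#' @export
setGeneric("hillOrder", function(x) standardGeneric("hillOrder"))

#' @rdname dissMatrix
#' @export
setGeneric("hillVariant", function(x) standardGeneric("hillVariant"))

#' @rdname dissMatrix
#' @export
setMethod("dissMatrix", "HillDissimilarity", function(x) x@d)

#' @rdname dissMatrix
#' @export
setMethod("hillOrder", "HillDissimilarity", function(x) x@q)

#' @rdname dissMatrix
#' @export
setMethod("hillVariant", "HillDissimilarity", function(x) x@variant)

#' Accessors for correlation results
#'
#' @param x a [CorrelationResult-class]
#' @return `corMatrix`: the rho matrix; `corPvalues`: two-sided p-values;
#'   `corQvalues`: BH-adjusted values (spearman); `corSignificant`:
#'   logical matrix of significant pairs.
#' @export
setGeneric("corMatrix", function(x) standardGeneric("corMatrix"))

#' @rdname corMatrix
#' @export
setGeneric("corPvalues", function(x) standardGeneric("corPvalues"))

#' @rdname corMatrix
#' @export
setGeneric("corQvalues", function(x) standardGeneric("corQvalues"))

#' @rdname corMatrix
#' @export
setGeneric("corSignificant", function(x) standardGeneric("corSignificant"))

#' @rdname corMatrix
#' @export
setMethod("corMatrix", "CorrelationResult", function(x) x@rho)

#' @rdname corMatrix
#' @export
setMethod("corPvalues", "CorrelationResult", function(x) x@p)

#' @rdname corMatrix
#' @export
setMethod("corQvalues", "CorrelationResult", function(x) x@qvalues)

#' @rdname corMatrix
#' @export
setMethod("corSignificant", "CorrelationResult", function(x) x@significant)

#' Accessors for consensus networks
#'
#' @param x a [ConsensusNetwork-class]
#' @return `networkEdges`: edge data.frame; `networkNodes`: node labels;
#'   `modulePartition`: named integer node -> module; `modularityScore`:
#'   modularity Q.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname networkEdges
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname networkEdges
#' @export
setGeneric("modulePartition", function(x) standardGeneric("modulePartition"))

#' @rdname networkEdges
#' @export
setGeneric("modularityScore", function(x) standardGeneric("modularityScore"))

#' @rdname networkEdges
#' @export
setMethod("networkEdges", "ConsensusNetwork", function(x) x@edges)

#' @rdname networkEdges
#' @export
setMethod("networkNodes", "ConsensusNetwork", function(x) names(x@partition))

#' @rdname networkEdges
#' @export
setMethod("modulePartition", "ConsensusNetwork", function(x) x@partition)

#' @rdname networkEdges
#' @export
setMethod("modularityScore", "ConsensusNetwork", function(x) x@modularity)

#' Accessors for ordinations
#'
#' @param x an [Ordination-class]
#' @return `ordCoordinates`: samples-by-axes matrix; `ordProportions`:
#'   proportion of variation per axis; `ordEigenvalues`: all eigenvalues.
#' @export
setGeneric("ordCoordinates", function(x) standardGeneric("ordCoordinates"))

#' @rdname ordCoordinates
#' @export
setGeneric("ordProportions", function(x) standardGeneric("ordProportions"))

#' @rdname ordCoordinates
#' @export
setGeneric("ordEigenvalues", function(x) standardGeneric("ordEigenvalues"))

#' @rdname ordCoordinates
#' @export
setMethod("ordCoordinates", "Ordination", function(x) x@coordinates)

#' @rdname ordCoordinates
#' @export
setMethod("ordProportions", "Ordination", function(x) x@proportions)

#' @rdname ordCoordinates
#' @export
setMethod("ordEigenvalues", "Ordination", function(x) x@eigenvalues)

#' Ground truth of a synthetic dataset
#'
#' Returns the planted parameters stored by [simulateReactorSeries()]:
#' module membership per ASV, module kind (seasonal / trend / stable) and
#' phase, guild labels, and reactor affinity. `NULL` for real datasets.
#'
#' @param x an [AmpliconExperiment-class]
#' @return a list, or `NULL`
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "AmpliconExperiment", function(x) {
  S4Vectors::metadata(x)$ground_truth
})
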