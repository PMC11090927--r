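#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay 'assay<-' assays rowData colData
NULL

#' AmpliconExperiment: ASV count table with taxonomy and sample metadata
#'
#' An S4 container for an amplicon time series, extending
#' [SummarizedExperiment::SummarizedExperiment]. Rows are amplicon sequence
#' variants (ASVs), columns are samples. The `"counts"` assay holds
#' non-negative integer read counts; `rowData` carries the seven taxonomic
#' ranks (Kingdom..Species); `colData` carries per-sample covariates:
#' `reactor` (e.g. `"AGS1"`, `"AGS2"`, `"CAS"`), `date` (a `Date`), and
#' optionally `temperature` (degrees C).
#'
#' Synthetic datasets additionally carry the generator's ground truth in
#' `metadata(x)$ground_truth` (see [groundTruth()]).
#'
#' @seealso [AmpliconExperiment()] for construction,
#'   [readAmpliconTSV()] / [writeAmpliconTSV()] for I/O.
#' @name AmpliconExperiment-class
#' @exportClass AmpliconExperiment
setClass("AmpliconExperiment", contains = "SummarizedExperiment")

setValidity("AmpliconExperiment", function(object) {
  msg <- character()
  if (!("counts" %in% names(assays(object))))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- assay(object, "counts")
    if (any(is.na(m)) || any(m < 0))
      msg <- c(msg, "counts must be non-negative and non-missing")
    else if (any(abs(m - round(m)) > 1e-8))
      msg <- c(msg, "counts must be whole numbers")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "ASV identifiers (rownames) must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers (colnames) must be unique")
  cd <- colData(object)
  for (need in c("reactor", "date"))
    if (!(need %in% colnames(cd)))
      msg <- c(msg, sprintf("colData must contain a '%s' column", need))
  if (length(msg)) msg else TRUE
})

#' HillDissimilarity: pairwise Hill-framework sample dissimilarities
#'
#' Symmetric sample-by-sample matrix of Hill-number dissimilarities
#' \eqn{^q d \in [0, 1]} at diversity order `q`, with the overlap variant
#' used (`"local"` for \eqn{1 - C_{qN}}, `"regional"` for \eqn{1 - U_{qN}}).
#'
#' @slot d symmetric numeric matrix with zero diagonal, sample IDs as dimnames
#' @slot q diversity order (non-negative)
#' @slot variant `"local"` or `"regional"`
#' @name HillDissimilarity-class
#' @exportClass HillDissimilarity
setClass("HillDissimilarity",
         representation(d = "matrix", q = "numeric", variant = "character"))

setValidity("HillDissimilarity", function(object) {
  m <- object@d
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  else {
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
      msg <- c(msg, "matrix must be symmetric")
    if (any(abs(diag(m)) > 1e-9)) msg <- c(msg, "diagonal must be zero")
    if (any(m < -1e-9 | m > 1 + 1e-9)) msg <- c(msg, "entries must lie in [0, 1]")
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
      msg <- c(msg, "dimnames must be identical sample IDs")
  }
  if (length(object@q) != 1L || object@q < 0) msg <- c(msg, "q must be a single value >= 0")
  if (!object@variant %in% c("local", "regional"))
    msg <- c(msg, "variant must be 'local' or 'regional'")
  if (length(msg)) msg else TRUE
})

#' CorrelationResult: pairwise ASV correlations with significance
#'
#' Holds a symmetric correlation matrix `rho` (unit diagonal) between ASVs,
#' and significance information depending on the method: permutation
#' p-values for `"sparcc"` (filled by [permutationPvalues()]),
#' Benjamini-Hochberg adjusted q-values and a logical significance matrix
#' for `"spearman"`.
#'
#' @slot rho symmetric numeric matrix in \[-1, 1\], unit diagonal
#' @slot p two-sided p-values (empty matrix until computed)
#' @slot qvalues BH-adjusted p-values (spearman only; empty otherwise)
#' @slot significant logical matrix of BH-significant pairs (spearman only)
#' @slot method `"sparcc"` or `"spearman"`
#' @name CorrelationResult-class
#' @exportClass CorrelationResult
setClass("CorrelationResult",
         representation(rho = "matrix", p = "matrix", qvalues = "matrix",
                        significant = "matrix", method = "character"),
         prototype(p = matrix(numeric(), 0, 0),
                   qvalues = matrix(numeric(), 0, 0),
                   significant = matrix(logical(), 0, 0)))

setValidity("CorrelationResult", function(object) {
  msg <- character()
  r <- object@rho
  if (nrow(r) != ncol(r)) msg <- c(msg, "rho must be square")
  else {
    if (any(abs(diag(r) - 1) > 1e-8, na.rm = TRUE))
      msg <- c(msg, "rho diagonal must be 1")
    ok <- abs(r) <= 1 + 1e-8
    if (any(!ok, na.rm = TRUE)) msg <- c(msg, "rho entries must lie in [-1, 1]")
  }
  if (!object@method %in% c("sparcc", "spearman"))
    msg <- c(msg, "method must be 'sparcc' or 'spearman'")
  if (nrow(object@p) && !identical(dim(object@p), dim(r)))
    msg <- c(msg, "p must match rho dimensions")
  if (length(msg)) msg else TRUE
})

#' ConsensusNetwork: co-occurrence network with module partition
#'
#' Positive-edge consensus network over ASVs: an undirected edge list (with
#' both correlation coefficients and their significance), a module
#' partition from greedy modularity maximisation, and the modularity score
#' Q of that partition. Isolated ASVs are not nodes.
#'
#' @slot edges data.frame with columns `asv_a`, `asv_b` and edge statistics
#' @slot partition named integer vector, node -> module id
#' @slot modularity modularity Q of the partition
#' @name ConsensusNetwork-class
#' @exportClass ConsensusNetwork
setClass("ConsensusNetwork",
         representation(edges = "data.frame", partition = "integer",
                        modularity = "numeric"))

setValidity("ConsensusNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("asv_a", "asv_b") %in% colnames(e)))
    msg <- c(msg, "edges need 'asv_a' and 'asv_b' columns")
  else {
    if (any(e$asv_a == e$asv_b)) msg <- c(msg, "self-loops are not allowed")
    nodes <- unique(c(e$asv_a, e$asv_b))
    if (!all(nodes %in% names(object@partition)))
      msg <- c(msg, "every node must be assigned to a module")
  }
  if (length(msg)) msg else TRUE
})

#' Ordination: principal coordinate embedding of samples
#'
#' @slot coordinates samples-by-axes coordinate matrix
#' @slot proportions proportion of (positive-eigenvalue) variation per axis
#' @slot eigenvalues all eigenvalues of the double-centred matrix
#' @name Ordination-class
#' @exportClass Ordination
setClass("Ordination",
         representation(coordinates = "matrix", proportions = "numeric",
                        eigenvalues = "numeric"))

setMethod("show", "AmpliconExperiment", function(object) {
  callNextMethod()
  gt <- S4Vectors::metadata(object)$ground_truth
  if (!is.null(gt))
    cat("synthetic dataset with planted ground truth (see groundTruth())\n")
})

setMethod("show", "HillDissimilarity", function(object) {
  cat(sprintf("HillDissimilarity: %d samples, q = %g, variant = %s\n",
              nrow(object@d), object@q, object@variant))
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("CorrelationResult (%s): %d ASVs%s\n", object@method,
              nrow(object@rho),
              if (nrow(object@p)) ", p-values computed" else ""))
})

setMethod("show", "ConsensusNetwork", function(object) {
  cat(sprintf("ConsensusNetwork: %d nodes, %d edges, %d modules, Q = %.3f\n",
              length(object@partition), nrow(object@edges),
              length(unique(object@partition)), object@modularity))
})

setMethod("show", "Ordination", function(object) {
  cat(sprintf("Ordination: %d samples on %d axes (%s of variation)\n",
              nrow(object@coordinates), ncol(object@coordinates),
              paste(sprintf("%.1f%%", 100 * object@proportions), collapse = ", ")))
})
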