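#' Hill-number alpha diversity
#'
#' The Hill number of order q is the effective number of taxa,
#' \deqn{^qD = \left(\sum_i p_i^q\right)^{1/(1-q)}}{qD = (sum p_i^q)^(1/(1-q))}
#' with the q = 1 limit \eqn{^1D = \exp(-\sum_i p_i \ln p_i)} (the
#' exponential of Shannon entropy). q = 0 counts taxa irrespective of
#' abundance (richness); increasing q down-weights rare taxa. Zero
#' abundances are excluded from all sums.
#'
#' @param p relative-abundance vector summing to 1
#' @param q diversity order, a single non-negative number
#' @return effective number of taxa
#' @examples
#' hillAlpha(rep(0.25, 4), q = 0)   # 4
#' hillAlpha(c(0.9, 0.1), q = 1)    # exp(Shannon) = 1.38415
#' @export
hillAlpha <- function(p, q) {
  stopifnot(length(q) == 1L, q >= 0)
  if (any(p < 0)) stop("abundances must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("abundances must sum to 1")
  p <- p[p > 0]
  if (abs(q - 1) < 1e-12) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Pairwise Hill-framework dissimilarity
#'
#' Beta diversity between two communities in the multiplicative Hill
#' framework: \eqn{\beta = \gamma / \alpha \in [1, 2]}, where
#' \eqn{\gamma} is the Hill diversity of the pooled (equal-weight mean)
#' abundances and \eqn{\alpha} the equal-weight alpha diversity. Beta is
#' normalised onto \[0, 1\] through an overlap measure:
#' `"local"` uses the Sorensen-type overlap
#' \eqn{C_{q2} = [(1/\beta)^{q-1} - (1/2)^{q-1}] / [1 - (1/2)^{q-1}]},
#' `"regional"` the Jaccard-type \eqn{U_{q2}} with exponent \eqn{1-q};
#' the dissimilarity is \eqn{1 - C} (resp. \eqn{1 - U}). At q = 1 both
#' equal \eqn{\ln\beta / \ln 2}.
#'
#' @param p1,p2 relative-abundance vectors over a common taxon index
#' @param q diversity order
#' @param variant `"local"` (default) or `"regional"`
#' @return dissimilarity in \[0, 1\]; 0 for identical communities, 1 for
#'   disjoint ones
#' @examples
#' hillDissimilarity(c(1, 0), c(0.5, 0.5), q = 0)   # 1/3, Sorensen
#' @export
hillDissimilarity <- function(p1, p2, q, variant = c("local", "regional")) {
  variant <- match.arg(variant)
  if (length(p1) != length(p2)) stop("abundance vectors differ in length")
  for (p in list(p1, p2)) {
    if (any(p < 0)) stop("abundances must be non-negative")
    if (abs(sum(p) - 1) > 1e-6) stop("abundances must sum to 1")
  }
  gamma <- hillAlpha((p1 + p2) / 2, q)
  h <- c(p1[p1 > 0], p2[p2 > 0]) / 2
  alpha <- if (abs(q - 1) < 1e-12) {
    0.5 * exp(-sum(h * log(h)))
  } else {
    0.5 * sum(h^q)^(1 / (1 - q))
  }
  beta <- min(max(gamma / alpha, 1), 2)
  if (abs(q - 1) < 1e-12) return(log(beta) / log(2))
  expo <- switch(variant, local = q - 1, regional = 1 - q)
  overlap <- ((1 / beta)^expo - 0.5^expo) / (1 - 0.5^expo)
  min(max(1 - overlap, 0), 1)
}

#' Pairwise dissimilarity matrix over all samples
#'
#' @param x an [AmpliconExperiment-class] (relative abundances computed
#'   from counts) or an ASVs-x-samples matrix of relative abundances
#'   (columns summing to 1)
#' @param q diversity order (the study's orders are 0 and 1)
#' @param variant overlap variant, see [hillDissimilarity()]
#' @return a [HillDissimilarity-class]
#' @export
dissimilarityMatrix <- function(x, q = 1, variant = c("local", "regional")) {
  variant <- match.arg(variant)
  relab <- if (is(x, "AmpliconExperiment")) relativeAbundance(x) else as.matrix(x)
  if (ncol(relab) < 2) stop("at least two samples are required")
  if (any(abs(colSums(relab) - 1) > 1e-6))
    stop("columns must be relative abundances summing to 1")
  n <- ncol(relab)
  d <- matrix(0, n, n, dimnames = list(colnames(relab), colnames(relab)))
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      v <- hillDissimilarity(relab[, j], relab[, k], q = q, variant = variant)
      d[j, k] <- d[k, j] <- v
    }
  }
  new("HillDissimilarity", d = d, q = q, variant = variant)
}

#' Principal coordinate analysis (classical multidimensional scaling)
#'
#' Gower double-centering of \eqn{-\frac12 d^2} followed by
#' eigendecomposition; coordinates are taken from the top `k`
#' positive-eigenvalue axes and each axis's proportion of variation is its
#' eigenvalue over the sum of positive eigenvalues. Negative eigenvalues
#' (possible for non-Euclidean dissimilarities) are dropped and retained
#' in `ordEigenvalues` for inspection.
#'
#' @param d a [HillDissimilarity-class] or symmetric dissimilarity matrix
#' @param k number of axes requested; silently truncated (with a warning)
#'   if it exceeds the number of positive eigenvalues
#' @return an [Ordination-class]
#' @export
pcoaOrdination <- function(d, k = 2) {
  m <- if (is(d, "HillDissimilarity")) dissMatrix(d) else as.matrix(d)
  n <- nrow(m)
  A <- -0.5 * m^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- which(e$values > 1e-10)
  if (!length(pos)) {
    coords <- matrix(0, n, max(k, 1),
                     dimnames = list(rownames(m), paste0("Axis", seq_len(max(k, 1)))))
    return(new("Ordination", coordinates = coords,
               proportions = rep(0, ncol(coords)), eigenvalues = e$values))
  }
  if (k > length(pos)) {
    warning("only ", length(pos), " positive eigenvalue(s); truncating axes")
    k <- length(pos)
  }
  idx <- pos[seq_len(k)]
  coords <- e$vectors[, idx, drop = FALSE] %*%
    diag(sqrt(e$values[idx]), nrow = k)
  dimnames(coords) <- list(rownames(m), paste0("Axis", seq_len(k)))
  new("Ordination", coordinates = coords,
      proportions = e$values[idx] / sum(e$values[pos]),
      eigenvalues = e$values)
}
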