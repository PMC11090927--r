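#' Parameters for SparCC-type correlation inference
#'
#' Numeric conventions follow the original sparse compositional
#' correlation method and its fast reimplementations: Dirichlet
#' resampling of per-sample fractions, log-ratio variance system, and
#' iterative exclusion of the strongest correlated pairs from the
#' sparsity approximation.
#'
#' @param n_resamples Dirichlet resamples; the final rho is their
#'   element-wise median
#' @param exclusion_threshold |rho| above which the strongest pair is
#'   excluded from the linear system, one pair per round
#' @param max_exclusion_rounds cap on exclusion rounds per resample
#' @param pseudocount added to every count before forming fractions
#' @param seed optional integer fixing the resampling
#' @return a list of class `sparcc_params`
#' @export
sparccParams <- function(n_resamples = 50L, exclusion_threshold = 0.1,
                         max_exclusion_rounds = 10L, pseudocount = 1,
                         seed = NULL) {
  stopifnot(n_resamples >= 1, exclusion_threshold > 0, exclusion_threshold < 1,
            max_exclusion_rounds >= 0, pseudocount >= 0)
  structure(list(n_resamples = as.integer(n_resamples),
                 exclusion_threshold = exclusion_threshold,
                 max_exclusion_rounds = as.integer(max_exclusion_rounds),
                 pseudocount = pseudocount, seed = seed),
            class = "sparcc_params")
}

#' Log-ratio variation matrix
#'
#' \eqn{t_{ij} = \mathrm{Var}_k[\ln(f_{ik}/f_{jk})]}, the variance over
#' samples of the log-ratio of two taxa's fractions — the compositionally
#' invariant quantity at the heart of SparCC: rescaling all counts within
#' a sample leaves it unchanged.
#'
#' @param x counts (ASVs x samples) or a fractions matrix; with counts,
#'   fractions are formed as `(counts + pseudocount) / colsum`
#' @param pseudocount added before forming fractions (ignored if columns
#'   already sum to 1)
#' @return symmetric matrix with zero diagonal
#' @export
variationMatrix <- function(x, pseudocount = 1) {
  m <- .count_matrix(x)
  if (ncol(m) < 2) stop("at least two samples are required")
  f <- if (all(abs(colSums(m) - 1) < 1e-8)) m else {
    mm <- m + pseudocount
    if (any(mm <= 0))
      stop("non-positive fractions; a taxon with zero counts needs pseudocount > 0")
    sweep(mm, 2, colSums(mm), "/")
  }
  if (any(f <= 0)) stop("fractions must be strictly positive")
  L <- log(f)
  C <- stats::cov(t(L))
  v <- diag(C)
  t_mat <- outer(v, v, "+") - 2 * C
  t_mat <- (t_mat + t(t_mat)) / 2
  diag(t_mat) <- 0
  t_mat
}

# Solve the SparCC sparsity system for basis variances, with optional
# excluded pairs removed from both the right-hand side and the matrix.
.basis_solve <- function(t_mat, excluded = NULL, floor = 1e-10, warn = TRUE) {
  D <- nrow(t_mat)
  if (D <= 2) stop("basis variance system is singular for fewer than 3 taxa")
  M <- matrix(1, D, D) + diag(D - 2, D)
  b <- rowSums(t_mat)
  if (!is.null(excluded) && nrow(excluded)) {
    for (r in seq_len(nrow(excluded))) {
      i <- excluded[r, 1]; j <- excluded[r, 2]
      b[i] <- b[i] - t_mat[i, j]
      b[j] <- b[j] - t_mat[i, j]
      M[i, i] <- M[i, i] - 1
      M[j, j] <- M[j, j] - 1
      M[i, j] <- M[i, j] - 1
      M[j, i] <- M[j, i] - 1
    }
  }
  w <- solve(M, b)
  neg <- w < floor
  if (any(neg)) {
    if (warn) warning(sum(neg), " basis variance(s) clamped to ", floor)
    w[neg] <- floor
  }
  w
}

#' Basis variances from a variation matrix
#'
#' Under the SparCC sparsity approximation (most pairs uncorrelated),
#' \eqn{t_{ij} \approx \omega_i^2 + \omega_j^2}, so the row sums of t
#' satisfy the linear system \eqn{[(D-2) I + J]\, \omega^2 = t\,\mathbf 1}
#' with J the all-ones matrix. Negative solutions are clamped to a small
#' positive floor with a warning.
#'
#' @param t_mat symmetric variation matrix (see [variationMatrix()])
#' @param floor clamp value for non-positive solutions
#' @return vector of basis variances \eqn{\omega^2}
#' @examples
#' t3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3)
#' basisVariances(t3)   # 1 2 3
#' @export
basisVariances <- function(t_mat, floor = 1e-10) {
  t_mat <- as.matrix(t_mat)
  if (!isTRUE(all.equal(t_mat, t(t_mat), tolerance = 1e-8)))
    stop("variation matrix must be symmetric")
  .basis_solve(t_mat, floor = floor)
}

.rho_from_basis <- function(w, t_mat) {
  rho <- (outer(w, w, "+") - t_mat) / (2 * sqrt(outer(w, w)))
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  (rho + t(rho)) / 2
}

# One SparCC pass on a fractions matrix: variation matrix, then iterative
# exclusion of the single strongest above-threshold pair per round.
.sparcc_once <- function(f, exclusion_threshold = 0.1,
                         max_exclusion_rounds = 10L) {
  t_mat <- variationMatrix(f)
  D <- nrow(t_mat)
  excluded <- matrix(integer(), 0, 2)
  excl_mask <- matrix(FALSE, D, D)
  w <- .basis_solve(t_mat, warn = FALSE)
  rho <- .rho_from_basis(w, t_mat)
  for (round in seq_len(max_exclusion_rounds)) {
    cand <- abs(rho)
    diag(cand) <- 0
    cand[excl_mask] <- 0
    top <- max(cand)
    if (top <= exclusion_threshold) break
    idx <- which(cand == top, arr.ind = TRUE)
    # deterministic tie-break: smallest row, then column index
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    i <- min(idx); j <- max(idx)
    excluded <- rbind(excluded, c(i, j))
    excl_mask[i, j] <- excl_mask[j, i] <- TRUE
    w <- .basis_solve(t_mat, excluded = excluded, warn = FALSE)
    rho <- .rho_from_basis(w, t_mat)
  }
  rho
}

#' SparCC-type compositional correlations
#'
#' Estimates basis correlations between ASVs from compositional count
#' data. Per resample, each sample's fractions are drawn from
#' Dirichlet(counts + pseudocount); the log-ratio variation matrix is
#' reduced to basis variances under the sparsity approximation, the
#' strongest above-threshold pairs are iteratively excluded from the
#' linear system, and correlations are formed as
#' \eqn{\rho_{ij} = (\omega_i^2 + \omega_j^2 - t_{ij}) /
#' (2 \omega_i \omega_j)}, clipped to \[-1, 1\]. The final estimate is
#' the element-wise median over resamples.
#'
#' Apply [prevalenceFilter()] first; p-values come from
#' [permutationPvalues()].
#'
#' @param x counts (ASVs x samples) or [AmpliconExperiment-class]
#' @param params a [sparccParams()] list
#' @return a [CorrelationResult-class] with `method = "sparcc"` (p empty)
#' @export
sparccCorrelations <- function(x, params = sparccParams()) {
  m <- .count_matrix(x)
  if (nrow(m) < 4) stop("SparCC needs at least 4 taxa")
  if (!is.null(params$seed)) withr::local_seed(params$seed)
  D <- nrow(m)
  acc <- array(NA_real_, c(D, D, params$n_resamples))
  alpha <- m + params$pseudocount
  for (r in seq_len(params$n_resamples)) {
    g <- matrix(stats::rgamma(length(alpha), shape = alpha), nrow = D)
    f <- sweep(g, 2, colSums(g), "/")
    acc[, , r] <- .sparcc_once(f, params$exclusion_threshold,
                               params$max_exclusion_rounds)
  }
  rho <- apply(acc, c(1, 2), stats::median)
  dimnames(rho) <- list(rownames(m), rownames(m))
  diag(rho) <- 1
  new("CorrelationResult", rho = rho, method = "sparcc")
}

#' Permutation p-values for SparCC correlations
#'
#' Each permutation independently shuffles every ASV's counts across
#' samples, destroying co-occurrence while preserving each ASV's count
#' distribution, and recomputes the correlation matrix with a fast
#' single pass (point-estimate fractions, no resampling or exclusion).
#' The test statistic for the *observed* data is computed with the same
#' single pass, so observed and permuted values are exchangeable under
#' the null and the test is correctly calibrated; the resampled median
#' in `observed` remains the reported effect size. Two-sided p-values
#' use the add-one estimator
#' \eqn{p_{ij} = (\#\{|\rho^{perm}| \ge |\rho^{obs}|\} + 1) / (n_{perm} + 1)},
#' which is never exactly zero.
#'
#' @param x the same counts the observed result was computed from
#' @param observed a `"sparcc"` [CorrelationResult-class]
#' @param n_perm number of permutations
#' @param seed optional integer
#' @param pseudocount added before forming fractions
#' @return `observed` with its `p` slot filled
#' @export
permutationPvalues <- function(x, observed, n_perm = 1000L, seed = NULL,
                               pseudocount = 1) {
  m <- .count_matrix(x)
  if (n_perm < 1) stop("n_perm must be at least 1")
  stopifnot(is(observed, "CorrelationResult"),
            identical(rownames(corMatrix(observed)), rownames(m)))
  if (!is.null(seed)) withr::local_seed(seed)
  fast_rho <- function(cnt) {
    f <- sweep(cnt + pseudocount, 2, colSums(cnt + pseudocount), "/")
    t_mat <- variationMatrix(f)
    .rho_from_basis(.basis_solve(t_mat, warn = FALSE), t_mat)
  }
  obs <- abs(fast_rho(m))
  n <- ncol(m)
  ge <- matrix(0L, nrow(m), nrow(m))
  for (b in seq_len(n_perm)) {
    perm <- m
    for (i in seq_len(nrow(m))) perm[i, ] <- perm[i, sample.int(n)]
    ge <- ge + (abs(fast_rho(perm)) >= obs)
  }
  p <- (ge + 1) / (n_perm + 1)
  diag(p) <- 1
  dimnames(p) <- dimnames(obs)
  initialize(observed, p = p)
}

#' Spearman correlations with Benjamini-Hochberg FDR
#'
#' Pairwise Spearman rank correlations between ASVs across samples, with
#' two-sided p-values from the t approximation, adjusted over all
#' upper-triangle pairs by the Benjamini-Hochberg step-up procedure.
#' Pairs involving a constant ASV are undefined and reported as `NA`
#' (never significant).
#'
#' @param relab relative abundances (ASVs x samples) or
#'   [AmpliconExperiment-class]; ranks make the result identical for
#'   counts or fractions
#' @param fdr false discovery rate for the BH gate
#' @return a [CorrelationResult-class] with `method = "spearman"`,
#'   q-values and a logical `significant` matrix
#' @export
spearmanCorrelations <- function(relab, fdr = 0.05) {
  m <- if (is(relab, "AmpliconExperiment")) relativeAbundance(relab) else as.matrix(relab)
  n <- ncol(m)
  if (n < 3) stop("at least 3 samples are required")
  constant <- apply(m, 1, function(v) length(unique(v)) == 1)
  ranks <- t(apply(m, 1, rank))
  rho <- suppressWarnings(stats::cor(t(ranks)))
  rho[constant, ] <- NA
  rho[, constant] <- NA
  diag(rho) <- 1
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  p[is.na(rho)] <- NA
  diag(p) <- 1
  ut <- upper.tri(p)
  q <- matrix(NA_real_, nrow(p), ncol(p), dimnames = dimnames(rho))
  q[ut] <- stats::p.adjust(p[ut], method = "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  sig <- !is.na(q) & q <= fdr
  new("CorrelationResult", rho = rho, p = p, qvalues = q,
      significant = sig, method = "spearman")
}

#' Consensus positive edges from the two correlation methods
#'
#' An ASV pair becomes an edge only when both methods agree: the SparCC
#' permutation p-value is below `p_max`, the Spearman correlation is
#' BH-significant, and *both* coefficients exceed `rho_min`. Only
#' positive correlations qualify (the networks are networks of positive
#' co-occurrence).
#'
#' @param sparcc a `"sparcc"` [CorrelationResult-class] with p-values
#' @param spearman a `"spearman"` [CorrelationResult-class]
#' @param rho_min correlation threshold applied to both coefficients
#' @param p_max SparCC permutation p-value threshold
#' @return data.frame with columns `asv_a`, `asv_b`, `rho_sparcc`,
#'   `rho_spearman`, `p_sparcc`, `q_spearman`
#' @export
consensusEdges <- function(sparcc, spearman, rho_min = 0.5, p_max = 0.05) {
  stopifnot(is(sparcc, "CorrelationResult"), sparcc@method == "sparcc",
            is(spearman, "CorrelationResult"), spearman@method == "spearman")
  rs <- corMatrix(sparcc)
  rp <- corMatrix(spearman)
  if (!identical(rownames(rs), rownames(rp)))
    stop("ASV sets of the two correlation results differ")
  if (!nrow(corPvalues(sparcc)))
    stop("sparcc result has no p-values; run permutationPvalues() first")
  ps <- corPvalues(sparcc)
  sig <- corSignificant(spearman)
  ut <- which(upper.tri(rs), arr.ind = TRUE)
  keep <- !is.na(rs[ut]) & !is.na(rp[ut]) &
    ps[ut] < p_max & sig[ut] &
    rs[ut] > rho_min & rp[ut] > rho_min
  ut <- ut[keep, , drop = FALSE]
  data.frame(asv_a = rownames(rs)[ut[, 1]],
             asv_b = rownames(rs)[ut[, 2]],
             rho_sparcc = rs[ut],
             rho_spearman = rp[ut],
             p_sparcc = ps[ut],
             q_spearman = corQvalues(spearman)[ut])
}
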