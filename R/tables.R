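.count_matrix <- function(x) {
  if (is(x, "AmpliconExperiment")) counts(x) else as.matrix(x)
}

.rebuild <- function(x, m) {
  # carry an AmpliconExperiment's annotation through a row/value change
  keep <- intersect(rownames(m), rownames(x))
  ae <- x[keep, colnames(m)]
  assay(ae, "counts") <- m[keep, , drop = FALSE]
  validObject(ae)
  ae
}

#' Merge two pipeline count tables into a consensus table
#'
#' Two bioinformatic pipelines run on the same samples generally disagree
#' on marginal ASVs. The consensus table keeps exactly the ASVs present
#' (nonzero in at least one sample) in *both* inputs, matched by ASV
#' identifier, and reconciles each cell with a chosen strategy. Sample
#' order follows `a`.
#'
#' @param a,b count matrices (ASVs x samples) or
#'   [AmpliconExperiment-class] objects over the same sample set (any
#'   order).
#' @param strategy `"mean"` (default): rounded arithmetic mean of the two
#'   counts (round-half-to-even); `"min"`: element-wise minimum;
#'   `"first"`: counts taken from `a`.
#' @return same type as `a`
#' @examples
#' a <- matrix(c(10L, 4L), 1, 2, dimnames = list("ASV1", c("S1", "S2")))
#' b <- matrix(c(12L, 4L), 1, 2, dimnames = list("ASV1", c("S1", "S2")))
#' consensusMerge(a, b)   # 11, 4
#' @export
consensusMerge <- function(a, b, strategy = c("mean", "min", "first")) {
  strategy <- match.arg(strategy)
  ma <- .count_matrix(a)
  mb <- .count_matrix(b)
  if (!setequal(colnames(ma), colnames(mb)))
    stop("sample sets differ between the two tables")
  mb <- mb[, colnames(ma), drop = FALSE]
  present_a <- rownames(ma)[rowSums(ma) > 0]
  present_b <- rownames(mb)[rowSums(mb) > 0]
  shared <- intersect(present_a, present_b)
  ma <- ma[shared, , drop = FALSE]
  mb <- mb[shared, , drop = FALSE]
  out <- switch(strategy,
                mean = round((ma + mb) / 2),
                min = pmin(ma, mb),
                first = ma)
  storage.mode(out) <- "integer"
  if (is(a, "AmpliconExperiment")) .rebuild(a, out) else out
}

#' Rarefy samples to equal depth by subsampling without replacement
#'
#' Each sample's reads are subsampled without replacement (multivariate
#' hypergeometric) to a common depth, the standard normalisation before
#' diversity analysis of libraries with unequal sequencing depth. A sample
#' whose total already equals `depth` is returned unchanged.
#'
#' @param x count matrix (ASVs x samples) or [AmpliconExperiment-class]
#' @param depth target reads per sample; default the smallest sample total
#' @param seed optional integer; fixes the subsampling
#' @param drop_below if `TRUE`, samples with fewer than `depth` reads are
#'   dropped; if `FALSE` (default) they raise an error
#' @return same type as `x`, every sample summing exactly to `depth`
#' @export
rarefyCounts <- function(x, depth = NULL, seed = NULL, drop_below = FALSE) {
  m <- .count_matrix(x)
  tot <- colSums(m)
  if (is.null(depth)) depth <- min(tot)
  depth <- as.integer(depth)
  low <- colnames(m)[tot < depth]
  if (length(low)) {
    if (!drop_below)
      stop("depth ", depth, " exceeds total reads of sample(s): ",
           paste(low, collapse = ", "))
    m <- m[, setdiff(colnames(m), low), drop = FALSE]
    if (!ncol(m)) stop("no samples left after dropping those below depth")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  # vegan warns when all nonzero counts exceed 1 (a percent-data
  # heuristic); our inputs are genuine read counts, so silence it
  out <- t(suppressWarnings(vegan::rrarefy(t(m), depth)))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(m)
  if (is(x, "AmpliconExperiment")) .rebuild(x, out) else out
}

#' Relative abundances
#'
#' Divides each sample's counts by its total, so every sample (column)
#' sums to one.
#'
#' @param x count matrix (ASVs x samples) or [AmpliconExperiment-class]
#' @return numeric matrix of per-sample fractions, ASVs x samples
#' @export
relativeAbundance <- function(x) {
  m <- .count_matrix(x)
  tot <- colSums(m)
  zero <- colnames(m)[tot == 0]
  if (length(zero))
    stop("sample(s) with zero total counts: ", paste(zero, collapse = ", "))
  sweep(m, 2, tot, "/")
}

#' Prevalence and abundance filter for network analysis
#'
#' Keeps the ASVs with nonzero counts in at least `min_samples` samples
#' *and* a maximum per-sample relative abundance strictly exceeding
#' `min_max_relabund`. Samples are unchanged. The defaults correspond to
#' presence in at least two samples and a maximum relative abundance
#' above 0.05%.
#'
#' @param x count matrix (ASVs x samples) or [AmpliconExperiment-class]
#' @param min_samples minimum number of samples with nonzero counts
#' @param min_max_relabund relative-abundance threshold (strict)
#' @return same type as `x`, possibly with zero ASVs
#' @export
prevalenceFilter <- function(x, min_samples = 2L, min_max_relabund = 5e-4) {
  m <- .count_matrix(x)
  relab <- relativeAbundance(m)
  keep <- rowSums(m > 0) >= min_samples &
    apply(relab, 1, max) > min_max_relabund
  out <- m[keep, , drop = FALSE]
  if (is(x, "AmpliconExperiment")) x[rownames(out), ] else out
}

#' Aggregate counts to a taxonomic rank
#'
#' Sums counts over ASVs sharing a label at the requested rank. ASVs with
#' an empty or missing label are pooled into `"unclassified_<parent>"`
#' where `<parent>` is the nearest classified higher rank.
#'
#' @param x an [AmpliconExperiment-class] with taxonomy
#' @param rank one of Kingdom, Phylum, Class, Order, Family, Genus, Species
#' @return count matrix, rank labels x samples
#' @export
aggregateByRank <- function(x, rank = "Genus") {
  if (!rank %in% TAX_RANKS)
    stop("unknown rank '", rank, "'; valid ranks: ", paste(TAX_RANKS, collapse = ", "))
  tax <- taxonomyTable(x)
  if (!rank %in% colnames(tax)) stop("taxonomy lacks rank '", rank, "'")
  lab <- as.character(tax[[rank]])
  lab[is.na(lab)] <- ""
  need <- which(lab == "")
  if (length(need)) {
    above <- rev(TAX_RANKS[seq_len(match(rank, TAX_RANKS) - 1L)])
    for (i in need) {
      parent <- ""
      for (r in above) {
        v <- if (r %in% colnames(tax)) as.character(tax[i, r]) else ""
        if (!is.na(v) && nzchar(v)) { parent <- v; break }
      }
      lab[i] <- paste0("unclassified_", if (nzchar(parent)) parent else "root")
    }
  }
  m <- counts(x)
  out <- rowsum(m, group = lab, reorder = TRUE)
  storage.mode(out) <- "integer"
  out
}
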