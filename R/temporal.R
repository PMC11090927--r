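.temporal_meta <- function(meta) {
  if (is(meta, "AmpliconExperiment")) meta <- sampleMetadata(meta)
  meta <- as.data.frame(meta)
  stopifnot(all(c("sample", "reactor", "date") %in% colnames(meta)))
  meta$date <- as.Date(meta$date)
  meta
}

.reactor_samples <- function(d, meta, reactor) {
  meta <- .temporal_meta(meta)
  s <- meta[meta$reactor == reactor & meta$sample %in% rownames(dissMatrix(d)), ]
  if (!nrow(s)) stop("no samples found for reactor '", reactor, "'")
  s[order(s$date), ]
}

#' Rate of community change between consecutive samples
#'
#' For one reactor's date-ordered samples, each entry is the dissimilarity
#' between consecutive samples divided by the days separating them — the
#' per-day rate of succession.
#'
#' @param d a [HillDissimilarity-class] covering the reactor's samples
#' @param meta sample metadata ([sampleMetadata()] data.frame or the
#'   [AmpliconExperiment-class] itself)
#' @param reactor reactor label
#' @return data.frame with columns `sample_from`, `sample_to`,
#'   `midpoint_date`, `days`, `dissimilarity`, `rate` (per day); zero rows
#'   when the reactor has a single sample
#' @export
rateOfChange <- function(d, meta, reactor) {
  s <- .reactor_samples(d, meta, reactor)
  if (anyDuplicated(s$date))
    stop("duplicate sampling dates within reactor '", reactor, "'")
  n <- nrow(s)
  if (n < 2)
    return(data.frame(sample_from = character(), sample_to = character(),
                      midpoint_date = as.Date(character()), days = numeric(),
                      dissimilarity = numeric(), rate = numeric()))
  m <- dissMatrix(d)
  i <- seq_len(n - 1)
  days <- as.numeric(s$date[i + 1] - s$date[i])
  diss <- m[cbind(s$sample[i], s$sample[i + 1])]
  data.frame(sample_from = s$sample[i], sample_to = s$sample[i + 1],
             midpoint_date = s$date[i] + days / 2, days = days,
             dissimilarity = diss, rate = diss / days)
}

#' Time-gap dissimilarity curve (periodicity detection)
#'
#' All unordered within-reactor sample pairs are listed as (time gap in
#' days, dissimilarity), sorted by gap (ties broken by the earlier
#' first-sample date), and smoothed with a moving window of `window`
#' consecutive pairs advanced by `stride`. A peak in mean dissimilarity at
#' a gap near half the seasonal period indicates periodicity; see
#' [peakGap()].
#'
#' @inheritParams rateOfChange
#' @param window number of consecutive gap-sorted pairs per point
#' @param stride window advance (1 = maximally overlapping)
#' @return data.frame with one row per window: `mean_gap`,
#'   `mean_dissimilarity`, `sd_dissimilarity`, `n_pairs`; attributes
#'   `window`, `stride`, `q`, `pairs` (the raw sorted pair table)
#' @export
timeGapCurve <- function(d, meta, reactor, window = 10L, stride = 1L) {
  s <- .reactor_samples(d, meta, reactor)
  n <- nrow(s)
  if (n < 2) stop("need at least two samples for reactor '", reactor, "'")
  m <- dissMatrix(d)
  pr <- t(utils::combn(n, 2))
  pairs <- data.frame(
    first = s$sample[pr[, 1]], second = s$sample[pr[, 2]],
    first_date = s$date[pr[, 1]],
    gap = as.numeric(s$date[pr[, 2]] - s$date[pr[, 1]]),
    dissimilarity = m[cbind(s$sample[pr[, 1]], s$sample[pr[, 2]])])
  pairs <- pairs[order(pairs$gap, pairs$first_date), ]
  if (nrow(pairs) < window)
    stop("fewer pairs (", nrow(pairs), ") than the window size (", window, ")")
  starts <- seq(1L, nrow(pairs) - window + 1L, by = stride)
  curve <- do.call(rbind, lapply(starts, function(i) {
    w <- pairs[i:(i + window - 1L), ]
    data.frame(mean_gap = mean(w$gap),
               mean_dissimilarity = mean(w$dissimilarity),
               sd_dissimilarity = stats::sd(w$dissimilarity),
               n_pairs = window)
  }))
  structure(curve, window = window, stride = stride, q = hillOrder(d),
            pairs = pairs)
}

#' Gap at maximal mean dissimilarity of a time-gap curve
#'
#' @param curve result of [timeGapCurve()]
#' @return the `mean_gap` (days) of the window with the highest mean
#'   dissimilarity (first such window on ties)
#' @export
peakGap <- function(curve) {
  curve$mean_gap[which.max(curve$mean_dissimilarity)]
}

#' Same-day dissimilarity between two reactors
#'
#' Pairs the two reactors' samples by exact sampling date and summarises
#' the dissimilarities of the matched pairs.
#'
#' @inheritParams rateOfChange
#' @param reactorA,reactorB reactor labels
#' @return data.frame (one row): `mean`, `sd` (0 when n = 1), `n`
#' @export
sameDayDissimilarity <- function(d, meta, reactorA, reactorB) {
  meta <- .temporal_meta(meta)
  m <- dissMatrix(d)
  a <- meta[meta$reactor == reactorA & meta$sample %in% rownames(m), ]
  b <- meta[meta$reactor == reactorB & meta$sample %in% rownames(m), ]
  shared <- intersect(as.numeric(a$date), as.numeric(b$date))
  if (!length(shared))
    stop("no shared sampling dates between '", reactorA, "' and '", reactorB, "'")
  vals <- vapply(shared, function(day) {
    sa <- a$sample[match(day, as.numeric(a$date))]
    sb <- b$sample[match(day, as.numeric(b$date))]
    m[sa, sb]
  }, numeric(1))
  data.frame(mean = mean(vals),
             sd = if (length(vals) > 1) stats::sd(vals) else 0,
             n = length(vals))
}
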