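#' Default functional-guild map for wastewater microbiomes
#'
#' Genus-to-guild assignments for the functional groups that drive
#' nitrogen and phosphorus removal: ammonia oxidisers (AOB), nitrite
#' oxidisers (NOB), polyphosphate-accumulating organisms (PAO),
#' glycogen-accumulating organisms (GAO) and the bulking filament
#' *Microthrix*. Denitrifiers are deliberately not a guild: the trait is
#' spread over too many lineages to delimit by genus. Override or extend
#' by passing your own named vector wherever a guild map is accepted.
#'
#' @return named character vector, genus -> guild
#' @export
defaultGuildMap <- function() {
  c(Nitrosomonas = "AOB",
    Nitrospira = "NOB", Ca_Nitrotoga = "NOB",
    Tetrasphaera = "PAO", Ca_Accumulibacter = "PAO", Dechloromonas = "PAO",
    Ca_Competibacter = "GAO", Propionivibrio = "GAO",
    Microthrix = "filament")
}

#' Guild abundance trajectories
#'
#' Per sample, each guild's value is the summed relative abundance of
#' the ASVs whose genus maps to that guild; genera absent from the map
#' (and unclassified ASVs) are pooled under `"other"`.
#'
#' @param x an [AmpliconExperiment-class] with genus-level taxonomy
#' @param guild_map named character vector genus -> guild
#' @return matrix, guilds x samples (columns sum to 1)
#' @export
guildSeries <- function(x, guild_map = defaultGuildMap()) {
  if (!length(guild_map)) stop("guild map is empty")
  tax <- taxonomyTable(x)
  if (!"Genus" %in% colnames(tax)) stop("taxonomy lacks a Genus rank")
  relab <- relativeAbundance(x)
  genus <- as.character(tax$Genus)
  guild <- unname(guild_map[genus])
  guild[is.na(guild)] <- "other"
  levels <- c(sort(unique(unname(guild_map))), "other")
  sums <- rowsum(relab, group = factor(guild, levels = levels))
  out <- matrix(0, length(levels), ncol(relab),
                dimnames = list(levels, colnames(relab)))
  out[rownames(sums), ] <- sums  # guilds with no member ASVs stay at zero
  out
}

#' Spearman correlations with water temperature
#'
#' Correlates each series (row) with sample temperature, separately per
#' reactor. P-values are two-sided and reported unadjusted, as is usual
#' for small panels of pre-specified taxa; treat borderline values with
#' multiplicity in mind.
#'
#' @param series matrix with one row per taxon/guild/index and one column
#'   per sample (column names = sample IDs)
#' @param meta [sampleMetadata()] data.frame (or
#'   [AmpliconExperiment-class]) with a `temperature` column
#' @return data.frame: `series`, `reactor`, `n`, `rho`, `p`,
#'   `significant` (p < 0.05); constant series give `NA` rho/p
#' @export
temperatureCorrelations <- function(series, meta) {
  meta <- .temporal_meta(meta)
  if (!"temperature" %in% colnames(meta)) stop("metadata lacks temperature")
  series <- as.matrix(series)
  out <- list()
  for (rx in unique(meta$reactor)) {
    sel <- meta[meta$reactor == rx & meta$sample %in% colnames(series) &
                  !is.na(meta$temperature), ]
    if (nrow(sel) < 3) next
    for (nm in rownames(series)) {
      v <- series[nm, sel$sample]
      if (length(unique(v)) == 1) {
        out[[length(out) + 1]] <- data.frame(series = nm, reactor = rx,
                                             n = nrow(sel), rho = NA_real_,
                                             p = NA_real_, significant = NA)
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(v, sel$temperature, method = "spearman", exact = FALSE))
      out[[length(out) + 1]] <- data.frame(series = nm, reactor = rx,
                                           n = nrow(sel),
                                           rho = unname(ct$estimate),
                                           p = ct$p.value,
                                           significant = ct$p.value < 0.05)
    }
  }
  do.call(rbind, out)
}

# Exact two-sided signed-rank p-value by enumeration over sign
# assignments, conditioning on the observed (possibly tied, averaged)
# ranks. Unlike the normal approximation, this remains exact under ties.
.signed_rank_exact <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  if (!m) return(list(statistic = 0, p.value = 1))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  total <- 2^m
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  v_null <- as.matrix(signs) %*% r
  p_ge <- mean(v_null >= v_obs - 1e-9)
  p_le <- mean(v_null <= v_obs + 1e-9)
  list(statistic = v_obs, p.value = min(1, 2 * min(p_ge, p_le)))
}

#' Paired comparison of two reactors' series
#'
#' Matches the two series strictly by sampling date and tests the paired
#' differences. In `"auto"` mode a Shapiro-Wilk normality check on the
#' differences (alpha = 0.05) selects the paired t-test, falling back to
#' the Wilcoxon signed-rank test for non-normal differences. The
#' signed-rank p-value is exact (enumeration, tie-safe) for up to 12
#' non-zero differences, and the normal approximation beyond.
#'
#' @param x,y numeric series named by sampling date (anything
#'   `as.Date()` accepts)
#' @param method `"auto"`, `"t"` or `"wilcoxon"`
#' @return list with `statistic`, `p.value`, `n` (matched pairs),
#'   `method` (`"paired-t"` or `"wilcoxon-signed-rank"`)
#' @export
pairedReactorTest <- function(x, y, method = c("auto", "t", "wilcoxon")) {
  method <- match.arg(method)
  if (is.null(names(x)) || is.null(names(y)))
    stop("series must be named by sampling date")
  shared <- intersect(names(x), names(y))
  if (!length(shared)) stop("no matched sampling dates between the series")
  if (length(shared) < 2) stop("need at least 2 matched pairs")
  d <- as.numeric(x[shared]) - as.numeric(y[shared])
  n <- length(d)
  if (method == "auto") {
    method <- if (stats::sd(d) == 0) {
      if (all(d == 0)) "t" else "wilcoxon"
    } else if (stats::shapiro.test(d)$p.value < 0.05) "wilcoxon" else "t"
  }
  if (method == "t") {
    if (stats::sd(d) == 0 && all(d == 0))
      return(list(statistic = 0, p.value = 1, n = n, method = "paired-t"))
    tt <- stats::t.test(d)
    return(list(statistic = unname(tt$statistic), p.value = tt$p.value,
                n = n, method = "paired-t"))
  }
  nz <- sum(d != 0)
  if (nz <= 12) {
    ex <- .signed_rank_exact(d)
    list(statistic = ex$statistic, p.value = ex$p.value, n = n,
         method = "wilcoxon-signed-rank")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE))
    list(statistic = unname(wt$statistic), p.value = wt$p.value, n = n,
         method = "wilcoxon-signed-rank")
  }
}

#' Guild-by-module contingency table
#'
#' Cross-tabulates the guild-member ASVs of a taxonomy against the
#' detected network modules; guild ASVs that are not network nodes
#' (isolated or filtered out) appear in the `"unassigned"` column.
#' Guild members spread over several modules indicate functional
#' redundancy: sub-populations of the same guild following different
#' temporal dynamics.
#'
#' @param net a [ConsensusNetwork-class]
#' @param tax taxonomy data.frame (rownames = ASV ids, `Genus` column) or
#'   an [AmpliconExperiment-class]
#' @param guild_map named character vector genus -> guild
#' @return integer matrix, guilds x (modules, "unassigned")
#' @export
guildModuleCrosstab <- function(net, tax, guild_map = defaultGuildMap()) {
  if (is(tax, "AmpliconExperiment")) tax <- taxonomyTable(tax)
  genus <- as.character(tax$Genus)
  guild <- unname(guild_map[genus])
  members <- rownames(tax)[!is.na(guild)]
  guild <- guild[!is.na(guild)]
  part <- modulePartition(net)
  mods <- sort(unique(part))
  module_of <- ifelse(members %in% names(part),
                      paste0("M", part[members]), "unassigned")
  tab <- table(factor(guild, levels = sort(unique(unname(guild_map)))),
               factor(module_of, levels = c(paste0("M", mods), "unassigned")))
  out <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  out
}
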