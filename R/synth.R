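#' Configuration for the synthetic parallel-reactor generator
#'
#' Defines the study conditions the generator emulates: three parallel
#' reactors (two near-identical granular-sludge twins and one divergent
#' floc-based system) sampled monthly for 19 months, several hundred
#' ASVs organised into co-varying modules that are seasonal (annual
#' sinusoid), trending (monotone drift) or stable, a fraction of
#' reactor-specific taxa, sequencing depths spanning the tens of
#' thousands to about 1.5 million reads, and guild-labelled genera for
#' the functional-group analyses.
#'
#' @param n_reactors number of reactors; with 3 (default) the labels are
#'   AGS1, AGS2 (twins) and CAS (divergent), otherwise R1..Rn with the
#'   last reactor divergent
#' @param n_timepoints monthly sampling occasions
#' @param n_asvs total ASVs
#' @param n_modules planted co-occurrence modules; kinds cycle through
#'   seasonal, seasonal, trend-up, trend-down, stable, stable
#' @param period_days seasonal period
#' @param seasonal_amplitude log-scale amplitude of the seasonal sinusoid
#'   for ASVs in seasonal modules
#' @param trend_slope log-scale drift per year for ASVs in trend modules
#' @param reactor_specific_fraction proportion of ASVs confined to one
#'   reactor (near-zero elsewhere)
#' @param depth_range min/max reads per sample (drawn uniformly)
#' @param guild_spec named list: guild -> named integer vector of ASVs
#'   per genus; `NULL` for the built-in wastewater genera
#' @param divergent_shift_sd log-scale sd of the divergent reactor's
#'   per-ASV baseline offset (drives the AGS-vs-CAS separation)
#' @param module_noise_sd sd of the shared module-level temporal noise
#'   (creates within-module correlation)
#' @param asv_noise_sd sd of the reactor-specific per-ASV temporal noise
#' @param turnover per-reactor multiplier on the idiosyncratic temporal
#'   noise; the divergent reactor defaults to 1.5 (flocs turn over faster
#'   than granules), twins to 1
#' @param env_coupling per-reactor multiplier on the shared temporal
#'   drivers (seasonal amplitude and module noise); the divergent reactor
#'   defaults to 1.6: flocculent sludge co-varies with environmental
#'   fluctuations more strongly than granules
#' @param dropout_prob default ASV dropout probability for
#'   [simulatePipelineVariants()]
#' @param start_date first sampling date
#' @param seed integer; fixes every draw bit-for-bit
#' @return a list of class `reactor_sim_config`
#' @export
reactorSimConfig <- function(n_reactors = 3L, n_timepoints = 19L,
                             n_asvs = 800L, n_modules = 6L,
                             period_days = 365, seasonal_amplitude = 1.2,
                             trend_slope = 0.15,
                             reactor_specific_fraction = 0.15,
                             depth_range = c(41776L, 1485104L),
                             guild_spec = NULL,
                             divergent_shift_sd = 1.5,
                             module_noise_sd = 0.35,
                             asv_noise_sd = 0.35,
                             turnover = NULL,
                             env_coupling = NULL,
                             dropout_prob = 0.1,
                             start_date = as.Date("2020-06-15"),
                             seed = 1L) {
  stopifnot(n_reactors >= 1, n_timepoints >= 2, n_asvs >= 10, n_modules >= 1,
            period_days > 0, seasonal_amplitude >= 0,
            reactor_specific_fraction >= 0, reactor_specific_fraction <= 1,
            dropout_prob >= 0, dropout_prob <= 1,
            length(depth_range) == 2, depth_range[1] >= 1,
            depth_range[1] <= depth_range[2])
  reactors <- if (n_reactors == 3) c("AGS1", "AGS2", "CAS")
              else paste0("R", seq_len(n_reactors))
  divergent <- reactors[length(reactors)]
  if (is.null(turnover)) {
    turnover <- stats::setNames(rep(1, n_reactors), reactors)
    turnover[divergent] <- 1.5
  }
  if (is.null(env_coupling)) {
    env_coupling <- stats::setNames(rep(1, n_reactors), reactors)
    env_coupling[divergent] <- 1.6
  }
  if (is.null(guild_spec)) {
    guild_spec <- list(
      AOB = c(Nitrosomonas = 3L),
      NOB = c(Nitrospira = 3L, Ca_Nitrotoga = 2L),
      PAO = c(Tetrasphaera = 4L, Ca_Accumulibacter = 4L, Dechloromonas = 4L),
      GAO = c(Ca_Competibacter = 3L, Propionivibrio = 2L),
      filament = c(Microthrix = 2L))
  }
  structure(list(n_reactors = as.integer(n_reactors), reactors = reactors,
                 divergent = divergent,
                 n_timepoints = as.integer(n_timepoints),
                 n_asvs = as.integer(n_asvs), n_modules = as.integer(n_modules),
                 period_days = period_days,
                 seasonal_amplitude = seasonal_amplitude,
                 trend_slope = trend_slope,
                 reactor_specific_fraction = reactor_specific_fraction,
                 depth_range = as.integer(depth_range),
                 guild_spec = guild_spec,
                 divergent_shift_sd = divergent_shift_sd,
                 module_noise_sd = module_noise_sd,
                 asv_noise_sd = asv_noise_sd, turnover = turnover,
                 env_coupling = env_coupling,
                 dropout_prob = dropout_prob,
                 start_date = as.Date(start_date), seed = as.integer(seed)),
            class = "reactor_sim_config")
}

.synth_taxonomy <- function(asv_ids, guild_genus, n_modules) {
  n <- length(asv_ids)
  phyla <- c("Proteobacteria", "Bacteroidota", "Actinobacteriota",
             "Chloroflexi", "Planctomycetota", "Acidobacteriota",
             "Myxococcota", "Verrucomicrobiota")
  phylum <- sample(phyla, n, replace = TRUE)
  class_ <- paste0(substr(phylum, 1, 5), "_class_", sample(1:3, n, TRUE))
  order_ <- paste0("Order_", sample(1:40, n, TRUE))
  family <- paste0("Family_", sample(1:120, n, TRUE))
  genus <- paste0("Genus_", sample(1:300, n, TRUE))
  # ~8% of ASVs unclassified at genus level
  genus[stats::runif(n) < 0.08] <- ""
  known <- !is.na(guild_genus)
  genus[known] <- guild_genus[known]
  data.frame(Kingdom = "Bacteria", Phylum = phylum, Class = class_,
             Order = order_, Family = family, Genus = genus,
             Species = "", row.names = asv_ids, stringsAsFactors = FALSE)
}

#' Simulate a parallel-reactor amplicon time series
#'
#' Generates counts from a latent log-abundance model. For reactor r,
#' ASV i of module m at sampling day t:
#' \deqn{\eta = b_i + s_{ri} + \beta_i t/365 +
#'   A_i \sin(2\pi (t - \phi_m)/P) + u_{mt} + \tau_r \nu_{rit}}
#' with baseline \eqn{b_i \sim N(0, 1.8)}, a divergent-reactor offset
#' \eqn{s_{ri}} (sd `divergent_shift_sd`; reactor-specific ASVs get
#' \eqn{s = -10} outside their home reactor), module kind deciding trend
#' \eqn{\beta_i} and seasonal amplitude \eqn{A_i}, module-shared noise
#' \eqn{u_{mt}} (within-module positive correlation) and independent
#' noise \eqn{\nu} scaled by the reactor's turnover; the shared drivers
#' (seasonal term and module noise) are scaled by the reactor's
#' environmental coupling. Fractions are the
#' per-sample softmax of \eqn{\eta}; counts are multinomial at a depth
#' drawn uniformly from `depth_range`, so each sample's total equals its
#' drawn depth exactly. Water temperature is a seasonal sinusoid
#' (8-20 degrees C) with small noise.
#'
#' The planted structure (module membership and kind, phases, guild
#' labels, reactor affinity, per-sample depths) is stored as ground
#' truth for recovery tests; see [groundTruth()].
#'
#' @param config a [reactorSimConfig()]
#' @return an [AmpliconExperiment-class] with `counts`, taxonomy,
#'   metadata (`reactor`, `date`, `temperature`) and ground truth
#' @export
simulateReactorSeries <- function(config = reactorSimConfig()) {
  stopifnot(inherits(config, "reactor_sim_config"))
  withr::local_seed(config$seed)
  nA <- config$n_asvs; nT <- config$n_timepoints; nR <- config$n_reactors
  nM <- config$n_modules
  asv_ids <- sprintf("ASV%04d", seq_len(nA))
  dates <- seq(config$start_date, by = "month", length.out = nT)
  days <- as.numeric(dates - dates[1])

  kinds_cycle <- c("seasonal", "seasonal", "trend_up", "trend_down",
                   "stable", "stable")
  module_kind <- kinds_cycle[((seq_len(nM) - 1) %% length(kinds_cycle)) + 1]
  phase <- round(stats::runif(nM, 0, config$period_days))
  phase[module_kind != "seasonal"] <- 0

  # guild ASVs first (cycled over modules so each guild spans several),
  # remaining ASVs assigned to modules uniformly
  guild_genus <- rep(NA_character_, nA)
  guild_of <- rep(NA_character_, nA)
  k <- 0L
  for (g in names(config$guild_spec)) {
    for (gen in names(config$guild_spec[[g]])) {
      cnt <- config$guild_spec[[g]][[gen]]
      idx <- k + seq_len(cnt)
      guild_genus[idx] <- gen
      guild_of[idx] <- g
      k <- k + cnt
    }
  }
  if (k > nA) stop("guild_spec requests more ASVs than n_asvs")
  module_of <- integer(nA)
  module_of[seq_len(k)] <- ((seq_len(k) - 1) %% nM) + 1
  module_of[(k + 1):nA] <- sample.int(nM, nA - k, replace = TRUE)

  baseline <- stats::rnorm(nA, 0, 1.8)
  amp <- ifelse(module_kind[module_of] == "seasonal", config$seasonal_amplitude, 0)
  slope <- ifelse(module_kind[module_of] == "trend_up", config$trend_slope,
                  ifelse(module_kind[module_of] == "trend_down",
                         -config$trend_slope, 0))

  n_spec <- round(config$reactor_specific_fraction * nA)
  specific <- sample.int(nA, n_spec)
  home <- stats::setNames(rep(NA_character_, nA), asv_ids)
  home[specific] <- sample(config$reactors, n_spec, replace = TRUE)

  # divergent reactor's persistent compositional shift
  shift <- matrix(0, nA, nR, dimnames = list(asv_ids, config$reactors))
  shift[, config$divergent] <- stats::rnorm(nA, 0, config$divergent_shift_sd)
  for (i in specific)
    shift[i, setdiff(config$reactors, home[asv_ids[i]])] <- -10

  u_mod <- matrix(stats::rnorm(nM * nT, 0, config$module_noise_sd), nM, nT)
  seasonal <- t(vapply(seq_len(nA), function(i) {
    amp[i] * sin(2 * pi * (days - phase[module_of[i]]) / config$period_days)
  }, numeric(nT)))
  trend <- outer(slope, days / 365)

  doy <- as.integer(format(dates, "%j"))
  temperature <- 14 + 6 * sin(2 * pi * (doy - 110) / 365) +
    stats::rnorm(nT, 0, 0.3)

  counts_list <- list()
  meta_list <- list()
  latent <- array(NA_real_, c(nA, nT, nR),
                  dimnames = list(asv_ids, NULL, config$reactors))
  for (r in seq_len(nR)) {
    rx <- config$reactors[r]
    eta <- baseline + shift[, r] + trend +
      config$env_coupling[rx] * (seasonal + u_mod[module_of, , drop = FALSE]) +
      config$turnover[rx] *
        matrix(stats::rnorm(nA * nT, 0, config$asv_noise_sd), nA, nT)
    latent[, , r] <- eta
    frac <- apply(eta, 2, function(col) { e <- exp(col - max(col)); e / sum(e) })
    depth <- config$depth_range[1] - 1L +
      sample.int(config$depth_range[2] - config$depth_range[1] + 1L, nT,
                 replace = TRUE)
    cnt <- vapply(seq_len(nT), function(t)
      as.integer(stats::rmultinom(1, depth[t], frac[, t])), integer(nA))
    rownames(cnt) <- asv_ids
    colnames(cnt) <- sprintf("%s_T%02d", rx, seq_len(nT))
    counts_list[[rx]] <- cnt
    meta_list[[rx]] <- data.frame(sample_id = colnames(cnt), reactor = rx,
                                  date = dates, temperature = temperature,
                                  depth = depth, row.names = colnames(cnt))
  }
  counts <- do.call(cbind, counts_list)
  meta <- do.call(rbind, meta_list)
  rownames(meta) <- meta$sample_id

  tax <- .synth_taxonomy(asv_ids, guild_genus, nM)
  gt <- list(
    module_of_asv = stats::setNames(module_of, asv_ids),
    module_kind = stats::setNames(module_kind, paste0("module", seq_len(nM))),
    phase_of_module = stats::setNames(phase, paste0("module", seq_len(nM))),
    guild_of_asv = stats::setNames(guild_of, asv_ids)[!is.na(guild_of)],
    reactor_affinity = home[!is.na(home)],
    depths = stats::setNames(meta$depth, meta$sample_id),
    latent = latent,
    config = config)
  AmpliconExperiment(counts, taxonomy = tax, metadata = meta,
                     ground_truth = gt)
}

#' Simulate two bioinformatic pipeline variants of a count table
#'
#' Emulates two independent read-processing pipelines applied to the same
#' sequencing run: each variant independently loses each ASV with
#' probability `dropout_prob` (counts set to zero; identifiers are
#' preserved), and retained counts are multiplied by lognormal noise of
#' log-sd `noise_sd` and rounded. Feed the two variants to
#' [consensusMerge()].
#'
#' @param x counts (ASVs x samples) or [AmpliconExperiment-class]
#' @param dropout_prob per-ASV dropout probability in \[0, 1\]
#' @param noise_sd log-scale sd of the multiplicative count noise
#' @param seed optional integer
#' @return list of two count matrices (`variant_a`, `variant_b`)
#' @export
simulatePipelineVariants <- function(x, dropout_prob = 0.1, noise_sd = 0.1,
                                     seed = NULL) {
  m <- .count_matrix(x)
  if (!nrow(m) || !ncol(m)) stop("count table is empty")
  if (dropout_prob < 0 || dropout_prob > 1)
    stop("dropout_prob must lie in [0, 1]")
  stopifnot(noise_sd >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  perturb <- function() {
    out <- m
    drop <- stats::runif(nrow(m)) < dropout_prob
    out[drop, ] <- 0L
    if (noise_sd > 0) {
      keep <- which(!drop)
      noise <- matrix(stats::rlnorm(length(keep) * ncol(m), 0, noise_sd),
                      length(keep), ncol(m))
      out[keep, ] <- round(m[keep, , drop = FALSE] * noise)
    }
    storage.mode(out) <- "integer"
    out
  }
  list(variant_a = perturb(), variant_b = perturb())
}
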