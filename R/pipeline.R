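#' Configuration for the end-to-end pipeline
#'
#' Bundles every stage's parameters with one master seed; stage seeds are
#' derived from it so reruns are byte-identical.
#'
#' @param sim a [reactorSimConfig()] for synthetic input, or `NULL` when
#'   reading files
#' @param input named list of file paths (`counts`, and optionally
#'   `counts_b` for a second pipeline's table to consensus-merge,
#'   `taxonomy`, `metadata`); ignored when `sim` is given
#' @param out_dir output directory for TSV/JSON artifacts
#' @param q_orders Hill orders for alpha diversity
#' @param q_network Hill order for the dissimilarity-based stages
#' @param rarefy_depth `"min"` (smallest sample total) or a fixed count
#' @param min_samples,min_max_relabund prevalence filter, see
#'   [prevalenceFilter()]
#' @param sparcc a [sparccParams()] list
#' @param n_perm SparCC permutation count
#' @param rho_min,p_max,fdr consensus-edge thresholds, see
#'   [consensusEdges()] and [spearmanCorrelations()]
#' @param window,stride time-gap curve smoothing, see [timeGapCurve()]
#' @param network_top_n per-reactor cap on ASVs entering correlation
#'   inference (most-abundant kept); `Inf` disables
#' @param guild_map named genus -> guild vector
#' @param seed master seed
#' @return a list of class `pipeline_config`
#' @export
pipelineConfig <- function(sim = reactorSimConfig(), input = NULL,
                           out_dir = tempfile("granulaR_run_"),
                           q_orders = c(0, 1), q_network = 1,
                           rarefy_depth = "min",
                           min_samples = 2L, min_max_relabund = 5e-4,
                           sparcc = sparccParams(), n_perm = 1000L,
                           rho_min = 0.5, p_max = 0.05, fdr = 0.05,
                           window = 10L, stride = 1L,
                           network_top_n = 300L,
                           guild_map = defaultGuildMap(), seed = 1L) {
  structure(list(sim = sim, input = input, out_dir = out_dir,
                 q_orders = q_orders, q_network = q_network,
                 rarefy_depth = rarefy_depth, min_samples = min_samples,
                 min_max_relabund = min_max_relabund, sparcc = sparcc,
                 n_perm = as.integer(n_perm), rho_min = rho_min,
                 p_max = p_max, fdr = fdr, window = as.integer(window),
                 stride = as.integer(stride), network_top_n = network_top_n,
                 guild_map = guild_map, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, optional consensus merge, rarefaction to the
#' minimum depth, prevalence filtering, alpha diversity and PCoA,
#' per-reactor succession statistics (rate of change, time-gap curve,
#' same-day comparisons), per-reactor consensus networks with module
#' detection and major-module trajectories, and guild summaries with
#' temperature correlations. Every table is written as TSV under
#' `config$out_dir` and listed in `manifest.json` together with the
#' parameters and seed; rerunning the same config reproduces every
#' output byte for byte.
#'
#' @param config a [pipelineConfig()]
#' @return invisibly, the manifest list
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  seed <- config$seed

  ae <- .stage("input", {
    if (!is.null(config$sim)) {
      cfg <- config$sim
      cfg$seed <- seed
      simulateReactorSeries(cfg)
    } else {
      if (is.null(config$input$counts)) stop("no counts path configured")
      a <- readAmpliconTSV(config$input$counts, config$input$taxonomy,
                           config$input$metadata)
      if (!is.null(config$input$counts_b)) {
        b <- readAmpliconTSV(config$input$counts_b, config$input$taxonomy,
                             config$input$metadata)
        consensusMerge(a, b)
      } else a
    }
  })

  rare <- .stage("rarefaction", {
    depth <- if (identical(config$rarefy_depth, "min"))
      min(colSums(counts(ae))) else as.integer(config$rarefy_depth)
    rarefyCounts(ae, depth = depth, seed = seed + 1L)
  })
  filt <- .stage("prevalence_filter",
                 prevalenceFilter(rare, config$min_samples,
                                  config$min_max_relabund))
  relab <- .stage("relative_abundance", relativeAbundance(filt))
  meta <- sampleMetadata(filt)
  reactors <- unique(meta$reactor)

  alpha <- .stage("alpha_diversity", {
    out <- meta
    for (q in config$q_orders)
      out[[paste0("q", q)]] <- apply(relab, 2, hillAlpha, q = q)[out$sample]
    out
  })
  files["alpha_diversity"] <- .write_tsv(
    alpha, file.path(config$out_dir, "alpha_diversity.tsv"))

  d <- .stage("dissimilarity",
              dissimilarityMatrix(relab, q = config$q_network))
  dm <- data.frame(sample = rownames(dissMatrix(d)), dissMatrix(d),
                   check.names = FALSE)
  files["dissimilarity"] <- .write_tsv(
    dm, file.path(config$out_dir, "dissimilarity_q1.tsv"))

  ord <- .stage("pcoa", pcoaOrdination(d, k = 2))
  oc <- data.frame(sample = rownames(ordCoordinates(ord)),
                   ordCoordinates(ord),
                   proportion = rep(NA_real_, nrow(ordCoordinates(ord))))
  oc$proportion[seq_along(ordProportions(ord))] <- ordProportions(ord)
  files["pcoa"] <- .write_tsv(oc, file.path(config$out_dir, "pcoa.tsv"))

  temporal <- .stage("temporal", {
    out <- list()
    for (rx in reactors) {
      roc <- rateOfChange(d, meta, rx)
      roc$reactor <- rx
      curve <- timeGapCurve(d, meta, rx, window = config$window,
                            stride = config$stride)
      curve$reactor <- rx
      out[[rx]] <- list(rate = roc, curve = as.data.frame(curve),
                        peak_gap = peakGap(curve))
    }
    out
  })
  files["rate_of_change"] <- .write_tsv(
    do.call(rbind, lapply(temporal, `[[`, "rate")),
    file.path(config$out_dir, "rate_of_change.tsv"))
  files["time_gap_curves"] <- .write_tsv(
    do.call(rbind, lapply(temporal, `[[`, "curve")),
    file.path(config$out_dir, "time_gap_curves.tsv"))

  same_day <- .stage("same_day", {
    prs <- utils::combn(reactors, 2)
    do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
      s <- sameDayDissimilarity(d, meta, prs[1, j], prs[2, j])
      cbind(data.frame(reactor_a = prs[1, j], reactor_b = prs[2, j]), s)
    }))
  })
  files["same_day"] <- .write_tsv(
    same_day, file.path(config$out_dir, "same_day_dissimilarity.tsv"))

  networks <- list()
  for (rx in reactors) {
    networks[[rx]] <- .stage(paste0("network_", rx), {
      sub <- filt[, meta$sample[meta$reactor == rx]]
      sub <- prevalenceFilter(sub, config$min_samples, config$min_max_relabund)
      rel_rx <- relativeAbundance(sub)
      if (is.finite(config$network_top_n) &&
          nrow(sub) > config$network_top_n) {
        keep <- order(apply(rel_rx, 1, max),
                      decreasing = TRUE)[seq_len(config$network_top_n)]
        sub <- sub[sort(keep), ]
        rel_rx <- rel_rx[sort(keep), , drop = FALSE]
      }
      sp <- config$sparcc
      sp$seed <- seed + 10L
      obs <- sparccCorrelations(sub, sp)
      obs <- permutationPvalues(sub, obs, n_perm = config$n_perm,
                                seed = seed + 11L,
                                pseudocount = sp$pseudocount)
      spr <- spearmanCorrelations(rel_rx, fdr = config$fdr)
      edges <- consensusEdges(obs, spr, rho_min = config$rho_min,
                              p_max = config$p_max)
      if (!nrow(edges)) {
        list(edges = edges, network = NULL, modules = NULL)
      } else {
        net <- detectModules(edges)
        mods <- majorModules(net, rel_rx)
        list(edges = edges, network = net, modules = mods,
             trajectories = attr(mods, "trajectories"))
      }
    })
    files[paste0("edges_", rx)] <- .write_tsv(
      networks[[rx]]$edges,
      file.path(config$out_dir, paste0("edges_", rx, ".tsv")))
    if (!is.null(networks[[rx]]$network)) {
      files[paste0("modules_", rx)] <- .write_tsv(
        networks[[rx]]$modules,
        file.path(config$out_dir, paste0("modules_", rx, ".tsv")))
      files[paste0("network_", rx)] <- writeNetworkGraphML(
        networks[[rx]]$network,
        file.path(config$out_dir, paste0("network_", rx, ".graphml")))
    }
  }

  guilds <- .stage("guilds", {
    if (!"Genus" %in% colnames(taxonomyTable(filt)))
      stop("taxonomy with a Genus rank is required for guild summaries")
    gs <- guildSeries(filt, config$guild_map)
    tc <- if ("temperature" %in% colnames(meta))
      temperatureCorrelations(gs, meta) else NULL
    xt <- lapply(networks, function(nw) {
      if (is.null(nw$network)) NULL
      else guildModuleCrosstab(nw$network, filt, config$guild_map)
    })
    list(series = gs, temperature = tc, crosstab = xt)
  })
  gs_df <- data.frame(guild = rownames(guilds$series), guilds$series,
                      check.names = FALSE)
  files["guild_series"] <- .write_tsv(
    gs_df, file.path(config$out_dir, "guild_series.tsv"))
  if (!is.null(guilds$temperature))
    files["guild_temperature"] <- .write_tsv(
      guilds$temperature,
      file.path(config$out_dir, "guild_temperature_correlations.tsv"))

  manifest <- list(
    package = "granulaR",
    version = as.character(utils::packageVersion("granulaR")),
    seed = seed,
    parameters = list(
      q_orders = config$q_orders, q_network = config$q_network,
      rarefy_depth = min(colSums(counts(rare))),
      min_samples = config$min_samples,
      min_max_relabund = config$min_max_relabund,
      n_perm = config$n_perm, rho_min = config$rho_min,
      p_max = config$p_max, fdr = config$fdr,
      window = config$window, stride = config$stride,
      network_top_n = config$network_top_n,
      sparcc = unclass(config$sparcc)),
    n_samples = ncol(filt), n_asvs_filtered = nrow(filt),
    reactors = reactors,
    files = as.list(files))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest$results <- list(experiment = filt, dissimilarity = d,
                           ordination = ord, alpha = alpha,
                           temporal = temporal, same_day = same_day,
                           networks = networks, guilds = guilds)
  invisible(manifest)
}
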