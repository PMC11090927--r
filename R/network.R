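.edges_to_graph <- function(edges) {
  nodes <- sort(unique(c(edges$asv_a, edges$asv_b)))
  g <- igraph::graph_from_data_frame(edges[, c("asv_a", "asv_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  igraph::simplify(g)
}

#' Module detection by greedy modularity maximisation
#'
#' Builds the undirected, unweighted network from a consensus edge list
#' (nodes are the endpoints of retained edges; isolated ASVs are not
#' nodes) and partitions it by Clauset-Newman-Moore greedy agglomeration.
#' Modularity is \deqn{Q = \sum_c \left[\frac{e_c}{m} -
#' \left(\frac{d_c}{2m}\right)^2\right]}{Q = sum_c [e_c/m - (d_c/2m)^2]}
#' over modules c, with \eqn{e_c} within-module edges, \eqn{d_c} the
#' module's total degree and m the edge count. Vertices are added in
#' sorted label order so the agglomeration is deterministic.
#'
#' @param edges edge data.frame from [consensusEdges()] (any data.frame
#'   with `asv_a`/`asv_b` columns works)
#' @param method community method: `"fast_greedy"` (default,
#'   Clauset-Newman-Moore) or `"louvain"`
#' @return a [ConsensusNetwork-class]
#' @export
detectModules <- function(edges, method = c("fast_greedy", "louvain")) {
  method <- match.arg(method)
  if (!nrow(edges)) stop("edge list is empty")
  g <- .edges_to_graph(edges)
  part <- if (method == "fast_greedy") {
    comm <- igraph::cluster_fast_greedy(g)
    # cut the agglomeration dendrogram at its modularity maximum ourselves:
    # membership() can return a sub-optimal cut when the maximum is the
    # single-community root
    best <- which.max(comm$modularity)
    igraph::cut_at(comm, no = igraph::vcount(g) - (best - 1L))
  } else {
    igraph::membership(igraph::cluster_louvain(g))
  }
  q <- igraph::modularity(g, part)
  partition <- as.integer(part)
  names(partition) <- igraph::V(g)$name
  new("ConsensusNetwork", edges = edges, partition = partition,
      modularity = q)
}

#' Major modules and their abundance trajectories
#'
#' A module is "major" when it contains at least `min_asvs` ASVs and its
#' members' summed relative abundance reaches at least `min_relab` in at
#' least one sample. Trajectories are the per-sample sums of member
#' relative abundances.
#'
#' @param net a [ConsensusNetwork-class]
#' @param relab relative abundances (ASVs x samples) or
#'   [AmpliconExperiment-class]; must cover the network's nodes
#' @param min_asvs minimum module size
#' @param min_relab minimum summed relative abundance in some sample
#' @return data.frame with one row per module (`module`, `n_asvs`,
#'   `max_abundance`, `major`), with the modules-x-samples trajectory
#'   matrix as attribute `"trajectories"`
#' @export
majorModules <- function(net, relab, min_asvs = 10L, min_relab = 0.02) {
  m <- if (is(relab, "AmpliconExperiment")) relativeAbundance(relab) else as.matrix(relab)
  part <- modulePartition(net)
  missing <- setdiff(names(part), rownames(m))
  if (length(missing))
    stop("relative abundances lack network node(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  mods <- sort(unique(part))
  traj <- vapply(mods, function(mod) {
    members <- names(part)[part == mod]
    colSums(m[members, , drop = FALSE])
  }, numeric(ncol(m)))
  traj <- if (is.matrix(traj)) t(traj) else matrix(traj, ncol = 1)
  dimnames(traj) <- list(paste0("M", mods), colnames(m))
  n_asvs <- as.integer(table(factor(part, levels = mods)))
  max_ab <- apply(traj, 1, max)
  out <- data.frame(module = mods, n_asvs = n_asvs, max_abundance = max_ab,
                    major = n_asvs >= min_asvs & max_ab >= min_relab,
                    row.names = NULL)
  structure(out, trajectories = traj)
}

#' Export a consensus network as GraphML
#'
#' Writes the network (with module membership as a vertex attribute and
#' both correlation coefficients as edge attributes) for use in external
#' graph tools.
#'
#' @param net a [ConsensusNetwork-class]
#' @param path output file
#' @return invisibly, `path`
#' @export
writeNetworkGraphML <- function(net, path) {
  edges <- networkEdges(net)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  part <- modulePartition(net)
  igraph::V(g)$module <- unname(part[igraph::V(g)$name])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
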