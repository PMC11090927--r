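# Small in-code fixtures shared across test files.

tiny_counts <- function() {
  m <- matrix(c(3L, 0L, 5L,
                1L, 2L, 0L,
                0L, 4L, 4L), nrow = 3, byrow = TRUE,
              dimnames = list(c("ASV1", "ASV2", "ASV3"),
                              c("S1", "S2", "S3")))
  m
}

tiny_metadata <- function(samples = c("S1", "S2", "S3"),
                          reactor = c("AGS1", "AGS1", "CAS"),
                          dates = as.Date(c("2020-06-15", "2020-07-15",
                                            "2020-06-15"))) {
  data.frame(sample_id = samples, reactor = reactor, date = dates,
             temperature = c(15, 17, 15), row.names = samples)
}

tiny_ae <- function() {
  tax <- data.frame(Kingdom = "Bacteria", Phylum = "Proteobacteria",
                    Class = "Gamma", Order = "O1", Family = "F1",
                    Genus = c("Nitrosomonas", "Genus_1", ""),
                    Species = "",
                    row.names = c("ASV1", "ASV2", "ASV3"))
  AmpliconExperiment(tiny_counts(), taxonomy = tax,
                     metadata = tiny_metadata())
}

# small, fast generator configuration used where full study scale is not
# the point of the test
small_sim_config <- function(seed, ...) {
  args <- list(n_asvs = 200L, depth_range = c(20000L, 60000L), seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(reactorSimConfig, args)
}

# modularity by the definition formula, independent of igraph:
# Q = sum_c [ e_c / m - (d_c / 2m)^2 ]
modularity_by_formula <- function(edges, partition) {
  m <- nrow(edges)
  deg <- table(c(edges$asv_a, edges$asv_b))
  q <- 0
  for (mod in unique(partition)) {
    members <- names(partition)[partition == mod]
    e_c <- sum(edges$asv_a %in% members & edges$asv_b %in% members)
    d_c <- sum(deg[names(deg) %in% members])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# Brute-force Benjamini-Hochberg: largest i with p_(i) <= i * fdr / m,
# reject all p <= that threshold.
bh_reject_bruteforce <- function(p, fdr) {
  m <- length(p)
  ps <- sort(p)
  thresh <- which(ps <= seq_len(m) * fdr / m)
  if (!length(thresh)) return(logical(m))
  p <= ps[max(thresh)]
}

# Multinomial counts whose latent fractions come from a known lognormal
# basis; two designated taxa share the same basis draws (rho_basis = 1).
planted_basis_counts <- function(n_taxa = 52, n_samples = 200, depth = 50000,
                                 seed = 1, planted = TRUE) {
  set.seed(seed)
  logb <- matrix(rnorm(n_taxa * n_samples, 0, 1), n_taxa, n_samples)
  logb <- logb + rnorm(n_taxa, 0, 1)  # taxon-specific means
  if (planted) logb[2, ] <- logb[1, ] + 0.3
  f <- apply(logb, 2, function(v) { e <- exp(v); e / sum(e) })
  cnt <- vapply(seq_len(n_samples), function(j)
    as.integer(rmultinom(1, depth, f[, j])), integer(n_taxa))
  dimnames(cnt) <- list(paste0("t", seq_len(n_taxa)),
                        paste0("s", seq_len(n_samples)))
  cnt
}

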