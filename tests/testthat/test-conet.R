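test_that("variation matrix: proportional pairs, additivity, scale invariance", {
  set.seed(1)
  n <- 10000
  # taxon 2 proportional to taxon 1; taxa 3,4 independent lognormal with
  # log-variances 1 and 2
  base <- cbind(exp(rnorm(n, 0, 1)))
  f <- rbind(t(base), t(base * 3),
             exp(rnorm(n, -1, 1)), exp(rnorm(n, -2, sqrt(2))))
  f <- sweep(f, 2, colSums(f), "/")
  rownames(f) <- paste0("t", 1:4)
  colnames(f) <- paste0("s", 1:n)
  tm <- variationMatrix(f)
  expect_equal(tm["t1", "t2"], 0, tolerance = 1e-9)
  expect_equal(tm["t3", "t4"], 3, tolerance = 0.1)
  expect_equal(diag(tm), setNames(rep(0, 4), rownames(f)))
  expect_true(isSymmetric(tm))

  # compositional invariance: per-sample count rescaling changes nothing
  cnt <- matrix(rpois(40, 50) + 1L, 4, 10,
                dimnames = list(paste0("t", 1:4), paste0("s", 1:10)))
  scaled <- sweep(cnt, 2, c(1:10), "*")
  expect_equal(variationMatrix(cnt, pseudocount = 0),
               variationMatrix(scaled, pseudocount = 0), tolerance = 1e-12)
})

test_that("basis variances solve the sparsity system", {
  t3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3)
  expect_equal(basisVariances(t3), c(1, 2, 3), tolerance = 1e-12)

  # exact uncorrelated-basis construction is recovered to 1e-9
  set.seed(2)
  w <- rgamma(30, 2)
  t_exact <- outer(w, w, "+")
  diag(t_exact) <- 0
  expect_equal(basisVariances(t_exact), w, tolerance = 1e-9)

  # all-equal variation matrix gives equal variances
  te <- matrix(2, 5, 5); diag(te) <- 0
  expect_equal(basisVariances(te), rep(1, 5), tolerance = 1e-12)

  expect_error(basisVariances(matrix(0, 2, 2)), "singular|fewer than 3")
  t_neg <- matrix(c(0, 0.1, 0.1, 0.1, 0, 5, 0.1, 5, 0), 3, 3)
  expect_warning(basisVariances(t_neg), "clamped")
})

test_that("basis variances agree with an independent dense solve", {
  set.seed(3)
  for (i in 1:5) {
    D <- sample(5:20, 1)
    w <- rgamma(D, 2)
    t_mat <- outer(w, w, "+") + matrix(rnorm(D * D, 0, 0.01), D, D)
    t_mat <- (t_mat + t(t_mat)) / 2
    diag(t_mat) <- 0
    M <- matrix(1, D, D) + diag(D - 2, D)
    oracle <- solve(M) %*% rowSums(t_mat)
    expect_equal(basisVariances(t_mat), as.numeric(oracle), tolerance = 1e-9)
  }
})

test_that("SparCC recovers a planted correlated pair among independents", {
  cnt <- planted_basis_counts(seed = 4)
  res <- sparccCorrelations(cnt, sparccParams(seed = 11))
  rho <- corMatrix(res)
  expect_true(isSymmetric(rho))
  expect_equal(unname(diag(rho)), rep(1, nrow(rho)))
  expect_gte(rho["t1", "t2"], 0.9)
  off <- abs(rho[upper.tri(rho)])
  off <- off[-1]  # drop the planted pair (t1, t2 is the first upper entry)
  expect_lte(median(off), 0.1)
})

test_that("SparCC is invariant to sample order and reproducible by seed", {
  cnt <- planted_basis_counts(n_taxa = 20, n_samples = 60, seed = 5)
  r1 <- sparccCorrelations(cnt, sparccParams(n_resamples = 10, seed = 42))
  r2 <- sparccCorrelations(cnt, sparccParams(n_resamples = 10, seed = 42))
  expect_identical(corMatrix(r1), corMatrix(r2))
  perm <- sample(ncol(cnt))
  r3 <- sparccCorrelations(cnt[, perm], sparccParams(n_resamples = 10, seed = 42))
  # Dirichlet draws consume randomness per sample, so only the structure,
  # not the noise, is shared: estimates agree closely but not exactly
  expect_equal(corMatrix(r3), corMatrix(r1), tolerance = 0.15)
  expect_error(sparccCorrelations(cnt[1:3, ]), "at least 4")
})

test_that("on a fully independent basis, SparCC reports near-zero correlation", {
  meds <- vapply(1:20, function(s) {
    cnt <- planted_basis_counts(n_taxa = 30, n_samples = 200, seed = 100 + s,
                                planted = FALSE)
    rho <- corMatrix(sparccCorrelations(cnt, sparccParams(n_resamples = 10,
                                                          seed = s)))
    median(abs(rho[upper.tri(rho)]))
  }, numeric(1))
  expect_true(all(meds <= 0.1))
})

test_that("permutation p-values use the add-one estimator and calibrate", {
  cnt <- planted_basis_counts(n_taxa = 10, n_samples = 50, seed = 6)
  obs <- sparccCorrelations(cnt, sparccParams(n_resamples = 10, seed = 1))
  withp <- permutationPvalues(cnt, obs, n_perm = 99, seed = 2)
  p <- corPvalues(withp)
  expect_true(isSymmetric(p))
  expect_equal(min(p[upper.tri(p)]), 1 / 100)  # planted pair beats all perms
  expect_true(all(p[upper.tri(p)] > 0 & p[upper.tri(p)] <= 1))
  expect_error(permutationPvalues(cnt, obs, n_perm = 0), "n_perm")
})

test_that("BH procedure matches the brute-force threshold scan", {
  # worked example: exactly 2 of 10 rejected at fdr 0.05
  p10 <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.07, 0.08, 0.09, 0.10)
  expect_equal(sum(bh_reject_bruteforce(p10, 0.05)), 2)
  expect_equal(sum(p.adjust(p10, "BH") <= 0.05), 2)
  expect_equal(sum(bh_reject_bruteforce(rep(1, 20), 0.05)), 0)

  set.seed(8)
  for (i in 1:1000) {
    m <- sample(3:30, 1)
    p <- round(runif(m)^sample(1:3, 1), 4)
    expect_identical(p.adjust(p, "BH") <= 0.05, bh_reject_bruteforce(p, 0.05))
  }
})

test_that("Spearman correlations flag monotone pairs and mark constants NA", {
  x <- rbind(a = 1:10, b = (1:10)^2, c = rep(5, 10),
             d = c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3))
  colnames(x) <- paste0("s", 1:10)
  res <- spearmanCorrelations(x, fdr = 0.05)
  rho <- corMatrix(res)
  expect_equal(rho["a", "b"], 1)
  expect_true(all(is.na(rho["c", c("a", "b", "d")])))
  expect_false(any(corSignificant(res)["c", ], na.rm = FALSE))
  q <- corQvalues(res)
  expect_true(res@method == "spearman")
  expect_true(corSignificant(res)["a", "b"])
  expect_error(spearmanCorrelations(x[, 1:2]), "3 samples")
})

test_that("consensus edge rule requires both methods, both thresholds, positivity", {
  ids <- paste0("t", 1:4)
  mk <- function(vals) {
    m <- matrix(0, 4, 4, dimnames = list(ids, ids))
    m[upper.tri(m)] <- vals
    m <- m + t(m); diag(m) <- 1
    m
  }
  # pairs in upper.tri order: (1,2), (1,3), (2,3), (1,4), (2,4), (3,4)
  rho_s <- mk(c(0.6, 0.6, -0.8, 0.2, 0.7, 0.9))
  rho_p <- mk(c(0.55, 0.45, -0.8, 0.3, 0.7, 0.9))
  p_s <- mk(c(0.01, 0.01, 0.001, 0.2, 0.3, 0.01)); diag(p_s) <- 1
  q_p <- mk(c(0.03, 0.01, 0.001, 0.5, 0.01, 0.04)); diag(q_p) <- 1
  sparcc <- new("CorrelationResult", rho = rho_s, p = p_s, method = "sparcc")
  spear <- new("CorrelationResult", rho = rho_p, p = q_p, qvalues = q_p,
               significant = q_p <= 0.05, method = "spearman")
  e <- consensusEdges(sparcc, spear, rho_min = 0.5, p_max = 0.05)
  key <- paste(e$asv_a, e$asv_b)
  expect_true("t1 t2" %in% key)    # both above 0.5, both significant
  expect_false("t1 t3" %in% key)   # spearman rho 0.45 <= 0.5
  expect_false("t2 t3" %in% key)   # negative correlation
  expect_false("t2 t4" %in% key)   # sparcc p 0.3 >= 0.05
  expect_true("t3 t4" %in% key)
})

test_that("modularity of toy graphs matches hand-derived values", {
  tri2 <- data.frame(
    asv_a = c("a1", "a2", "a3", "b1", "b2", "b3"),
    asv_b = c("a2", "a3", "a1", "b2", "b3", "b1"))
  net <- detectModules(tri2)
  expect_equal(length(unique(modulePartition(net))), 2)
  expect_equal(modularityScore(net), 0.5, tolerance = 1e-12)

  k5 <- t(combn(paste0("v", 1:5), 2))
  net5 <- detectModules(data.frame(asv_a = k5[, 1], asv_b = k5[, 2]))
  expect_equal(length(unique(modulePartition(net5))), 1)
  expect_equal(modularityScore(net5), 0, tolerance = 1e-12)
  expect_error(detectModules(data.frame(asv_a = character(),
                                        asv_b = character())), "empty")
})

test_that("reported modularity equals the definition-formula recomputation", {
  set.seed(9)
  for (i in 1:5) {
    n <- 30
    edges <- unique(data.frame(
      asv_a = paste0("n", sample(n, 60, TRUE)),
      asv_b = paste0("n", sample(n, 60, TRUE))))
    edges <- edges[edges$asv_a != edges$asv_b, ]
    # canonical order, drop duplicated undirected pairs
    swap <- edges$asv_a > edges$asv_b
    tmp <- edges$asv_a[swap]; edges$asv_a[swap] <- edges$asv_b[swap]
    edges$asv_b[swap] <- tmp
    edges <- edges[!duplicated(edges), ]
    net <- detectModules(edges)
    expect_equal(modularityScore(net),
                 modularity_by_formula(networkEdges(net), modulePartition(net)),
                 tolerance = 1e-12)
  }
})

test_that("planted block structure is recovered with high ARI", {
  skip_if_not_installed("mclust")
  aris <- vapply(1:10, function(s) {
    set.seed(s)
    blocks <- rep(1:3, each = 20)
    ids <- paste0("n", sprintf("%02d", 1:60))
    pairs <- t(combn(60, 2))
    p_edge <- ifelse(blocks[pairs[, 1]] == blocks[pairs[, 2]], 0.8, 0.02)
    keep <- runif(nrow(pairs)) < p_edge
    edges <- data.frame(asv_a = ids[pairs[keep, 1]],
                        asv_b = ids[pairs[keep, 2]])
    net <- detectModules(edges)
    part <- modulePartition(net)
    mclust::adjustedRandIndex(part, blocks[match(names(part), ids)])
  }, numeric(1))
  expect_true(all(aris > 0.8))
})

test_that("major-module rule applies both size and abundance clauses", {
  # module 1: 9 ASVs (too few); module 2: 12 ASVs but max 1.5% (too rare);
  # module 3: 10 ASVs reaching 2.5% in one sample (major)
  mk_clique <- function(ids) {
    pr <- t(combn(ids, 2))
    data.frame(asv_a = pr[, 1], asv_b = pr[, 2])
  }
  g1 <- paste0("a", 1:9); g2 <- paste0("b", 1:12); g3 <- paste0("c", 1:10)
  edges <- rbind(mk_clique(g1), mk_clique(g2), mk_clique(g3))
  net <- detectModules(edges)
  all_ids <- c(g1, g2, g3, "filler")
  relab <- matrix(0, length(all_ids), 2,
                  dimnames = list(all_ids, c("S1", "S2")))
  relab[g1, 1] <- 0.03 / 9;    relab[g1, 2] <- 0.001
  relab[g2, 1] <- 0.015 / 12;  relab[g2, 2] <- 0.010 / 12
  relab[g3, 1] <- 0.025 / 10;  relab[g3, 2] <- 0.001
  relab["filler", ] <- 1 - colSums(relab)
  mm <- majorModules(net, relab, min_asvs = 10, min_relab = 0.02)
  part <- modulePartition(net)
  mod_of <- function(ids) unique(part[ids])
  expect_false(mm$major[mm$module == mod_of(g1)])
  expect_false(mm$major[mm$module == mod_of(g2)])
  expect_true(mm$major[mm$module == mod_of(g3)])
  traj <- attr(mm, "trajectories")
  expect_equal(unname(traj[paste0("M", mod_of(g3)), "S1"]), 0.025)
  expect_true(all(traj >= 0 & traj <= 1))
})

test_that("synthetic planted modules are recovered as coherent network modules", {
  agree <- vapply(1:3, function(s) {
    ae <- simulateReactorSeries(small_sim_config(seed = s, n_asvs = 150L))
    rare <- rarefyCounts(ae, seed = s + 50)
    md <- sampleMetadata(rare)
    sub <- prevalenceFilter(rare[, md$sample[md$reactor == "AGS1"]])
    obs <- sparccCorrelations(sub, sparccParams(n_resamples = 20, seed = s))
    obs <- permutationPvalues(sub, obs, n_perm = 200, seed = s + 1)
    spear <- spearmanCorrelations(relativeAbundance(sub))
    edges <- consensusEdges(obs, spear)
    net <- detectModules(edges)
    part <- modulePartition(net)
    gt <- groundTruth(ae)$module_of_asv[names(part)]
    # fraction of same-planted-module node pairs placed in one detected module
    pr <- t(combn(length(part), 2))
    same_pl <- gt[pr[, 1]] == gt[pr[, 2]]
    mean((part[pr[, 1]] == part[pr[, 2]])[same_pl])
  }, numeric(1))
  expect_true(all(agree > 0.7))
})
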