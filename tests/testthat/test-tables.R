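test_that("TSV round trip reproduces counts, order and metadata exactly", {
  ae <- tiny_ae()
  dir <- withr::local_tempdir()
  writeAmpliconTSV(ae, dir, prefix = "t")
  back <- readAmpliconTSV(file.path(dir, "t_counts.tsv"),
                          file.path(dir, "t_taxonomy.tsv"),
                          file.path(dir, "t_metadata.tsv"))
  expect_identical(counts(back), counts(ae))
  expect_identical(rownames(back), rownames(ae))
  expect_identical(colnames(back), colnames(ae))
  expect_equal(sampleMetadata(back)$date, sampleMetadata(ae)$date)
  expect_equal(taxonomyTable(back)$Genus, taxonomyTable(ae)$Genus)
})

test_that("loading rejects malformed inputs with informative errors", {
  dir <- withr::local_tempdir()
  writeLines(c("asv_id\tS1\tS2", "ASV1\t3\t-1"), file.path(dir, "neg.tsv"))
  expect_error(readAmpliconTSV(file.path(dir, "neg.tsv")), "negative")

  md <- tiny_metadata()[1:2, ]  # S3 missing
  expect_error(AmpliconExperiment(tiny_counts(), metadata = md), "S3")
  cnt <- tiny_counts()
  rownames(cnt) <- c("ASV1", "ASV1", "ASV3")
  expect_error(AmpliconExperiment(cnt, metadata = tiny_metadata()), "ASV1")
})

test_that("BIOM round trip preserves the count matrix", {
  skip_if_not_installed("biomformat")
  ae <- tiny_ae()
  path <- withr::local_tempfile(fileext = ".biom")
  writeAmpliconBiom(ae, path)
  back <- readAmpliconBiom(path, metadata = tiny_metadata())
  expect_equal(unname(counts(back)[rownames(ae), colnames(ae)]),
               unname(counts(ae)))
})

test_that("consensus merge keeps shared ASVs, averages, and is commutative", {
  mk <- function(vals, asvs) matrix(as.integer(vals), length(asvs), 2,
                                    dimnames = list(asvs, c("S1", "S2")),
                                    byrow = TRUE)
  a <- mk(c(10, 4, 7, 0), c("ASV1", "ASV2"))   # ASV2 present (7 in S1)
  b <- mk(c(12, 4, 0, 0), c("ASV1", "ASV2"))   # ASV2 all-zero in b
  out <- consensusMerge(a, b)
  expect_identical(rownames(out), "ASV1")       # intersection of present sets
  expect_identical(unname(out["ASV1", ]), c(11L, 4L))  # mean of 10,12 -> 11

  # round-half-to-even at .5
  a2 <- mk(c(1, 0), "ASVx"); b2 <- mk(c(2, 0), "ASVx")
  expect_identical(unname(consensusMerge(a2, b2)["ASVx", 1]), 2L)  # 1.5 -> 2
  a3 <- mk(c(2, 0), "ASVx"); b3 <- mk(c(3, 0), "ASVx")
  expect_identical(unname(consensusMerge(a3, b3)["ASVx", 1]), 2L)  # 2.5 -> 2

  expect_identical(consensusMerge(a, a), a)     # idempotent
  ba <- consensusMerge(b, a)
  expect_identical(ba[rownames(out), colnames(out), drop = FALSE], out)  # commutative
  expect_error(consensusMerge(a, mk(c(1, 1), "ASV1")[, 1, drop = FALSE]),
               "sample sets")
  # alternative strategies
  expect_identical(unname(consensusMerge(a2, b2, "min")["ASVx", 1]), 1L)
  expect_identical(unname(consensusMerge(a2, b2, "first")["ASVx", 1]), 1L)
})

test_that("rarefaction hits exact totals, is seeded, and errors below depth", {
  m <- matrix(c(60L, 40L, 50L, 30L), 2, 2,
              dimnames = list(c("a", "b"), c("S1", "S2")))
  r <- rarefyCounts(m, depth = 80, seed = 1)
  expect_equal(unname(colSums(r)), c(80, 80))
  expect_identical(rarefyCounts(m, depth = 80, seed = 1), r)
  expect_error(rarefyCounts(m, depth = 101), "S1")
  dropped <- rarefyCounts(m, depth = 90, drop_below = TRUE, seed = 1)
  expect_identical(colnames(dropped), "S1")
  # a sample already at depth is returned unchanged
  expect_identical(rarefyCounts(m, depth = 100, drop_below = TRUE,
                                seed = 5)[, "S1"], m[, "S1"])
})

test_that("rarefied counts follow the hypergeometric distribution", {
  # one sample (60, 40), depth 50: taxon-1 count ~ Hypergeom(100, 60, 50)
  m <- matrix(c(60L, 40L), 2, 1, dimnames = list(c("a", "b"), "S1"))
  draws <- vapply(1:2000, function(s) rarefyCounts(m, 50, seed = s)["a", 1],
                  numeric(1))
  expect_equal(mean(draws), 50 * 60 / 100, tolerance = 0.01)
  hyper_var <- 50 * 0.6 * 0.4 * (100 - 50) / (100 - 1)
  expect_equal(var(draws), hyper_var, tolerance = 0.07)
})

test_that("relative abundance normalises, is scale invariant, rejects zeros", {
  m <- matrix(c(3L, 1L, 0L, 0L), 2, 2,
              dimnames = list(c("a", "b"), c("S1", "S2")))
  expect_error(relativeAbundance(m), "S2")
  m2 <- m[, 1, drop = FALSE]
  expect_equal(unname(relativeAbundance(m2)[, 1]), c(0.75, 0.25))
  expect_equal(relativeAbundance(m2 * 10L), relativeAbundance(m2))
  expect_equal(colSums(relativeAbundance(tiny_counts())),
               setNames(rep(1, 3), c("S1", "S2", "S3")))
})

test_that("prevalence filter applies both clauses on enumerated edge cases", {
  # 4 samples at depth 10000; engineered per-ASV patterns
  m <- rbind(
    one_sample_high = c(100L, 0L, 0L, 0L),      # 1 sample at 1% -> out
    five_low        = c(4L, 4L, 4L, 4L),        # max 0.04% -> out
    two_ok          = c(6L, 6L, 0L, 0L),        # 2 samples, 0.06% -> in
    filler          = rep(9890L, 4) - c(110L, 10L, 4L, 4L))
  filler_fix <- 10000L - colSums(m[1:3, , drop = FALSE]) - m[4, ]
  m[4, ] <- m[4, ] + filler_fix
  colnames(m) <- paste0("S", 1:4)
  expect_equal(unname(colSums(m)), rep(10000, 4))
  kept <- rownames(prevalenceFilter(m, min_samples = 2,
                                    min_max_relabund = 5e-4))
  expect_true("two_ok" %in% kept)
  expect_false("one_sample_high" %in% kept)
  expect_false("five_low" %in% kept)
  # threshold is strict: exactly 0.05% is removed
  m2 <- rbind(at_threshold = c(5L, 5L), rest = c(9995L, 9995L))
  colnames(m2) <- c("S1", "S2")
  expect_false("at_threshold" %in%
                 rownames(prevalenceFilter(m2, 2, 5e-4)))
})

test_that("filtering then renormalising commutes with sample subsetting", {
  set.seed(21)
  m <- matrix(rpois(50 * 6, 3), 50, 6,
              dimnames = list(paste0("A", 1:50), paste0("S", 1:6)))
  storage.mode(m) <- "integer"
  f_all <- prevalenceFilter(m, 2, 1e-3)
  sub <- c("S2", "S5")
  # relative abundances of untouched samples are unaffected by which other
  # samples are present
  expect_equal(relativeAbundance(f_all)[, sub],
               relativeAbundance(f_all[, sub]))
})

test_that("rank aggregation conserves totals and pools unclassified by parent", {
  tax <- data.frame(
    Kingdom = "Bacteria", Phylum = "P", Class = "C", Order = "O",
    Family = c("F1", "F1", "X", "F2"),
    Genus = c("Nitrospira", "Nitrospira", "", "Other"),
    Species = "",
    row.names = paste0("ASV", 1:4))
  m <- matrix(c(5L, 7L, 2L, 3L), 4, 1,
              dimnames = list(paste0("ASV", 1:4), "S1"))
  md <- data.frame(sample_id = "S1", reactor = "AGS1",
                   date = as.Date("2020-06-15"), row.names = "S1")
  ae <- AmpliconExperiment(m, taxonomy = tax, metadata = md)
  agg <- aggregateByRank(ae, "Genus")
  expect_equal(unname(agg["Nitrospira", "S1"]), 12)
  expect_equal(unname(agg["unclassified_X", "S1"]), 2)
  expect_equal(colSums(agg), colSums(m))
  expect_error(aggregateByRank(ae, "Serovar"), "unknown rank")
})
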