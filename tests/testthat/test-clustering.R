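test_that("feature preprocessing retains the components the eigen oracle keeps", {
  # construct log-scale data with a known covariance spectrum, then map it
  # back through 2^x - eps so preprocessFeatures sees proportions
  set.seed(41)
  n <- 2000
  sds <- sqrt(c(0.50, 0.30, 0.15, 0.04, 0.006, 0.003, 0.001))
  z <- sapply(sds, function(s) rnorm(n, 0, s)) * 0.05
  base <- log2(0.30)
  p <- 2^(base + z) - 1e-3
  stopifnot(all(p > 0 & p < 1))
  df <- data.frame(tile_id = sprintf("t%04d", 1:n), tumor_id = "T1",
                   slide_id = "S1", row = 1:n, col = 0L, x0 = 0L, y0 = 1:n,
                   x1 = 1L, y1 = 2:(n + 1), inside_fraction = 1,
                   truncated = FALSE)
  colnames(p) <- subtypeMarkers()
  df <- cbind(df, p, PANCK = 0.7)
  tt <- tileTable(df)
  cfg <- analysisConfig()
  f <- preprocessFeatures(tt, cfg)
  # oracle: eigenvalues of the covariance of the actual log features
  logP <- log2(as.matrix(df[, subtypeMarkers()]) + cfg$logEpsilon)
  ev <- eigen(cov(logP), symmetric = TRUE)$values
  expect_equal(ncol(f@scores), sum(ev / sum(ev) > cfg$pcaVarMin))
  expect_equal(unname(f@explainedVariance),
               (ev / sum(ev))[seq_len(ncol(f@scores))], tolerance = 1e-8)
})

test_that("preprocessing is deterministic and errors on degenerate input", {
  out <- makePlantedTiles(nPer = 50)
  f1 <- preprocessFeatures(out$tileTable)
  f2 <- preprocessFeatures(out$tileTable)
  expect_identical(f1@scores, f2@scores)
  # duplicated single row -> zero variance
  df <- out$tileTable@tiles[rep(1, 10), ]
  df$tile_id <- paste0("d", 1:10)
  expect_error(preprocessFeatures(tileTable(df)), "zero-variance")
  empty <- out$tileTable@tiles[0, ]
  expect_error(preprocessFeatures(tileTable(empty)), "empty")
})

test_that("silhouette matches the direct-formula oracle on small instances", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(20:50, 1)
    x <- matrix(rnorm(n * 3), ncol = 3)
    k <- sample(2:4, 1)
    km <- kmeans(x, k, nstart = 5)
    d <- dist(x)
    pkg <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
    expect_equal(pkg, oracleSilhouette(x, km$cluster), tolerance = 1e-12)
    expect_true(pkg >= -1 && pkg <= 1)
  }
})

test_that("silhouette selection finds two well-separated blobs", {
  set.seed(8)
  x <- rbind(matrix(rnorm(120, 0, 0.4), ncol = 2),
             matrix(rnorm(120, 6, 0.4), ncol = 2))
  f <- new("FeatureMatrix", scores = x, explainedVariance = c(0.6, 0.4),
           epsilon = 1e-3, center = c(0, 0), rotation = diag(2))
  cfg <- analysisConfig(kRange = 2:6)
  sel <- selectK(f, cfg)
  expect_equal(sel$k, 2L)
  # single candidate k is returned as-is
  expect_equal(selectK(f, analysisConfig(kRange = 2))$k, 2L)
})

test_that("the planted 4-phenotype table selects k = 4 and recovers labels", {
  out <- makePlantedTiles(nPer = 250, seed = 19)
  cfg <- analysisConfig(seed = 19, kRange = 2:6)
  f <- preprocessFeatures(out$tileTable, cfg)
  sel <- selectK(f, cfg)
  expect_equal(sel$k, 4L)
  fit <- fitPhenotypes(out$tileTable, f, 4L, cfg)
  expect_setequal(fit$model@clusterNames, phenotypeLevels())
  expect_gt(labelAgreement(fit$labels, out$groundTruth), 0.95)
})

test_that("noise-free tables are recovered perfectly", {
  out <- generateTileTable(defaultProfiles(concentration = Inf),
                           c(Classical = 40, Intermediate = 40,
                             Basal.MUC16 = 40, Basal.S100A2 = 40), seed = 2)
  cfg <- analysisConfig(seed = 2)
  f <- preprocessFeatures(out$tileTable, cfg)
  fit <- fitPhenotypes(out$tileTable, f, 4L, cfg)
  expect_equal(labelAgreement(fit$labels, out$groundTruth), 1.0)
})

test_that("increasing noise degrades agreement monotonically from exact", {
  agr <- vapply(c(Inf, 100, 12), function(conc) {
    out <- generateTileTable(defaultProfiles(concentration = conc),
                             c(Classical = 150, Intermediate = 150,
                               Basal.MUC16 = 150, Basal.S100A2 = 150),
                             seed = 23)
    cfg <- analysisConfig(seed = 23)
    f <- preprocessFeatures(out$tileTable, cfg)
    fit <- fitPhenotypes(out$tileTable, f, 4L, cfg)
    labelAgreement(fit$labels, out$groundTruth)
  }, numeric(1))
  expect_equal(agr[1], 1.0)
  expect_true(all(diff(agr) <= 0))
})

test_that("naming is invariant to tile order", {
  out <- makePlantedTiles(nPer = 120, seed = 31)
  cfg <- analysisConfig(seed = 31)
  f <- preprocessFeatures(out$tileTable, cfg)
  fit <- fitPhenotypes(out$tileTable, f, 4L, cfg)
  # permute tiles: the label each tile receives must not change
  perm <- sample(nrow(out$tileTable@tiles))
  dfP <- out$tileTable@tiles[perm, ]
  ttP <- tileTable(dfP)
  fP <- preprocessFeatures(ttP, cfg)
  fitP <- fitPhenotypes(ttP, fP, 4L, cfg)
  common <- names(fit$labels)
  expect_equal(sum(fit$labels[common] != fitP$labels[common]), 0)
})

test_that("k = 2 merges basal profiles without leaving clusters unnamed", {
  out <- makePlantedTiles(nPer = 120, seed = 37)
  cfg <- analysisConfig(seed = 37)
  f <- preprocessFeatures(out$tileTable, cfg)
  fit <- fitPhenotypes(out$tileTable, f, 2L, cfg)
  expect_equal(sum(fit$model@clusterNames == "Unassigned"), 0)
  expect_error(fitPhenotypes(out$tileTable, f, 1L, cfg), "k must be")
})

test_that("compositions respect strict thresholds and tie-breaks", {
  mkTiles <- function(counts, tumor = "T1") {
    n <- sum(counts)
    df <- data.frame(tile_id = paste0(tumor, "_", seq_len(n)),
                     tumor_id = tumor, slide_id = "S1", row = seq_len(n),
                     col = 0L, x0 = 0L, y0 = seq_len(n), x1 = 1L,
                     y1 = seq_len(n) + 1L, inside_fraction = 1,
                     truncated = FALSE)
    for (mk in panelMarkers()) df[[mk]] <- 0.5
    labels <- stats::setNames(rep(names(counts), counts), df$tile_id)
    list(tt = tileTable(df), labels = labels)
  }
  cfg <- analysisConfig()
  # 0.989 / 0.011 split: basal present under the strict > 1% rule
  x <- mkTiles(c(Classical = 989, Basal.MUC16 = 11))
  comp <- as.data.frame(composeTumors(x$labels, x$tt, cfg))
  expect_true(comp$basal_present)
  expect_true(comp$`present.Basal.MUC16`)
  # exactly 1% basal: absent (strict inequality)
  y <- mkTiles(c(Classical = 990, Basal.MUC16 = 10))
  compY <- as.data.frame(composeTumors(y$labels, y$tt, cfg))
  expect_false(compY$basal_present)
  expect_false(compY$`present.Basal.MUC16`)
  # single-phenotype tumor
  z <- mkTiles(c(Intermediate = 25))
  compZ <- as.data.frame(composeTumors(z$labels, z$tt, cfg))
  expect_equal(compZ$Intermediate, 1.0)
  expect_identical(compZ$predominant, "Intermediate")
  expect_true(compZ$predominance_strict)
  # 50/50 tie breaks toward the earlier canonical phenotype
  w <- mkTiles(c(Classical = 10, Intermediate = 10))
  compW <- as.data.frame(composeTumors(w$labels, w$tt, cfg))
  expect_identical(compW$predominant, "Classical")
  expect_false(compW$predominance_strict)
})

test_that("pooled proportions equal the tile-weighted mean of compositions", {
  co <- generateCohort(15, seed = 3)
  tiles <- generateCohortTiles(co, nTilesPerTumor = 40L, seed = 3)
  labels <- tiles$groundTruth  # use planted labels directly
  comp <- composeTumors(labels, tiles$tileTable)
  df <- as.data.frame(comp)
  pooled <- pooledComposition(labels)
  weighted <- colSums(df[, phenotypeLevels()] * df$n_tiles) / sum(df$n_tiles)
  expect_equal(pooled$byPhenotype, weighted, tolerance = 1e-12)
  expect_equal(sum(pooled$byPhenotype), 1)
})
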