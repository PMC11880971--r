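test_that("tile generation obeys counts, labels and determinism", {
  prof <- defaultProfiles()
  out <- generateTileTable(prof, c(Classical = 100, Intermediate = 100),
                           seed = 3)
  expect_s4_class(out$tileTable, "TileTable")
  expect_equal(nrow(out$tileTable@tiles), 200L)
  expect_equal(as.integer(table(out$groundTruth)[c("Classical", "Intermediate")]),
               c(100L, 100L))
  # identical seed => identical table
  again <- generateTileTable(prof, c(Classical = 100, Intermediate = 100),
                             seed = 3)
  expect_identical(out$tileTable@tiles, again$tileTable@tiles)
  # different seed => different draws
  other <- generateTileTable(prof, c(Classical = 100, Intermediate = 100),
                             seed = 4)
  expect_false(identical(out$tileTable@tiles$GATA6, other$tileTable@tiles$GATA6))
})

test_that("infinite concentration is noise-free", {
  prof <- defaultProfiles(concentration = Inf)
  out <- generateTileTable(prof, c(Classical = 5, Basal.S100A2 = 5), seed = 1)
  m <- markerMatrix(out$tileTable)
  cl <- out$groundTruth == "Classical"
  for (mk in panelMarkers()) {
    expect_equal(unname(m[cl, mk]),
                 rep(prof$Classical$meanProportion[[mk]], 5))
    expect_equal(unname(m[!cl, mk]),
                 rep(prof$Basal.S100A2$meanProportion[[mk]], 5))
  }
})

test_that("tile generation rejects bad inputs", {
  expect_error(generateTileTable(list(), c(Classical = 1), seed = 1), "empty")
  expect_error(generateTileTable(defaultProfiles(), c(Classical = 0), seed = 1),
               ">= 1")
  expect_error(generateTileTable(defaultProfiles(), c(Nope = 5), seed = 1),
               "named")
  expect_error(phenotypeProfile("x", c(PANCK = 0.5)[rep(1, 3)]), "missing")
  expect_error(defaultProfiles(concentration = -1), "positive")
})

test_that("slide stacks plant the requested geometry and transforms", {
  prof <- defaultProfiles(concentration = Inf)
  layout <- list(list(annotation = c(10, 10, 110, 110), phenotype = "Classical"))
  st0 <- generateSlideStack(prof, layout, c(140, 140), mpp = 0.5, seed = 5)
  expect_s4_class(st0, "SlideStack")
  # identity transforms: duplicated channels of one slide are pixel-aligned
  # with an independently drawn but identically seeded stack
  st1 <- generateSlideStack(prof, layout, c(140, 140), mpp = 0.5, seed = 5)
  expect_identical(st0@masks, st1@masks)
  # planted shift displaces exactly the channels of that slide
  tr <- rigidTransform(7, -4, 0)
  st2 <- generateSlideStack(prof, layout, c(140, 140), mpp = 0.5,
                            plantedTransforms = list(slide2 = tr), seed = 5)
  expect_identical(st2@masks$PANCK, st0@masks$PANCK)
  expect_identical(st2@masks$GATA6, applyTransform(st0@masks$GATA6, tr))
  expect_identical(st2@masks$S100A2, applyTransform(st0@masks$S100A2, tr))
  expect_identical(st2@masks$MUC16, st0@masks$MUC16)
})

test_that("region positive-pixel fraction matches the binomial oracle", {
  prof <- defaultProfiles()
  # 500 x 500 region, Bernoulli(p) pixels: observed fraction within 3
  # binomial standard errors of p
  layout <- list(list(annotation = c(0, 0, 500, 500), phenotype = "Classical"))
  st <- generateSlideStack(prof, layout, c(500, 500), mpp = 0.5, seed = 9)
  n <- 500 * 500
  for (mk in c("GATA6", "CLDN18", "KRT17")) {
    p <- prof$Classical$meanProportion[[mk]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(st@masks[[mk]]) - p), 3 * se + 1e-12)
  }
})

test_that("slide stack generation validates layout", {
  prof <- defaultProfiles()
  expect_error(generateSlideStack(prof, list(), c(100, 100), 0.5), "empty")
  expect_error(generateSlideStack(
    prof, list(list(annotation = c(0, 0, 200, 50), phenotype = "Classical")),
    c(100, 100), 0.5), "outside canvas")
  expect_error(generateSlideStack(
    prof, list(list(annotation = c(0, 0, 50, 50), phenotype = "Classical")),
    c(100, 100), mpp = -1), "mpp")
})

test_that("cohort compositions are simplexes and survival is calibrated", {
  co <- generateCohort(200, seed = 21)
  comp <- co$groundTruth$composition
  expect_true(all(abs(rowSums(comp) - 1) < 1e-9))
  expect_true(all(comp >= 0))
  # basal presence flag consistent with the strict 1% rule
  expect_identical(unname(co$groundTruth$basal_present),
                   unname(comp[, "Basal.MUC16"] + comp[, "Basal.S100A2"] > 0.01))
  # both presence groups exist at this cohort size
  expect_gt(sum(co$survival$basal_present), 20)
  expect_gt(sum(!co$survival$basal_present), 20)
  # determinism
  co2 <- generateCohort(200, seed = 21)
  expect_identical(co$survival, co2$survival)
})

test_that("degenerate censoring rates behave as documented", {
  allCens <- generateCohort(30, censoringRate = 1, seed = 2)
  expect_true(all(allCens$survival$event == 0))
  km <- kmLogrank(allCens$survival, "basal_present")
  expect_true(all(is.na(km$median)))
  expect_true(is.na(km$p))
  noCens <- generateCohort(30, censoringRate = 0, seed = 2)
  expect_true(all(noCens$survival$event == 1))
})

test_that("cohort generation rejects invalid prevalence", {
  expect_error(generateCohort(10, phenotypePrevalence = c(Classical = 1.2,
    Intermediate = 0.9, Basal.MUC16 = 0.4, Basal.S100A2 = 0.4)), "prevalence")
})

test_that("cohort tile tables follow the drawn compositions", {
  co <- generateCohort(12, seed = 5)
  tiles <- generateCohortTiles(co, nTilesPerTumor = 50L, seed = 5)
  tab <- table(tiles$tileTable@tiles$tumor_id)
  expect_true(all(tab == 50L))
  # planted label counts equal the largest-remainder rounding of compositions
  for (tu in rownames(co$groundTruth$composition)[1:3]) {
    ids <- tiles$tileTable@tiles$tile_id[tiles$tileTable@tiles$tumor_id == tu]
    got <- table(factor(tiles$groundTruth[ids], levels = phenotypeLevels()))
    want <- co$groundTruth$composition[tu, phenotypeLevels()] * 50
    expect_true(all(abs(as.numeric(got) - want) <= 1))
  }
})
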