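test_that("Fisher p matches the hand enumeration on the 3/1/1/3 table", {
  # margins 4/4, 4/4; hypergeometric over a = 0..4 with C(8,4) = 70:
  # probs 1/70, 16/70, 36/70, 16/70, 1/70; two-sided p at a = 3 is
  # (1 + 16 + 16 + 1)/70 = 34/70
  res <- fisherExact2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(res$p, 34 / 70, tolerance = 1e-12)
  expect_equal(res$oddsRatio, 9)
})

test_that("Fisher p equals the independent implementation on all n <= 30 tables", {
  # sweep a lattice of 2x2 tables with total n up to 30 and compare with
  # stats::fisher.test (an independent C implementation of the same
  # two-sided definition)
  count <- 0L
  for (n in c(4L, 9L, 16L, 23L, 30L)) {
    for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
      d <- n - a - b - c
      tab <- matrix(c(a, b, c, d), 2, byrow = TRUE)
      p <- fisherExact2x2(tab)$p
      pref <- stats::fisher.test(tab)$p.value
      if (abs(p - pref) > 1e-10) {
        fail(sprintf("mismatch at table (%d,%d,%d,%d): %g vs %g",
                     a, b, c, d, p, pref))
      }
      count <- count + 1L
    }
  }
  expect_gt(count, 5000)
})

test_that("degenerate margins give p = 1 and an undefined odds ratio", {
  res <- fisherExact2x2(matrix(c(5, 3, 0, 0), 2, byrow = TRUE))
  expect_equal(res$p, 1)
  expect_false(res$orDefined)
  expect_true(is.na(res$oddsRatio))
})

test_that("co-occurrence tests run over all 6 pairs with BH adjustment", {
  co <- generateCohort(80, seed = 31)
  res <- cooccurrenceTest(co$compositions)
  expect_equal(nrow(res), 6L)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_equal(res$p_adj, p.adjust(res$p, "BH"))
  expect_true(all(res$n11 + res$n10 + res$n01 + res$n00 == 80))
  one <- generateCohort(1, seed = 1)
  expect_error(cooccurrenceTest(one$compositions), "at least 2")
})

test_that("independent presence yields mostly non-significant adjusted p", {
  hits <- vapply(1:30, function(i) {
    set.seed(500 + i)
    pres <- matrix(runif(200 * 4) < 0.5, 200, 4,
                   dimnames = list(NULL, phenotypeLevels()))
    prop <- matrix(0.25, 200, 4, dimnames = list(NULL, phenotypeLevels()))
    df <- data.frame(tumor_id = sprintf("P%03d", 1:200), n_tiles = 100L, prop,
                     check.names = FALSE)
    for (ph in phenotypeLevels()) df[[paste0("present.", ph)]] <- pres[, ph]
    df$predominant <- "Classical"; df$predominance_strict <- FALSE
    df$basal_present <- pres[, 3] | pres[, 4]
    comp <- new("TumorComposition", table = df, presenceMin = 0.01,
                predominanceMin = 0.5)
    any(cooccurrenceTest(comp)$p_adj <= 0.05)
  }, logical(1))
  expect_gte(mean(!hits), 0.9)
})

test_that("predominance shifts are detected per multi-slide tumor", {
  mk <- function(tumor, slide, dom) {
    prop <- stats::setNames(rep(0.05, 4), phenotypeLevels())
    prop[dom] <- 0.85
    c(list(tumor_id = paste(tumor, slide, sep = "|"), n_tiles = 100L),
      as.list(prop))
  }
  rows <- rbind(
    data.frame(mk("A", "s1", "Classical"), check.names = FALSE),
    data.frame(mk("A", "s2", "Classical"), check.names = FALSE),
    data.frame(mk("B", "s1", "Intermediate"), check.names = FALSE),
    data.frame(mk("B", "s2", "Basal.S100A2"), check.names = FALSE),
    data.frame(mk("C", "s1", "Basal.MUC16"), check.names = FALSE))
  prop <- as.matrix(rows[, phenotypeLevels()])
  rownames(prop) <- rows$tumor_id
  comp <- tilePheno:::.compositionTable(prop, rows$n_tiles, 0.01, 0.5)
  comp@table$slide_id <- sub("^.*\\|", "", comp@table$tumor_id)
  comp@table$tumor_id <- sub("\\|.*$", "", comp@table$tumor_id)
  res <- detectShifts(comp)
  expect_equal(res$nMultiSlide, 2L)       # single-slide C excluded
  expect_equal(res$nConserved, 1L)        # A conserved
  expect_equal(res$shifts$tumor_id, "B")
  expect_equal(res$shifts$from, "Intermediate")
  expect_equal(res$shifts$to, "Basal.S100A2")
})

test_that("KM and log-rank match the hand enumeration on a 6-patient fixture", {
  # group A: 2 (event), 4 (event), 6 (censored)
  # group B: 3 (event), 5 (censored), 7 (event)
  rec <- data.frame(patient_id = paste0("p", 1:6),
                    time_months = c(2, 4, 6, 3, 5, 7),
                    event = c(1, 1, 0, 1, 0, 1),
                    grp = rep(c("A", "B"), each = 3))
  out <- kmLogrank(rec, "grp")
  # frozen product-limit values computed by direct recursion:
  # A: S(2) = 2/3, S(4) = 1/3; B: S(3) = 2/3, S(7) = 0
  a <- out$curves[out$curves$group == "A" & out$curves$events > 0, ]
  expect_equal(a$survival, c(2 / 3, 1 / 3))
  b <- out$curves[out$curves$group == "B" & out$curves$events > 0, ]
  expect_equal(b$survival, c(2 / 3, 0))
  # frozen log-rank arithmetic: O = 2, E = 1.4, V = 0.74
  expect_equal(out$chisq, (2 - 1.4)^2 / 0.74, tolerance = 1e-9)
  expect_equal(out$p, pchisq((2 - 1.4)^2 / 0.74, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  # and the generic oracle agrees
  orc <- oracleLogrank(rec$time_months, rec$event, rec$grp)
  expect_equal(out$chisq, orc$chisq, tolerance = 1e-9)
  km <- oracleKM(rec$time_months[1:3], rec$event[1:3])
  expect_equal(a$survival, km$survival)
})

test_that("log-rank is symmetric in group labels and null on identical groups", {
  rec <- data.frame(time_months = c(3, 6, 9, 12, 2, 5, 8, 14),
                    event = c(1, 0, 1, 1, 1, 1, 0, 1),
                    grp = rep(c("X", "Y"), each = 4))
  out <- kmLogrank(rec, "grp")
  rec$grp <- ifelse(rec$grp == "X", "Y", "X")
  out2 <- kmLogrank(rec, "grp")
  expect_equal(out$chisq, out2$chisq, tolerance = 1e-12)
  # identical records in both groups
  same <- data.frame(time_months = rep(c(3, 6, 9), 2),
                     event = rep(c(1, 1, 0), 2),
                     grp = rep(c("A", "B"), each = 3))
  outS <- kmLogrank(same, "grp")
  expect_equal(outS$chisq, 0, tolerance = 1e-9)
  expect_equal(outS$p, 1, tolerance = 1e-6)
  expect_error(kmLogrank(same[same$grp == "A", ], "grp"), "2 levels")
})

test_that("Cox recovers a planted hazard ratio and is consistent at large n", {
  co <- generateCohort(500, basalHazardRatio = 2, censoringRate = 0.2,
                       seed = 11)
  cx <- coxFit(co$survival, c("basal_present", "age_over_65",
                              "margins_positive", "vascular_embolism",
                              "lymph_node_invasion", "vascular_invasion",
                              "perineural_invasion"))
  hr <- cx$hr[cx$covariate == "basal_present"]
  expect_gt(hr, 1.6); expect_lt(hr, 2.5)
  # consistency: |log HR bias| < 0.05 at n = 5000, single seeded run
  big <- generateCohort(5000, basalHazardRatio = 2, censoringRate = 0.2,
                        seed = 12)
  cxBig <- coxFit(big$survival, "basal_present")
  expect_lt(abs(cxBig$coef[1] - log(2)), 0.05)
})

test_that("Cox errors on constant covariates and impossible designs", {
  co <- generateCohort(40, seed = 9)
  df <- co$survival
  df$flat <- 1
  expect_error(coxFit(df, "flat"), "constant covariate")
  expect_error(coxFit(df, "not_there"), "missing covariate")
  few <- df[1:3, ]
  few$event <- c(1, 0, 0)
  expect_error(coxFit(few, c("basal_present", "age_over_65")), "fewer events")
})

test_that("scorer concordance handles identity, reversal and degenerate input", {
  x <- c(10, 40, 90, 150, 220, 300)
  expect_equal(scorerConcordance(x, x)$r, 1)
  expect_equal(scorerConcordance(x, rev(x), method = "spearman")$r, -1)
  expect_error(scorerConcordance(x[1:2], x[1:2]), "at least 3")
  expect_error(scorerConcordance(x, x[1:3]), "length")
  expect_error(scorerConcordance(rep(5, 6), x), "zero variance")
})
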