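#' Run the full synthetic-to-statistics pipeline
#'
#' Chains every stage from one configuration and one master seed, writing
#' inspectable outputs (CSV/JSON/PNG) to \code{outDir}:
#' \enumerate{
#'   \item simulate — a slide stack with planted per-slide misalignments for
#'     one demonstration tumor, a tumor cohort with planted basal hazard,
#'     and per-tumor tile tables matching the cohort compositions;
#'   \item register — re-align the mis-registered stack to the PANCK
#'     reference;
#'   \item tile — cut and quantify tiles over the annotation, apply the
#'     two-step filter;
#'   \item cluster — log/PCA features, silhouette-selected k, named k-means
#'     phenotypes on the cohort tiles;
#'   \item phenotype — per-tumor compositions and presence/predominance
#'     calls;
#'   \item stats — phenotype co-occurrence, per-slide predominance shifts,
#'     Kaplan-Meier/log-rank and Cox for basal presence.
#' }
#' All randomness derives from \code{cfg$seed}, so two runs with the same
#' configuration produce identical outputs (manifest timestamp aside).
#'
#' @param outDir output directory.
#' @param cfg an [analysisConfig()].
#' @param nTumors cohort size (default 60).
#' @param nTilesPerTumor tiles simulated per tumor (default 60).
#' @param basalHazardRatio planted hazard ratio for basal presence
#'   (default 2).
#' @param canvas canvas shape for the demonstration stack (default
#'   \code{c(360, 360)} with a reduced 30-um tile to keep desk-scale grids).
#' @param stackTileUm tile size (um) used on the demonstration stack.
#' @param verbose print per-stage record accounting.
#' @return invisibly, a list with the main in-memory results.
#' @export
runPipeline <- function(outDir, cfg = analysisConfig(), nTumors = 60L,
                        nTilesPerTumor = 60L, basalHazardRatio = 2,
                        canvas = c(360, 360), stackTileUm = 30,
                        verbose = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  profiles <- defaultProfiles()

  ## 1. simulate -------------------------------------------------------------
  say("[simulate] slide stack, cohort (n = %d), %d tiles/tumor",
      nTumors, nTilesPerTumor)
  planted <- list(slide2 = rigidTransform(6, -4, 0),
                  slide3 = rigidTransform(-5, 3, 0),
                  slide4 = rigidTransform(2, 7, 0),
                  slide5 = rigidTransform(-3, -6, 0))
  layout <- list(
    list(annotation = c(40, 40, 160, 160), phenotype = "Classical"),
    list(annotation = c(200, 40, 320, 160), phenotype = "Intermediate"),
    list(annotation = c(40, 200, 160, 320), phenotype = "Basal.MUC16"),
    list(annotation = c(200, 200, 320, 320), phenotype = "Basal.S100A2"))
  stack <- generateSlideStack(profiles, layout, canvas, mpp = cfg$mpp,
                              plantedTransforms = planted, seed = cfg$seed)
  writeSlideStack(stack, file.path(outDir, "stack"))
  cohort <- generateCohort(nTumors, basalHazardRatio = basalHazardRatio,
                           seed = cfg$seed + 1L)
  cohortTiles <- generateCohortTiles(cohort, profiles,
                                     nTilesPerTumor = nTilesPerTumor,
                                     seed = cfg$seed + 2L)
  writeTileTable(cohortTiles$tileTable, file.path(outDir, "cohort_tiles.csv"))
  utils::write.csv(cohort$survival, file.path(outDir, "survival.csv"),
                   row.names = FALSE)

  ## 2. register -------------------------------------------------------------
  reg <- registerStack(stack, maxShift = 12, maxTheta = 0, refine = FALSE)
  for (sl in names(reg$transforms)) {
    writeTransform(reg$transforms[[sl]],
                   file.path(outDir, paste0("transform_", sl, ".json")))
  }
  say("[register] %d slides aligned to PANCK", length(reg$transforms))

  ## 3. tile -----------------------------------------------------------------
  stackCfg <- cfg
  stackCfg$tileSizeUm <- stackTileUm
  tiles <- cutTiles(reg$stack@annotation, canvas, stackCfg, tumorId = "DEMO")
  tt <- quantifyTiles(tiles, reg$stack)
  ttF <- filterTiles(tt, stackCfg, verbose = verbose)
  writeTileTable(ttF, file.path(outDir, "demo_tiles.csv"))
  say("[tile] %d -> %d tiles after the two-step filter", nrow(tt), nrow(ttF))

  ## 4. cluster --------------------------------------------------------------
  ct <- filterTiles(cohortTiles$tileTable, cfg)
  feats <- preprocessFeatures(ct, cfg)
  ksel <- selectK(feats, cfg)
  fit <- fitPhenotypes(ct, feats, ksel$k, cfg)
  writePhenotypeModel(fit$model, file.path(outDir, "phenotype_model.json"))
  utils::write.csv(data.frame(tile_id = names(fit$labels),
                              phenotype = unname(fit$labels)),
                   file.path(outDir, "tile_labels.csv"), row.names = FALSE)
  say("[cluster] k = %d selected by silhouette", ksel$k)

  ## 5. phenotype ------------------------------------------------------------
  comp <- composeTumors(fit$labels, ct, cfg)
  utils::write.csv(as.data.frame(comp), file.path(outDir, "compositions.csv"),
                   row.names = FALSE)
  pooled <- pooledComposition(fit$labels)
  say("[phenotype] pooled basal/classical/intermediate = %.1f%% / %.1f%% / %.1f%%",
      100 * pooled$grouped["basal"], 100 * pooled$grouped["classical"],
      100 * pooled$grouped["intermediate"])

  ## 6. stats ----------------------------------------------------------------
  cooc <- cooccurrenceTest(comp)
  utils::write.csv(cooc, file.path(outDir, "cooccurrence.csv"),
                   row.names = FALSE)
  surv <- cohort$survival
  surv$basal_present <- as.data.frame(comp)$basal_present[
    match(surv$patient_id, as.data.frame(comp)$tumor_id)]
  km <- kmLogrank(surv, "basal_present")
  utils::write.csv(km$curves, file.path(outDir, "km_curves.csv"),
                   row.names = FALSE)
  cox <- coxFit(surv, c("basal_present", "age_over_65", "margins_positive",
                        "vascular_embolism", "lymph_node_invasion",
                        "vascular_invasion", "perineural_invasion"))
  utils::write.csv(cox, file.path(outDir, "cox.csv"), row.names = FALSE)
  say("[stats] log-rank p = %.3g; basal HR = %.2f", km$p,
      cox$hr[cox$covariate == "basal_present"])

  writeManifest(runManifest(cfg), file.path(outDir, "manifest.json"))
  invisible(list(stack = stack, registered = reg, demoTiles = ttF,
                 cohort = cohort, tileTable = ct, features = feats,
                 kSelection = ksel, fit = fit, compositions = comp,
                 pooled = pooled, cooccurrence = cooc, km = km, cox = cox))
}
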