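#' Default phenotype profile catalog
#'
#' Expected positive-pixel fractions per channel for the four tile
#' phenotypes. The numbers are package defaults chosen to reproduce the
#' qualitative marker ordering of the published phenotypes — Classical high
#' in CLDN18/GATA6/TFF1 with near-zero basal markers; Intermediate KRT17-high
#' with low-moderate GATA6; Basal.MUC16 MUC16-dominant with moderate KRT17;
#' Basal.S100A2 S100A2-dominant with moderate PanBS — they are not measured
#' values. All phenotypes are epithelial, so PANCK is high throughout.
#'
#' @param concentration Beta-noise concentration shared by all profiles
#'   (higher = less tile-to-tile noise; \code{Inf} = noise-free). Default 50.
#' @return a list of phenotype profiles, each with \code{name},
#'   \code{meanProportion} (named over [panelMarkers()]) and
#'   \code{concentration}.
#' @examples
#' names(defaultProfiles())
#' @export
defaultProfiles <- function(concentration = 50) {
  mk <- function(name, PANCK, GATA6, CLDN18, TFF1, MUC16, S100A2, KRT17, PanBS) {
    phenotypeProfile(name,
                     c(PANCK = PANCK, GATA6 = GATA6, CLDN18 = CLDN18,
                       TFF1 = TFF1, MUC16 = MUC16, S100A2 = S100A2,
                       KRT17 = KRT17, PanBS = PanBS),
                     concentration)
  }
  list(
    Classical    = mk("Classical",    0.75, 0.50, 0.55, 0.45, 0.02, 0.01, 0.03, 0.01),
    Intermediate = mk("Intermediate", 0.70, 0.15, 0.05, 0.03, 0.02, 0.02, 0.50, 0.02),
    Basal.MUC16  = mk("Basal.MUC16",  0.70, 0.02, 0.03, 0.02, 0.55, 0.03, 0.20, 0.05),
    Basal.S100A2 = mk("Basal.S100A2", 0.70, 0.02, 0.02, 0.01, 0.03, 0.55, 0.20, 0.25)
  )
}

#' Construct a phenotype profile
#'
#' @param name phenotype name.
#' @param meanProportion named numeric over [panelMarkers()], values in
#'   [0, 1]; for tumor phenotypes PANCK must exceed 0.10 (the tumor-tile
#'   gate).
#' @param concentration positive Beta concentration; \code{Inf} for
#'   noise-free draws.
#' @return a list of class \code{PhenotypeProfile}.
#' @export
phenotypeProfile <- function(name, meanProportion, concentration = 50) {
  miss <- setdiff(panelMarkers(), names(meanProportion))
  if (length(miss)) stop("profile means missing markers: ", paste(miss, collapse = ", "))
  meanProportion <- meanProportion[panelMarkers()]
  if (any(meanProportion < 0 | meanProportion > 1)) {
    stop("profile means must lie in [0, 1]")
  }
  if (meanProportion[["PANCK"]] <= 0.10) {
    stop("tumor phenotype profiles need PANCK mean > 0.10")
  }
  if (!(concentration > 0)) stop("concentration must be positive")
  structure(list(name = name, meanProportion = meanProportion,
                 concentration = concentration),
            class = "PhenotypeProfile")
}

.betaDraw <- function(n, mean, concentration) {
  # mean-parameterized Beta; degenerate endpoints and infinite concentration
  # collapse to the mean
  if (!is.finite(concentration) || mean <= 0 || mean >= 1) {
    return(rep(mean, n))
  }
  pmin(1, pmax(0, stats::rbeta(n, mean * concentration,
                               (1 - mean) * concentration)))
}

#' Generate a synthetic tile table with planted phenotype labels
#'
#' Each tile's marker proportions are drawn independently from a
#' mean-parameterized Beta around its phenotype's profile means. Tiles get a
#' synthetic full-tile geometry (unit grid, never truncated) so downstream
#' filtering behaves as on quantified data.
#'
#' @param profiles list of \code{PhenotypeProfile} (e.g. [defaultProfiles()]).
#' @param nPerPhenotype named integer: tiles to draw per profile name.
#' @param seed integer seed; identical seeds give identical tables.
#' @param tumorId tumor id(s) to assign; a single id, or a vector recycled
#'   across tiles.
#' @param slideId slide id stamped on every tile.
#' @return list with \code{tileTable} (a [TileTable-class]) and
#'   \code{groundTruth} (named character: tile id -> phenotype).
#' @examples
#' out <- generateTileTable(defaultProfiles(),
#'                          c(Classical = 20, Intermediate = 20), seed = 1)
#' nrow(out$tileTable)
#' @export
generateTileTable <- function(profiles, nPerPhenotype, seed,
                              tumorId = "T1", slideId = "S1") {
  if (length(profiles) == 0L) stop("empty profile list")
  profNames <- vapply(profiles, `[[`, character(1), "name")
  names(profiles) <- profNames
  if (is.null(names(nPerPhenotype)) ||
      !all(names(nPerPhenotype) %in% profNames)) {
    stop("nPerPhenotype must be named by profile names")
  }
  if (any(nPerPhenotype < 1)) stop("tile counts must be >= 1")
  nTot <- sum(nPerPhenotype)
  set.seed(as.integer(seed))
  labels <- rep(names(nPerPhenotype), times = nPerPhenotype)
  prop <- matrix(NA_real_, nTot, length(panelMarkers()),
                 dimnames = list(NULL, panelMarkers()))
  for (ph in names(nPerPhenotype)) {
    idx <- which(labels == ph)
    pr <- profiles[[ph]]
    for (m in panelMarkers()) {
      prop[idx, m] <- .betaDraw(length(idx), pr$meanProportion[[m]],
                                pr$concentration)
    }
  }
  side <- 1L
  df <- data.frame(
    tile_id = sprintf("tile_%05d", seq_len(nTot)),
    tumor_id = rep_len(tumorId, nTot),
    slide_id = slideId,
    row = seq_len(nTot) - 1L, col = 0L,
    x0 = 0L, y0 = seq_len(nTot) - 1L, x1 = side, y1 = seq_len(nTot),
    inside_fraction = 1, truncated = FALSE,
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(prop))
  gt <- stats::setNames(labels, df$tile_id)
  list(tileTable = tileTable(df), groundTruth = gt)
}

#' Generate a co-registered synthetic slide stack
#'
#' Builds one binary positive-pixel mask per channel on a shared canvas.
#' Each layout region carries one phenotype; inside it, pixels of channel m
#' are positive with that phenotype's profile mean for m (Bernoulli draws,
#' or a deterministic ordered-dither pattern in \code{pixelNoise = "exact"}
#' mode, which realizes the mean exactly — quantized to 1/100 — in every
#' aligned 10 x 10 block). Channels stained on the same physical slide are
#' displaced together by that slide's planted rigid transform.
#'
#' @param profiles list of \code{PhenotypeProfile}.
#' @param layout list of regions, each a list with \code{annotation} (a
#'   [SlideAnnotation-class] or a \code{c(x0, y0, x1, y1)} box) and
#'   \code{phenotype}.
#' @param canvas canvas shape \code{c(nrow, ncol)} in pixels.
#' @param mpp microns per pixel (> 0).
#' @param plantedTransforms named list of [RigidTransform-class], one per
#'   slide id in \code{channelSlides}; missing slides get the identity.
#' @param seed integer seed.
#' @param channelSlides named character mapping each channel to a physical
#'   slide id; the default mirrors the staining plan (PANCK alone,
#'   GATA6/S100A2 duplex, CLDN18/KRT17 duplex, TFF1/PanBS duplex, MUC16
#'   alone).
#' @param pixelNoise \code{"bernoulli"} (default) or \code{"exact"}.
#' @return a [SlideStack-class]; its \code{groundTruth} records the layout,
#'   profiles and planted transforms.
#' @export
generateSlideStack <- function(profiles, layout, canvas, mpp,
                               plantedTransforms = list(), seed = 1L,
                               channelSlides = defaultChannelSlides(),
                               pixelNoise = c("bernoulli", "exact")) {
  pixelNoise <- match.arg(pixelNoise)
  if (length(layout) == 0L) stop("empty layout")
  if (mpp <= 0) stop("mpp must be positive")
  profNames <- vapply(profiles, `[[`, character(1), "name")
  names(profiles) <- profNames
  nr <- as.integer(canvas[1]); nc <- as.integer(canvas[2])
  set.seed(as.integer(seed))
  regions <- lapply(layout, function(rg) {
    ann <- rg$annotation
    if (is.numeric(ann) && length(ann) == 4L) {
      ann <- rectAnnotation(ann[1], ann[2], ann[3], ann[4])
    }
    bb <- annotationBBox(ann)
    if (bb[1] < 0 || bb[2] < 0 || bb[3] > nc || bb[4] > nr) {
      stop("layout region outside canvas")
    }
    if (!rg$phenotype %in% profNames) {
      stop("layout phenotype without a profile: ", rg$phenotype)
    }
    list(mask = rasterizeAnnotation(ann, c(nr, nc)), annotation = ann,
         phenotype = rg$phenotype)
  })
  aligned <- list()
  for (ch in panelMarkers()) {
    m <- matrix(0L, nr, nc)
    for (rg in regions) {
      mean_ <- profiles[[rg$phenotype]]$meanProportion[[ch]]
      idx <- which(rg$mask)
      if (length(idx)) {
        if (pixelNoise == "bernoulli") {
          m[idx] <- as.integer(stats::runif(length(idx)) < mean_)
        } else {
          m[idx] <- .ditherPattern(nr, nc, mean_)[idx]
        }
      }
    }
    aligned[[ch]] <- m
  }
  # full annotation = union of region geometry
  fullAnn <- slideAnnotation(unlist(lapply(regions, function(rg)
    lapply(rg$annotation@polygons, identity)), recursive = FALSE))
  masks <- aligned
  for (ch in names(masks)) {
    sl <- channelSlides[[ch]]
    tr <- plantedTransforms[[sl]]
    if (!is.null(tr) && !.isIdentity(tr)) {
      masks[[ch]] <- applyTransform(masks[[ch]], tr)
    }
  }
  gt <- list(layout = lapply(regions, function(rg)
               list(annotation = rg$annotation, phenotype = rg$phenotype)),
             profiles = profiles,
             transforms = plantedTransforms,
             pixelNoise = pixelNoise, seed = as.integer(seed))
  new("SlideStack", masks = masks, channelSlide = channelSlides[panelMarkers()],
      annotation = fullAnn, mpp = mpp, groundTruth = gt)
}

#' @rdname generateSlideStack
#' @export
defaultChannelSlides <- function() {
  c(PANCK = "slide1", GATA6 = "slide2", S100A2 = "slide2",
    CLDN18 = "slide3", KRT17 = "slide3", TFF1 = "slide4", PanBS = "slide4",
    MUC16 = "slide5")
}

# 10x10 ordered-dither tile: round(p * 100) positives per block, scattered by
# a fixed permutation so partial tiles stay close to p as well
.ditherPattern <- function(nr, nc, p) {
  k <- round(p * 100)
  ord <- matrix(0L, 10, 10)
  # fixed pseudo-random threshold order (Bayer-like), independent of RNG state
  thr <- (seq_len(100) * 37L) %% 100L
  ord[order(thr)] <- seq_len(100) - 1L
  block <- matrix(as.integer(ord < k), 10, 10)
  block[((seq_len(nr) - 1L) %% 10L) + 1L, ((seq_len(nc) - 1L) %% 10L) + 1L,
        drop = FALSE]
}

.isIdentity <- function(t) t@dx == 0 && t@dy == 0 && t@theta == 0

#' Generate a synthetic tumor cohort with survival
#'
#' Each tumor first draws which phenotypes it contains (independent
#' Bernoulli per phenotype with the configured presence prevalence; a tumor
#' with no draw falls back to Intermediate, the near-ubiquitous phenotype),
#' then draws its composition from a Dirichlet over the contained
#' phenotypes. Overall survival times are exponential with the baseline
#' hazard, multiplied by \code{basalHazardRatio} when the summed basal
#' proportion strictly exceeds 1%. Censoring is independent exponential,
#' calibrated so the marginal probability of censoring equals
#' \code{censoringRate}. Six binary clinicopathological covariates (age >
#' 65, resection margins, vascular embolism, lymph-node invasion, vascular
#' invasion, perineural invasion) are drawn independently and carry no
#' planted effect.
#'
#' @param nTumors number of tumors.
#' @param phenotypePrevalence named numeric over [phenotypeLevels()]: the
#'   probability that each phenotype occurs in a tumor. Defaults emulate a
#'   resected-PDAC cohort: Intermediate nearly ubiquitous, classical in
#'   about three quarters, each basal phenotype in two fifths (so about 64%
#'   of tumors carry some basal contingent).
#' @param dirichletConcentration positive scalar; higher = less
#'   tumor-to-tumor spread around the prevalence-weighted composition.
#' @param basalHazardRatio hazard multiplier for basal-present tumors.
#' @param baselineHazard events per month for basal-free tumors.
#' @param censoringRate marginal probability that a record is censored, in
#'   [0, 1].
#' @param seed integer seed.
#' @param presenceMin presence threshold used to plant the hazard effect
#'   (default 0.01, strict).
#' @return list with \code{compositions} (a [TumorComposition-class]),
#'   \code{survival} (a data.frame of survival records) and
#'   \code{groundTruth} (the exact composition matrix and per-tumor basal
#'   flag).
#' @examples
#' co <- generateCohort(50, seed = 7)
#' head(co$survival)
#' @export
generateCohort <- function(nTumors,
                           phenotypePrevalence = c(Classical = 0.74,
                                                   Intermediate = 0.96,
                                                   Basal.MUC16 = 0.40,
                                                   Basal.S100A2 = 0.40),
                           dirichletConcentration = 6,
                           basalHazardRatio = 2,
                           baselineHazard = 0.02,
                           censoringRate = 0.2,
                           seed = 1L,
                           presenceMin = 0.01) {
  if (any(phenotypePrevalence < 0 | phenotypePrevalence > 1)) {
    stop("prevalence entries must lie in [0, 1]")
  }
  stopifnot(nTumors >= 1, dirichletConcentration > 0, basalHazardRatio > 0,
            baselineHazard > 0, censoringRate >= 0, censoringRate <= 1)
  levs <- phenotypeLevels()
  if (!all(levs %in% names(phenotypePrevalence))) {
    stop("prevalence must be named over phenotypeLevels()")
  }
  phenotypePrevalence <- phenotypePrevalence[levs]
  set.seed(as.integer(seed))
  alphaW <- phenotypePrevalence / sum(phenotypePrevalence)
  comp <- t(vapply(seq_len(nTumors), function(i) {
    inTumor <- stats::runif(length(levs)) < phenotypePrevalence
    if (!any(inTumor)) inTumor[match("Intermediate", levs)] <- TRUE
    a <- ifelse(inTumor, alphaW * dirichletConcentration, 0)
    g <- ifelse(inTumor, stats::rgamma(length(a), shape = pmax(a, 1e-8)), 0)
    g / sum(g)
  }, numeric(length(levs))))
  colnames(comp) <- levs
  ids <- sprintf("P%03d", seq_len(nTumors))
  rownames(comp) <- ids
  basal <- comp[, "Basal.MUC16"] + comp[, "Basal.S100A2"] > presenceMin
  hz <- baselineHazard * ifelse(basal, basalHazardRatio, 1)
  eventTime <- stats::rexp(nTumors, rate = hz)
  if (censoringRate >= 1) {
    time <- eventTime
    event <- rep(0L, nTumors)
  } else if (censoringRate <= 0) {
    time <- eventTime
    event <- rep(1L, nTumors)
  } else {
    censTime <- stats::rexp(nTumors,
                            rate = hz * censoringRate / (1 - censoringRate))
    event <- as.integer(eventTime <= censTime)
    time <- pmin(eventTime, censTime)
  }
  covP <- c(age_over_65 = 0.50, margins_positive = 0.25,
            vascular_embolism = 0.30, lymph_node_invasion = 0.65,
            vascular_invasion = 0.40, perineural_invasion = 0.80)
  covs <- vapply(covP, function(p) stats::rbinom(nTumors, 1L, p),
                 integer(nTumors))
  surv <- data.frame(patient_id = ids, time_months = time, event = event,
                     basal_present = basal, covs, stringsAsFactors = FALSE)
  compTab <- .compositionTable(comp, nTiles = rep(NA_integer_, nrow(comp)),
                               presenceMin = presenceMin,
                               predominanceMin = 0.5)
  list(compositions = compTab,
       survival = surv,
       groundTruth = list(composition = comp, basal_present = basal,
                          basalHazardRatio = basalHazardRatio,
                          baselineHazard = baselineHazard))
}

#' Draw per-tumor tile tables matching a cohort's compositions
#'
#' For each tumor in a generated cohort, draws tiles whose phenotype counts
#' follow the tumor's exact composition (rounded to \code{nTilesPerTumor}
#' tiles, largest-remainder rule) so clustered tile labels can be aggregated
#' back to per-tumor compositions.
#'
#' @param cohort output of [generateCohort()].
#' @param profiles phenotype profiles (default [defaultProfiles()]).
#' @param nTilesPerTumor tiles per tumor.
#' @param seed integer seed.
#' @return list with \code{tileTable} and \code{groundTruth} (tile labels),
#'   as in [generateTileTable()].
#' @export
generateCohortTiles <- function(cohort, profiles = defaultProfiles(),
                                nTilesPerTumor = 100L, seed = 1L) {
  comp <- cohort$groundTruth$composition
  tabs <- vector("list", nrow(comp))
  gts <- vector("list", nrow(comp))
  for (i in seq_len(nrow(comp))) {
    counts <- .largestRemainder(comp[i, ], nTilesPerTumor)
    counts <- counts[counts > 0]
    out <- generateTileTable(profiles, counts, seed = seed + i,
                             tumorId = rownames(comp)[i])
    df <- out$tileTable@tiles
    df$tile_id <- paste0(rownames(comp)[i], "_", df$tile_id)
    tabs[[i]] <- df
    gts[[i]] <- stats::setNames(unname(out$groundTruth), df$tile_id)
  }
  df <- do.call(rbind, tabs)
  rownames(df) <- NULL
  list(tileTable = tileTable(df), groundTruth = do.call(c, gts))
}

.largestRemainder <- function(p, n) {
  raw <- p * n
  k <- floor(raw)
  left <- n - sum(k)
  if (left > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(left)]
    k[extra] <- k[extra] + 1
  }
  stats::setNames(as.integer(k), names(p))
}
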