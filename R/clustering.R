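#' Log-transform and PCA-reduce tile marker proportions
#'
#' Features for clustering are the PCA scores of
#' \code{log2(proportion + epsilon)} over the seven subtype markers (PANCK is
#' the tumor gate, not a subtype signal, and is excluded). Columns are
#' centred but not variance-scaled before PCA (the log transform already
#' stabilizes the scale). Components with an explained-variance ratio
#' strictly above \code{cfg$pcaVarMin} are retained; each component's sign
#' is fixed so that its largest-magnitude loading is positive.
#'
#' @param x a [TileTable-class].
#' @param cfg an [analysisConfig()].
#' @return a [FeatureMatrix-class].
#' @export
preprocessFeatures <- function(x, cfg = analysisConfig()) {
  if (nrow(x@tiles) == 0L) stop("empty tile table")
  stopifnot(cfg$logEpsilon > 0)
  mk <- intersect(subtypeMarkers(), x@markers)
  if (length(mk) < 2L) stop("need at least two subtype markers")
  logP <- log2(markerMatrix(x)[, mk, drop = FALSE] + cfg$logEpsilon)
  if (all(apply(logP, 2, stats::var) < 1e-24)) {
    stop("zero-variance input: tiles are identical across markers")
  }
  pc <- stats::prcomp(logP, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- which(evr > cfg$pcaVarMin)
  if (length(keep) == 0L) {
    stop("no component exceeds the explained-variance threshold")
  }
  rot <- pc$rotation[, keep, drop = FALSE]
  scores <- pc$x[, keep, drop = FALSE]
  # deterministic sign convention
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- x@tiles$tile_id
  new("FeatureMatrix", scores = scores, explainedVariance = evr[keep],
      epsilon = cfg$logEpsilon, center = pc$center, rotation = rot)
}

.seededKmeans <- function(scores, k, cfg) {
  set.seed(cfg$seed + 1000L * k)
  stats::kmeans(scores, centers = k, nstart = cfg$kmeansRestarts,
                iter.max = 100L)
}

#' Mean silhouette width of a seeded k-means fit
#'
#' @param f a [FeatureMatrix-class].
#' @param k number of clusters.
#' @param cfg an [analysisConfig()]; when more than \code{silhouetteMax}
#'   tiles are present the silhouette is computed on a seeded subsample.
#' @return mean silhouette width in [-1, 1].
#' @export
silhouetteScore <- function(f, k, cfg = analysisConfig()) {
  km <- .seededKmeans(f@scores, k, cfg)
  idx <- .silhouetteSubsample(nrow(f@scores), cfg)
  d <- stats::dist(f@scores[idx, , drop = FALSE])
  .meanSilhouette(km$cluster[idx], d)
}

.silhouetteSubsample <- function(n, cfg) {
  if (n <= cfg$silhouetteMax) return(seq_len(n))
  set.seed(cfg$seed + 7L)
  sort(sample.int(n, cfg$silhouetteMax))
}

.meanSilhouette <- function(labels, d) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  sil <- cluster::silhouette(labels, d)
  mean(sil[, "sil_width"])
}

#' Select the number of clusters by the silhouette method
#'
#' Fits seeded k-means for every candidate k and returns the k maximizing
#' the mean silhouette width; ties break toward smaller k.
#'
#' @param f a [FeatureMatrix-class].
#' @param cfg an [analysisConfig()]; candidates come from \code{cfg$kRange}.
#' @return list with \code{k} and \code{silhouette} (named numeric over the
#'   candidates).
#' @export
selectK <- function(f, cfg = analysisConfig()) {
  n <- nrow(f@scores)
  ks <- cfg$kRange[cfg$kRange <= n - 1L]
  if (length(ks) == 0L) stop("too few tiles for the candidate k range")
  idx <- .silhouetteSubsample(n, cfg)
  d <- stats::dist(f@scores[idx, , drop = FALSE])
  sc <- vapply(ks, function(k) {
    km <- .seededKmeans(f@scores, k, cfg)
    .meanSilhouette(km$cluster[idx], d)
  }, numeric(1))
  names(sc) <- ks
  list(k = ks[which.max(sc)], silhouette = sc)
}

#' Fit and name tile phenotype clusters
#'
#' Seeded k-means (multiple random restarts) in the retained PCA space,
#' followed by rule-based naming of each cluster from its mean raw marker
#' proportions: the cluster in which MUC16 is both maximal across clusters
#' and dominant within the cluster is Basal.MUC16; likewise S100A2 for
#' Basal.S100A2; of the rest, the cluster maximizing the mean classical
#' signal (CLDN18, GATA6, TFF1) is Classical; a remaining cluster with KRT17
#' as top marker and a low classical mean is Intermediate. When clusters
#' remain unnamed and phenotype names remain unused (e.g. merged clusters at
#' small k), each leftover cluster takes the best-matching unused name under
#' a relaxed rule (dominance requirement dropped); only when more clusters
#' than names exist do clusters stay \code{"Unassigned"}.
#'
#' @param x a [TileTable-class].
#' @param f the matching [FeatureMatrix-class].
#' @param k number of clusters (>= 2).
#' @param cfg an [analysisConfig()].
#' @return list with \code{model} (a [PhenotypeModel-class]) and
#'   \code{labels} (named character: tile id -> phenotype name).
#' @export
fitPhenotypes <- function(x, f, k, cfg = analysisConfig()) {
  if (k < 2L) stop("k must be >= 2")
  if (k > nrow(unique(f@scores))) stop("k exceeds the number of distinct tiles")
  km <- .seededKmeans(f@scores, k, cfg)
  raw <- markerMatrix(x)
  centroidsRaw <- do.call(rbind, lapply(seq_len(k), function(i) {
    colMeans(raw[km$cluster == i, , drop = FALSE])
  }))
  nms <- .nameClusters(centroidsRaw, cfg)
  model <- new("PhenotypeModel", k = as.integer(k),
               centroidsPCA = km$centers, centroidsRaw = centroidsRaw,
               clusterNames = nms, seed = cfg$seed)
  labels <- stats::setNames(nms[km$cluster], x@tiles$tile_id)
  list(model = model, labels = labels)
}

# naming rules on the k x markers matrix of mean raw proportions
.nameClusters <- function(centroidsRaw, cfg) {
  sub <- centroidsRaw[, subtypeMarkers(), drop = FALSE]
  k <- nrow(sub)
  nms <- rep("Unassigned", k)
  classicalMean <- rowMeans(sub[, .classicalMarkers, drop = FALSE])
  dominant <- function(i, m) {
    others <- sub[i, setdiff(subtypeMarkers(), m)]
    sub[i, m] >= cfg$dominanceRatio * max(others)
  }
  taken <- logical(k)
  # (1)/(2): basal clusters by maximal + dominant marker
  for (spec in list(c("MUC16", "Basal.MUC16"), c("S100A2", "Basal.S100A2"))) {
    m <- spec[1]; nm <- spec[2]
    i <- which.max(ifelse(taken, -Inf, sub[, m]))
    if (!taken[i] && dominant(i, m)) {
      nms[i] <- nm; taken[i] <- TRUE
    }
  }
  # (3): classical = max mean of CLDN18/GATA6/TFF1 among the rest
  if (any(!taken)) {
    i <- which.max(ifelse(taken, -Inf, classicalMean))
    nms[i] <- "Classical"; taken[i] <- TRUE
  }
  # (4): intermediate = KRT17 top marker and low classical signal
  for (i in which(!taken)) {
    top <- colnames(sub)[which.max(sub[i, ])]
    if (top == "KRT17" && classicalMean[i] < cfg$classicalLowMax) {
      nms[i] <- "Intermediate"; taken[i] <- TRUE
      break
    }
  }
  # relaxed pass: leftover clusters take the best unused name
  unused <- setdiff(phenotypeLevels(), nms)
  for (i in which(!taken)) {
    if (length(unused) == 0L) break
    score <- vapply(unused, function(nm) .nameAffinity(sub[i, ], nm), numeric(1))
    pick <- unused[which.max(score)]
    nms[i] <- pick; taken[i] <- TRUE
    unused <- setdiff(unused, pick)
  }
  nms
}

.nameAffinity <- function(means, nm) {
  switch(nm,
    Classical    = mean(means[.classicalMarkers]),
    Intermediate = means[["KRT17"]] - mean(means[.classicalMarkers]),
    Basal.MUC16  = means[["MUC16"]],
    Basal.S100A2 = means[["S100A2"]]
  )
}

.compositionTable <- function(prop, nTiles, presenceMin, predominanceMin) {
  levs <- phenotypeLevels()
  prop <- prop[, levs, drop = FALSE]
  predominant <- apply(prop, 1, function(p) levs[which.max(p)])
  present <- prop > presenceMin
  colnames(present) <- paste0("present.", levs)
  df <- data.frame(tumor_id = rownames(prop), n_tiles = as.integer(nTiles),
                   prop, present,
                   predominant = predominant,
                   predominance_strict = apply(prop, 1, max) > predominanceMin,
                   basal_present = prop[, "Basal.MUC16"] +
                     prop[, "Basal.S100A2"] > presenceMin,
                   stringsAsFactors = FALSE, check.names = FALSE)
  rownames(df) <- NULL
  new("TumorComposition", table = df, presenceMin = presenceMin,
      predominanceMin = predominanceMin)
}

#' Per-tumor phenotype composition and presence/predominance calls
#'
#' Aggregates tile phenotype labels per tumor: the proportion of tiles in
#' each phenotype, strict presence calls (> 1% by default), the predominant
#' (argmax) phenotype with ties broken in [phenotypeLevels()] order, a
#' strict predominance flag (> 50% by default), and the basal-present flag
#' (summed Basal.MUC16 + Basal.S100A2 proportion strictly > the presence
#' threshold). Unassigned tiles are excluded from the denominator; tumors
#' with zero labeled tiles are dropped with a warning.
#'
#' @param labels named character (tile id -> phenotype), as returned by
#'   [fitPhenotypes()].
#' @param x the [TileTable-class] the labels refer to.
#' @param cfg an [analysisConfig()].
#' @param by aggregate per \code{"tumor"} (default) or per tumor-slide pair
#'   (\code{"slide"}, for shift detection).
#' @return a [TumorComposition-class].
#' @export
composeTumors <- function(labels, x, cfg = analysisConfig(),
                          by = c("tumor", "slide")) {
  by <- match.arg(by)
  df <- x@tiles
  if (!all(df$tile_id %in% names(labels))) stop("every tile must be labeled")
  lab <- labels[df$tile_id]
  unit <- if (by == "tumor") df$tumor_id else
    paste(df$tumor_id, df$slide_id, sep = "|")
  keep <- lab %in% phenotypeLevels()
  dropped <- setdiff(unique(unit), unique(unit[keep]))
  if (length(dropped)) {
    warning("tumor(s) with zero assigned tiles excluded: ",
            paste(dropped, collapse = ", "))
  }
  unit <- unit[keep]; lab <- lab[keep]
  cnt <- table(factor(unit), factor(lab, levels = phenotypeLevels()))
  prop <- sweep(unclass(cnt), 1, rowSums(cnt), "/")
  out <- .compositionTable(prop, rowSums(cnt), cfg$presenceMin,
                           cfg$predominanceMin)
  if (by == "slide") {
    sp <- strsplit(out@table$tumor_id, "|", fixed = TRUE)
    out@table$slide_id <- vapply(sp, `[`, character(1), 2)
    out@table$tumor_id <- vapply(sp, `[`, character(1), 1)
  }
  out
}

#' Pooled phenotype proportions over all tiles
#'
#' @param labels named character of tile phenotypes.
#' @return named numeric proportions over [phenotypeLevels()] (Unassigned
#'   tiles excluded), plus the grouped basal/classical/intermediate summary.
#' @export
pooledComposition <- function(labels) {
  lab <- labels[labels %in% phenotypeLevels()]
  p <- prop.table(table(factor(lab, levels = phenotypeLevels())))
  p <- stats::setNames(as.numeric(p), phenotypeLevels())
  list(byPhenotype = p,
       grouped = c(basal = unname(p["Basal.MUC16"] + p["Basal.S100A2"]),
                   classical = unname(p["Classical"]),
                   intermediate = unname(p["Intermediate"])))
}
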