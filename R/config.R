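#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline with the published
#' defaults: 200-um square tiles, the strict "more than 10% PanCK" tumor-tile
#' gate, the >1% presence and >50% predominance calls, and the >5%
#' explained-variance cut for retained principal components.
#'
#' @param tileSizeUm tile side in microns (default 200).
#' @param mpp microns per pixel of the digitized slides (default 0.5; the
#'   source scans do not state a resolution, so this is config-exposed).
#' @param panckMin tumor-tile gate: keep tiles with PANCK proportion
#'   strictly greater than this (default 0.10).
#' @param truncationMinInside minimum inside-annotation fraction for a tile
#'   to count as non-truncated (default 1.0: only full tiles are kept).
#' @param presenceMin phenotype presence call threshold, strict (default 0.01).
#' @param predominanceMin strict predominance threshold (default 0.50).
#' @param pcaVarMin keep principal components with explained-variance ratio
#'   strictly above this (default 0.05).
#' @param logEpsilon pseudo-count added to proportions before log2
#'   (default 1e-3).
#' @param alpha two-sided significance level (default 0.05).
#' @param kRange candidate cluster counts for silhouette selection
#'   (default 2:8).
#' @param seed master seed for all stochastic steps (default 1).
#' @param kmeansRestarts random restarts for each k-means fit (default 25).
#' @param silhouetteMax silhouette is computed on at most this many tiles,
#'   subsampled with the master seed (default 10000).
#' @param dominanceRatio a marker is "dominant" in a cluster when its mean is
#'   at least this multiple of every other subtype-marker mean (default 1.5).
#' @param classicalLowMax upper bound on the mean classical signal
#'   (CLDN18/GATA6/TFF1) for the Intermediate naming rule (default 0.2).
#' @return a list of class \code{AnalysisConfig}.
#' @examples
#' cfg <- analysisConfig(mpp = 0.5)
#' cfg$panckMin
#' @export
analysisConfig <- function(tileSizeUm = 200, mpp = 0.5, panckMin = 0.10,
                           truncationMinInside = 1.0, presenceMin = 0.01,
                           predominanceMin = 0.50, pcaVarMin = 0.05,
                           logEpsilon = 1e-3, alpha = 0.05, kRange = 2:8,
                           seed = 1L, kmeansRestarts = 25L,
                           silhouetteMax = 10000L, dominanceRatio = 1.5,
                           classicalLowMax = 0.2) {
  cfg <- list(tileSizeUm = tileSizeUm, mpp = mpp, panckMin = panckMin,
              truncationMinInside = truncationMinInside,
              presenceMin = presenceMin, predominanceMin = predominanceMin,
              pcaVarMin = pcaVarMin, logEpsilon = logEpsilon, alpha = alpha,
              kRange = as.integer(kRange), seed = as.integer(seed),
              kmeansRestarts = as.integer(kmeansRestarts),
              silhouetteMax = as.integer(silhouetteMax),
              dominanceRatio = dominanceRatio,
              classicalLowMax = classicalLowMax)
  class(cfg) <- "AnalysisConfig"
  validateConfig(cfg)
  cfg
}

validateConfig <- function(cfg) {
  stopifnot(cfg$tileSizeUm > 0, cfg$mpp > 0, cfg$logEpsilon > 0,
            cfg$kmeansRestarts >= 1, cfg$dominanceRatio > 0)
  frac <- c(panckMin = cfg$panckMin,
            truncationMinInside = cfg$truncationMinInside,
            presenceMin = cfg$presenceMin,
            predominanceMin = cfg$predominanceMin,
            pcaVarMin = cfg$pcaVarMin, alpha = cfg$alpha)
  bad <- names(frac)[frac <= 0 | frac > 1]
  if (length(bad)) {
    stop("config thresholds must lie in (0, 1]: ", paste(bad, collapse = ", "))
  }
  if (any(cfg$kRange < 2L)) stop("kRange must contain values >= 2")
  invisible(cfg)
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the published defaults.
#'
#' @param path path to a YAML file whose keys match [analysisConfig()]
#'   arguments.
#' @return an \code{AnalysisConfig} list.
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysisConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(analysisConfig, raw)
}

#' @export
print.AnalysisConfig <- function(x, ...) {
  cat("AnalysisConfig:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(x[[nm]], collapse = " ")))
  }
  invisible(x)
}
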