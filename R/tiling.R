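#' Cut an annotated region into fixed-size square tiles
#'
#' An axis-aligned, non-overlapping grid of square tiles is anchored at the
#' annotation bounding-box origin (floored to whole pixels). Tile side is
#' \code{round(tileSizeUm / mpp)} pixels. Every tile whose box intersects
#' the annotation is emitted with its inside fraction; tiles whose inside
#' fraction falls below \code{truncationMinInside} are flagged truncated.
#'
#' @param annotation a [SlideAnnotation-class].
#' @param canvas canvas shape \code{c(nrow, ncol)} in pixels.
#' @param cfg an [analysisConfig()]; uses \code{tileSizeUm}, \code{mpp} and
#'   \code{truncationMinInside}.
#' @param tumorId,slideId ids stamped on the tiles.
#' @return data.frame of tiles (geometry columns only, no marker columns).
#' @examples
#' tiles <- cutTiles(rectAnnotation(0, 0, 400, 400), c(400, 400),
#'                   analysisConfig(mpp = 0.5))
#' nrow(tiles)
#' @export
cutTiles <- function(annotation, canvas, cfg, tumorId = "T1", slideId = "S1") {
  if (cfg$mpp <= 0) stop("mpp must be positive")
  side <- as.integer(round(cfg$tileSizeUm / cfg$mpp))
  if (side < 1L) stop("tile side below one pixel")
  annMask <- rasterizeAnnotation(annotation, canvas)
  if (!any(annMask)) stop("empty annotation")
  bb <- annotationBBox(annotation)
  ox <- floor(bb[1]); oy <- floor(bb[2])
  nTx <- ceiling((bb[3] - ox) / side)
  nTy <- ceiling((bb[4] - oy) / side)
  out <- list()
  idx <- 0L
  for (ty in seq_len(nTy) - 1L) {
    for (tx in seq_len(nTx) - 1L) {
      x0 <- ox + tx * side; x1 <- x0 + side
      y0 <- oy + ty * side; y1 <- y0 + side
      rr <- max(y0, 0L):min(y1 - 1L, nrow(annMask) - 1L)
      cc <- max(x0, 0L):min(x1 - 1L, ncol(annMask) - 1L)
      if (length(rr) == 0L || length(cc) == 0L || rr[1] > rr[length(rr)]) next
      insidePx <- sum(annMask[rr + 1L, cc + 1L])
      if (insidePx == 0L) next
      frac <- insidePx / (side * side)
      idx <- idx + 1L
      out[[idx]] <- data.frame(
        tile_id = sprintf("%s_%s_r%03d_c%03d", tumorId, slideId, ty, tx),
        tumor_id = tumorId, slide_id = slideId, row = ty, col = tx,
        x0 = x0, y0 = y0, x1 = x1, y1 = y1,
        inside_fraction = frac,
        truncated = frac < cfg$truncationMinInside,
        stringsAsFactors = FALSE)
    }
  }
  if (idx == 0L) stop("annotation produced no tiles")
  do.call(rbind, out)
}

#' Quantify per-tile positive-pixel proportions
#'
#' For each tile and channel, the proportion is the number of positive
#' pixels within the tile-annotation intersection divided by the number of
#' annotation pixels in the tile — so boundary tiles are unbiased if they
#' are retained under a relaxed truncation threshold.
#'
#' @param tiles data.frame from [cutTiles()].
#' @param stack a [SlideStack-class]; must carry every panel channel.
#' @param channels channels to quantify (default [panelMarkers()]).
#' @return a [TileTable-class].
#' @export
quantifyTiles <- function(tiles, stack, channels = panelMarkers()) {
  miss <- setdiff(channels, names(stack@masks))
  if (length(miss)) {
    stop("stack is missing channel(s): ", paste(miss, collapse = ", "))
  }
  shape <- dim(stack@masks[[1]])
  if (any(tiles$x0 >= shape[2] | tiles$y0 >= shape[1] |
          tiles$x1 <= 0 | tiles$y1 <= 0)) {
    stop("tiles outside canvas")
  }
  annMask <- rasterizeAnnotation(stack@annotation, shape)
  prop <- matrix(NA_real_, nrow(tiles), length(channels),
                 dimnames = list(NULL, channels))
  for (i in seq_len(nrow(tiles))) {
    rr <- (max(tiles$y0[i], 0L):min(tiles$y1[i] - 1L, shape[1] - 1L)) + 1L
    cc <- (max(tiles$x0[i], 0L):min(tiles$x1[i] - 1L, shape[2] - 1L)) + 1L
    inAnn <- annMask[rr, cc, drop = FALSE]
    denom <- sum(inAnn)
    for (ch in channels) {
      sub <- stack@masks[[ch]][rr, cc, drop = FALSE]
      prop[i, ch] <- if (denom == 0L) 0 else sum(sub[inAnn] != 0) / denom
    }
  }
  tileTable(cbind(tiles, as.data.frame(prop)), markers = channels)
}

#' Two-step tile filter
#'
#' Keeps, in order, (1) the non-truncated tiles, then (2) the tumor tiles
#' whose PANCK proportion is strictly greater than \code{cfg$panckMin}
#' ("more than 10%"). Row order is preserved; the operation is idempotent.
#'
#' @param x a [TileTable-class].
#' @param cfg an [analysisConfig()].
#' @param verbose print the per-step tile accounting.
#' @return the filtered [TileTable-class].
#' @export
filterTiles <- function(x, cfg = analysisConfig(), verbose = FALSE) {
  df <- x@tiles
  step1 <- df[!df$truncated, , drop = FALSE]
  step2 <- step1[step1$PANCK > cfg$panckMin, , drop = FALSE]
  if (verbose) {
    message(sprintf("tiles: %d total -> %d non-truncated -> %d tumor (PANCK > %g)",
                    nrow(df), nrow(step1), nrow(step2), cfg$panckMin))
  }
  out <- x
  out@tiles <- step2
  out
}

#' H-score
#'
#' The immunohistochemical H-score: staining intensity class (0 = null,
#' 1 = weak, 2 = moderate, 3 = strong) multiplied by the percentage of
#' positive tumor cells (0-100), giving a value in [0, 300]. Vectorized.
#'
#' @param intensity integer in \{0, 1, 2, 3\}.
#' @param pctPositive percentage in [0, 100].
#' @return data.frame with \code{intensity}, \code{pct_positive},
#'   \code{value}.
#' @examples
#' computeHScore(3, 100)$value  # 300
#' @export
computeHScore <- function(intensity, pctPositive) {
  if (!all(intensity %in% 0:3)) stop("intensity must be in {0, 1, 2, 3}")
  if (any(!is.finite(pctPositive)) || any(pctPositive < 0 | pctPositive > 100)) {
    stop("pctPositive must lie in [0, 100]")
  }
  n <- max(length(intensity), length(pctPositive))
  intensity <- rep_len(as.numeric(intensity), n)
  pctPositive <- rep_len(as.numeric(pctPositive), n)
  data.frame(intensity = intensity, pct_positive = pctPositive,
             value = intensity * pctPositive)
}
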