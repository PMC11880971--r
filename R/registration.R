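#' Apply a rigid transform to a mask or point set
#'
#' Transforms map moving coordinates into fixed coordinates: rotate by
#' \code{theta} degrees counter-clockwise about \code{center}, then translate
#' by \code{(dx, dy)}. Point sets (n x 2 matrices of x, y) are transformed
#' exactly; masks are resampled by nearest neighbour on the same canvas
#' (pixels mapped outside the canvas are dropped, exposed pixels are 0).
#'
#' @param x a binary matrix mask, or an n x 2 numeric matrix of points.
#' @param transform a [RigidTransform-class].
#' @param center rotation centre \code{c(x, y)}; defaults to the canvas
#'   centre for masks and the origin for point sets.
#' @param isMask force mask interpretation; by default a matrix is treated
#'   as a mask unless it has exactly 2 columns and non-integer-like or
#'   explicitly point-ish content. Pass \code{isMask = FALSE} for 2-column
#'   point matrices.
#' @return the transformed object, same type as the input.
#' @examples
#' applyTransform(cbind(10, 10), rigidTransform(2, 0, 0), isMask = FALSE)
#' @export
applyTransform <- function(x, transform, center = NULL, isMask = NULL) {
  methods::validObject(transform)
  if (is.null(isMask)) isMask <- !(is.matrix(x) && ncol(x) == 2 && nrow(x) < 1e4 &&
                                     !all(x %in% c(0, 1)))
  if (!isMask) {
    if (is.null(center)) center <- c(0, 0)
    return(.transformPoints(x, transform, center))
  }
  nr <- nrow(x); nc <- ncol(x)
  if (is.null(center)) center <- c(nc / 2, nr / 2)
  # inverse mapping: for each output pixel centre, sample the input at the
  # inverse-transformed location (nearest neighbour)
  th <- -transform@theta * pi / 180
  cs <- cos(th); sn <- sin(th)
  xs <- rep(seq_len(nc) - 0.5, each = nr)
  ys <- rep(seq_len(nr) - 0.5, times = nc)
  xr <- xs - transform@dx - center[1]
  yr <- ys - transform@dy - center[2]
  sx <- cs * xr - sn * yr + center[1]
  sy <- sn * xr + cs * yr + center[2]
  ci <- floor(sx) + 1L
  ri <- floor(sy) + 1L
  ok <- ci >= 1L & ci <= nc & ri >= 1L & ri <= nr
  out <- matrix(0L, nr, nc)
  out[cbind(ys + 0.5, xs + 0.5)[ok, , drop = FALSE]] <-
    as.integer(x[cbind(ri[ok], ci[ok])])
  out
}

.transformPoints <- function(pts, transform, center) {
  th <- transform@theta * pi / 180
  cs <- cos(th); sn <- sin(th)
  xr <- pts[, 1] - center[1]
  yr <- pts[, 2] - center[2]
  cbind(cs * xr - sn * yr + center[1] + transform@dx,
        sn * xr + cs * yr + center[2] + transform@dy)
}

#' Invert a rigid transform
#'
#' @param transform a [RigidTransform-class].
#' @return the inverse transform (about the origin; when applied to masks or
#'   points, use the same \code{center} as the forward transform).
#' @export
invertTransform <- function(transform) {
  th <- -transform@theta * pi / 180
  cs <- cos(th); sn <- sin(th)
  rigidTransform(-(cs * transform@dx - sn * transform@dy),
                 -(sn * transform@dx + cs * transform@dy),
                 -transform@theta)
}

#' Dice overlap of two binary masks
#'
#' @param a,b binary matrices of the same shape.
#' @return 2|A n B| / (|A| + |B|), in [0, 1]; 1 when both masks are empty.
#' @export
diceOverlap <- function(a, b) {
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

#' Estimate the rigid transform aligning a moving mask to a fixed mask
#'
#' Exhaustive search over rotations (grid) with, for each rotation, the
#' best integer translation found by FFT cross-correlation of the foreground
#' indicators (the Dice numerator for every shift at once), followed by
#' coordinate-wise hill climbing down to 0.1 px / 0.1 degrees. Maximizes the
#' Dice overlap between the transformed moving mask and the fixed mask.
#'
#' @param fixed,moving binary matrices of the same shape, each with at least
#'   one positive pixel.
#' @param maxShift translation search bound in pixels (default 50).
#' @param maxTheta rotation search bound in degrees (default 5).
#' @param thetaStep rotation grid step in degrees (default 0.5).
#' @param refine refine to 0.1 px / 0.1 deg by local hill climbing
#'   (default TRUE).
#' @return list with \code{transform} (a [RigidTransform-class] mapping
#'   moving into fixed coordinates) and \code{score} (Dice after alignment).
#' @examples
#' m <- matrix(0L, 64, 64); m[20:40, 25:45] <- 1L
#' est <- estimateRigidTransform(m, applyTransform(m, rigidTransform(4, -2, 0)),
#'                               maxShift = 10)
#' est$transform
#' @export
estimateRigidTransform <- function(fixed, moving, maxShift = 50,
                                   maxTheta = 5, thetaStep = 0.5,
                                   refine = TRUE) {
  if (!all(dim(fixed) == dim(moving))) stop("masks must share the same shape")
  if (sum(fixed != 0) == 0L) stop("fixed mask has no positive pixels")
  if (sum(moving != 0) == 0L) stop("moving mask has no positive pixels")
  if (maxShift < 0 || maxTheta < 0 || thetaStep <= 0) {
    stop("empty search space")
  }
  thetas <- if (maxTheta == 0) 0 else seq(-maxTheta, maxTheta, by = thetaStep)
  fFixed <- stats::fft((fixed != 0) + 0)
  nr <- nrow(fixed); nc <- ncol(fixed)
  sFixed <- sum(fixed != 0)
  best <- list(dx = 0, dy = 0, theta = 0, score = -1)
  for (th in thetas) {
    rot <- if (th == 0) (moving != 0) + 0 else
      applyTransform(moving, rigidTransform(0, 0, th))
    sRot <- sum(rot != 0)
    if (sRot == 0) next
    # circular cross-correlation: overlap(dy, dx) for every integer shift
    cc <- Re(stats::fft(fFixed * Conj(stats::fft(rot + 0)), inverse = TRUE)) /
      (nr * nc)
    dys <- c(0:(nr - 1)); dys[dys > nr / 2] <- dys[dys > nr / 2] - nr
    dxs <- c(0:(nc - 1)); dxs[dxs > nc / 2] <- dxs[dxs > nc / 2] - nc
    okR <- abs(dys) <= maxShift
    okC <- abs(dxs) <= maxShift
    sub <- cc[okR, okC, drop = FALSE]
    iBest <- which.max(sub)
    ov <- sub[iBest]
    dice <- 2 * ov / (sFixed + sRot)
    if (dice > best$score + 1e-12) {
      ri <- (iBest - 1) %% nrow(sub) + 1
      ci <- (iBest - 1) %/% nrow(sub) + 1
      best <- list(dx = dxs[okC][ci], dy = dys[okR][ri], theta = th,
                   score = dice)
    }
  }
  if (refine) {
    best <- .refineTransform(fixed, moving, best, thetaStep)
  }
  list(transform = rigidTransform(best$dx, best$dy, best$theta),
       score = best$score)
}

.scoreTransform <- function(fixed, moving, dx, dy, th) {
  diceOverlap(fixed, applyTransform(moving, rigidTransform(dx, dy, th)))
}

.refineTransform <- function(fixed, moving, best, thetaStep) {
  # the grid stage scored with circular correlation; re-score exactly
  best$score <- .scoreTransform(fixed, moving, best$dx, best$dy, best$theta)
  for (step in c(0.5, 0.2, 0.1)) {
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (d in list(c(step, 0, 0), c(-step, 0, 0), c(0, step, 0),
                     c(0, -step, 0), c(0, 0, step), c(0, 0, -step))) {
        cand <- c(best$dx + d[1], best$dy + d[2], best$theta + d[3])
        sc <- .scoreTransform(fixed, moving, cand[1], cand[2], cand[3])
        if (sc > best$score + 1e-12) {
          best <- list(dx = cand[1], dy = cand[2], theta = cand[3], score = sc)
          improved <- TRUE
        }
      }
    }
  }
  best
}

#' Register every channel of a slide stack to a reference channel
#'
#' Estimates one rigid transform per physical slide (channels on the same
#' slide share a transform, estimated from the union of their masks against
#' the reference channel's mask) and resamples all masks into the reference
#' frame.
#'
#' @param stack a [SlideStack-class].
#' @param reference reference channel (default \code{"PANCK"}).
#' @param ... search parameters passed to [estimateRigidTransform()].
#' @return list with \code{stack} (registered [SlideStack-class]) and
#'   \code{transforms} (named list of per-slide [RigidTransform-class]).
#' @export
registerStack <- function(stack, reference = "PANCK", ...) {
  if (!reference %in% names(stack@masks)) {
    stop("reference channel missing: ", reference)
  }
  fixed <- stack@masks[[reference]]
  refSlide <- stack@channelSlide[[reference]]
  slides <- unique(stack@channelSlide)
  transforms <- list()
  masks <- stack@masks
  for (sl in slides) {
    chs <- names(stack@channelSlide)[stack@channelSlide == sl]
    if (sl == refSlide) {
      transforms[[sl]] <- rigidTransform(0, 0, 0)
      next
    }
    union <- Reduce(`|`, lapply(stack@masks[chs], function(m) m != 0))
    if (!any(union)) {
      transforms[[sl]] <- rigidTransform(0, 0, 0)
      next
    }
    est <- estimateRigidTransform(fixed, union + 0, ...)
    transforms[[sl]] <- est$transform
    for (ch in chs) {
      masks[[ch]] <- applyTransform(stack@masks[[ch]], est$transform)
    }
  }
  out <- stack
  out@masks <- masks
  list(stack = out, transforms = transforms)
}

#' Read/write rigid transforms as JSON
#'
#' @param transform a [RigidTransform-class].
#' @param path file path.
#' @return \code{readTransform} returns a [RigidTransform-class];
#'   \code{writeTransform} returns \code{path} invisibly.
#' @export
writeTransform <- function(transform, path) {
  jsonlite::write_json(list(dx = transform@dx, dy = transform@dy,
                            theta = transform@theta),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  j <- jsonlite::read_json(path)
  rigidTransform(j$dx, j$dy, j$theta)
}
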