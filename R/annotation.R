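#' Construct annotations from raw rings
#'
#' \code{slideAnnotation()} builds a [SlideAnnotation-class] from a list of
#' polygons; \code{rectAnnotation()} is a convenience for an axis-aligned
#' rectangle given as a 0-based half-open pixel box.
#'
#' @param polygons list of polygons; each either an n x 2 vertex matrix
#'   (taken as the outer ring) or a list with \code{outer} and optional
#'   \code{holes}.
#' @return a [SlideAnnotation-class].
#' @examples
#' a <- rectAnnotation(0, 0, 100, 100)
#' annotationArea(a, c(200, 200))
#' @export
slideAnnotation <- function(polygons) {
  polys <- lapply(polygons, function(p) {
    if (is.matrix(p)) p <- list(outer = p, holes = list())
    if (is.null(p$holes)) p$holes <- list()
    p$outer <- .closeRing(p$outer)
    p$holes <- lapply(p$holes, .closeRing)
    p
  })
  new("SlideAnnotation", polygons = polys)
}

#' @rdname slideAnnotation
#' @param x0,y0,x1,y1 box edges in pixels, 0-based half-open
#'   \code{[x0, x1) x [y0, y1)}: the covered pixel centres are
#'   \code{x0 .. x1-1} by \code{y0 .. y1-1}.
#' @export
rectAnnotation <- function(x0, y0, x1, y1) {
  stopifnot(x1 > x0, y1 > y0)
  # ring placed at half-open box edges; pixel centre (c + 0.5, r + 0.5)
  # falls inside iff x0 <= c < x1 and y0 <= r < y1
  ring <- cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  slideAnnotation(list(ring))
}

.closeRing <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

#' Annotation bounding box
#'
#' @param annotation a [SlideAnnotation-class].
#' @return numeric \code{c(x0, y0, x1, y1)} over all outer rings.
#' @export
annotationBBox <- function(annotation) {
  xs <- unlist(lapply(annotation@polygons, function(p) p$outer[, 1]))
  ys <- unlist(lapply(annotation@polygons, function(p) p$outer[, 2]))
  c(min(xs), min(ys), max(xs), max(ys))
}

#' Rasterize an annotation to a pixel mask
#'
#' A pixel belongs to the annotation when its centre (col + 0.5, row + 0.5)
#' lies inside an outer ring and outside every hole (even-odd rule via
#' point-in-polygon).
#'
#' @param annotation a [SlideAnnotation-class].
#' @param shape canvas shape \code{c(nrow, ncol)} in pixels.
#' @return a logical nrow x ncol matrix.
#' @export
rasterizeAnnotation <- function(annotation, shape) {
  stopifnot(length(shape) == 2L, all(shape >= 1))
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  mask <- matrix(FALSE, nr, nc)
  bb <- annotationBBox(annotation)
  c0 <- max(0L, floor(bb[1])); c1 <- min(nc - 1L, ceiling(bb[3]))
  r0 <- max(0L, floor(bb[2])); r1 <- min(nr - 1L, ceiling(bb[4]))
  if (c1 < c0 || r1 < r0) return(mask)
  cols <- c0:c1
  rows <- r0:r1
  pts <- cbind(rep(cols, each = length(rows)) + 0.5,
               rep(rows, times = length(cols)) + 0.5)
  inside <- rep(FALSE, nrow(pts))
  for (p in annotation@polygons) {
    inPoly <- mgcv::in.out(rbind(p$outer, p$outer[1, ]), pts)
    for (h in p$holes) {
      inPoly <- inPoly & !mgcv::in.out(rbind(h, h[1, ]), pts)
    }
    inside <- inside | inPoly
  }
  mask[cbind(rep(rows, times = length(cols)) + 1L,
             rep(cols, each = length(rows)) + 1L)] <- inside
  mask
}

#' Annotation pixel area
#'
#' @param annotation a [SlideAnnotation-class].
#' @param shape canvas shape \code{c(nrow, ncol)}.
#' @return number of pixels whose centre lies inside the annotation.
#' @export
annotationArea <- function(annotation, shape) {
  sum(rasterizeAnnotation(annotation, shape))
}
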