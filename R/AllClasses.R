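#' Marker panel
#'
#' The eight stained channels used throughout the package: pan-cytokeratin
#' (\code{PANCK}, the epithelial gate) plus the seven subtype markers.
#' \code{PanBS} is a single channel standing for the three-antibody basal
#' cocktail (KRT5, KRT14, p63).
#'
#' @return \code{panelMarkers()} returns all eight channel names;
#'   \code{subtypeMarkers()} the seven subtype markers (PANCK excluded);
#'   \code{phenotypeLevels()} the canonical phenotype order used for
#'   tie-breaking and factor levels.
#' @examples
#' panelMarkers()
#' @export
panelMarkers <- function() {
  c("PANCK", "GATA6", "CLDN18", "TFF1", "MUC16", "S100A2", "KRT17", "PanBS")
}

#' @rdname panelMarkers
#' @export
subtypeMarkers <- function() setdiff(panelMarkers(), "PANCK")

#' @rdname panelMarkers
#' @export
phenotypeLevels <- function() {
  c("Classical", "Intermediate", "Basal.MUC16", "Basal.S100A2")
}

.classicalMarkers <- c("CLDN18", "GATA6", "TFF1")

#' RigidTransform: a 2-D rigid (translation + rotation) transform
#'
#' Maps moving-image coordinates into fixed-image coordinates: a point is
#' rotated by \code{theta} degrees (counter-clockwise, about the canvas
#' centre when applied to masks, about the origin for bare point sets unless
#' a centre is supplied) and then shifted by \code{(dx, dy)} pixels.
#' Pixel coordinates are 0-based, x = column, y = row, origin top-left.
#'
#' @slot dx,dy translation in pixels.
#' @slot theta rotation in degrees, in (-180, 180].
#' @seealso [rigidTransform()], [applyTransform()], [estimateRigidTransform()]
#' @export
setClass("RigidTransform",
  representation(dx = "numeric", dy = "numeric", theta = "numeric"),
  prototype(dx = 0, dy = 0, theta = 0)
)

setValidity("RigidTransform", function(object) {
  v <- c(object@dx, object@dy, object@theta)
  if (length(object@dx) != 1L || length(object@dy) != 1L ||
      length(object@theta) != 1L) {
    return("dx, dy and theta must each have length 1")
  }
  if (!all(is.finite(v))) return("transform parameters must be finite")
  if (object@theta <= -180 || object@theta > 180) {
    return("theta must lie in (-180, 180]")
  }
  TRUE
})

#' Construct a rigid transform
#'
#' @param dx,dy translation in pixels (moving -> fixed).
#' @param theta rotation in degrees, counter-clockwise, in (-180, 180].
#' @return a [RigidTransform-class] object.
#' @examples
#' rigidTransform(5, -3, 0.5)
#' @export
rigidTransform <- function(dx = 0, dy = 0, theta = 0) {
  new("RigidTransform", dx = as.numeric(dx), dy = as.numeric(dy),
      theta = as.numeric(theta))
}

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: dx = %.3f px, dy = %.3f px, theta = %.3f deg\n",
              object@dx, object@dy, object@theta))
})

#' SlideAnnotation: tumor-region geometry in pixel coordinates
#'
#' A set of polygons (each with optional interior holes) delimiting the
#' annotated tumor area on the shared slide canvas, as exported from a
#' QuPath-style GeoJSON FeatureCollection. Coordinates are 0-based pixels,
#' x = column, y = row.
#'
#' @slot polygons list; each element is a list with \code{outer} (an n x 2
#'   matrix of x,y vertices) and \code{holes} (a possibly empty list of such
#'   matrices).
#' @seealso [readAnnotation()], [rectAnnotation()], [rasterizeAnnotation()]
#' @export
setClass("SlideAnnotation", representation(polygons = "list"))

setValidity("SlideAnnotation", function(object) {
  if (length(object@polygons) == 0L) return("annotation has no polygons")
  for (p in object@polygons) {
    if (!is.list(p) || is.null(p$outer)) return("each polygon needs an 'outer' ring")
    if (!is.matrix(p$outer) || ncol(p$outer) != 2L || nrow(p$outer) < 3L) {
      return("outer rings must be n x 2 matrices with n >= 3")
    }
    if (!all(is.finite(p$outer))) return("ring coordinates must be finite")
    for (h in p$holes) {
      if (!is.matrix(h) || ncol(h) != 2L || nrow(h) < 3L) {
        return("hole rings must be n x 2 matrices with n >= 3")
      }
    }
  }
  TRUE
})

setMethod("show", "SlideAnnotation", function(object) {
  bb <- annotationBBox(object)
  cat(sprintf("SlideAnnotation: %d polygon(s), bbox [%g, %g] x [%g, %g]\n",
              length(object@polygons), bb[1], bb[3], bb[2], bb[4]))
})

#' SlideStack: co-registered per-channel positive-pixel masks
#'
#' One binary mask per stained channel on a shared canvas, together with the
#' annotation geometry, the pixel size and (for synthetic stacks) the planted
#' ground truth. Channels stained on the same physical slide share a slide
#' id, so a registration error displaces them together.
#'
#' @slot masks named list of integer/logical matrices (rows x cols), one per
#'   channel, all the same shape, values 0/1.
#' @slot channelSlide named character; for each channel, the id of the
#'   physical slide it was stained on.
#' @slot annotation a [SlideAnnotation-class].
#' @slot mpp microns per pixel (scalar, > 0).
#' @slot groundTruth list or NULL; synthetic stacks record the planted
#'   transforms, the region layout and the generating profiles here.
#' @seealso [generateSlideStack()], [quantifyTiles()]
#' @export
setClass("SlideStack",
  representation(masks = "list", channelSlide = "character",
                 annotation = "SlideAnnotation", mpp = "numeric",
                 groundTruth = "ANY")
)

setValidity("SlideStack", function(object) {
  if (length(object@masks) == 0L) return("no channel masks")
  if (is.null(names(object@masks)) || any(names(object@masks) == "")) {
    return("masks must be named by channel")
  }
  dims <- vapply(object@masks, function(m) dim(m), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    return("all channel masks must share the same canvas shape")
  }
  for (m in object@masks) {
    if (!all(m %in% c(0L, 1L, TRUE, FALSE))) return("masks must be binary")
  }
  if (!setequal(names(object@channelSlide), names(object@masks))) {
    return("channelSlide must name exactly the mask channels")
  }
  if (length(object@mpp) != 1L || !is.finite(object@mpp) || object@mpp <= 0) {
    return("mpp must be a positive scalar")
  }
  TRUE
})

setMethod("show", "SlideStack", function(object) {
  d <- dim(object@masks[[1]])
  cat(sprintf("SlideStack: %d channels on a %d x %d canvas, %.3g um/px\n",
              length(object@masks), d[1], d[2], object@mpp))
  cat("  channels:", paste(names(object@masks), collapse = ", "), "\n")
  if (!is.null(object@groundTruth)) cat("  carries synthetic ground truth\n")
})

#' TileTable: per-tile marker proportions
#'
#' One row per tile: tumor/slide ids, grid position, pixel bounding box
#' (0-based, half-open), the fraction of the tile inside the annotation, the
#' truncation flag, and one column per channel with the positive-pixel
#' proportion in [0, 1].
#'
#' @slot tiles data.frame with columns \code{tile_id, tumor_id, slide_id,
#'   row, col, x0, y0, x1, y1, inside_fraction, truncated} and one numeric
#'   column per marker in [markers()].
#' @slot markers character; the marker columns present.
#' @seealso [quantifyTiles()], [filterTiles()], [generateTileTable()]
#' @export
setClass("TileTable", representation(tiles = "data.frame", markers = "character"))

.tileGeomCols <- c("tile_id", "tumor_id", "slide_id", "row", "col",
                   "x0", "y0", "x1", "y1", "inside_fraction", "truncated")

setValidity("TileTable", function(object) {
  df <- object@tiles
  miss <- setdiff(c(.tileGeomCols, object@markers), names(df))
  if (length(miss)) {
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(df$tile_id)) return("tile ids must be unique")
  for (m in object@markers) {
    v <- df[[m]]
    if (any(!is.finite(v)) || any(v < 0 | v > 1)) {
      return(sprintf("marker proportions for %s must lie in [0, 1]", m))
    }
  }
  if (any(df$inside_fraction < 0 | df$inside_fraction > 1)) {
    return("inside_fraction must lie in [0, 1]")
  }
  TRUE
})

#' @describeIn TileTable-class number of tiles.
#' @param x,object a TileTable.
#' @export
setMethod("nrow", "TileTable", function(x) nrow(x@tiles))

setMethod("show", "TileTable", function(object) {
  cat(sprintf("TileTable: %d tiles, %d tumors, markers: %s\n",
              nrow(object@tiles), length(unique(object@tiles$tumor_id)),
              paste(object@markers, collapse = ", ")))
  cat(sprintf("  truncated: %d; PANCK > 0.1: %d\n",
              sum(object@tiles$truncated),
              if ("PANCK" %in% object@markers) sum(object@tiles$PANCK > 0.1) else NA_integer_))
})

#' Accessors for TileTable
#'
#' \code{markers()} returns the marker column names; \code{markerMatrix()}
#' the tiles x markers numeric matrix (rownames = tile ids);
#' \code{tileInfo()} the geometry columns as a data.frame;
#' \code{as.data.frame} the full table.
#'
#' @param x a [TileTable-class].
#' @param ... unused.
#' @return see description.
#' @export
setGeneric("markers", function(x, ...) standardGeneric("markers"))

#' @rdname markers
#' @export
setMethod("markers", "TileTable", function(x, ...) x@markers)

#' @rdname markers
#' @export
setGeneric("markerMatrix", function(x, ...) standardGeneric("markerMatrix"))

#' @rdname markers
#' @export
setMethod("markerMatrix", "TileTable", function(x, ...) {
  m <- as.matrix(x@tiles[, x@markers, drop = FALSE])
  rownames(m) <- x@tiles$tile_id
  m
})

#' @rdname markers
#' @export
setGeneric("tileInfo", function(x, ...) standardGeneric("tileInfo"))

#' @rdname markers
#' @export
setMethod("tileInfo", "TileTable", function(x, ...) {
  x@tiles[, .tileGeomCols, drop = FALSE]
})

#' @rdname markers
#' @param row.names,optional passed for S3 compatibility, unused.
#' @export
as.data.frame.TileTable <- function(x, row.names = NULL, optional = FALSE, ...) {
  x@tiles
}

setMethod("as.data.frame", "TileTable", as.data.frame.TileTable)

#' Build a TileTable from a data.frame
#'
#' @param tiles data.frame with the geometry columns and marker columns.
#' @param markers marker column names; defaults to the panel channels found
#'   in \code{tiles}.
#' @return a [TileTable-class].
#' @export
tileTable <- function(tiles, markers = intersect(panelMarkers(), names(tiles))) {
  tiles <- as.data.frame(tiles)
  tiles$truncated <- as.logical(tiles$truncated)
  new("TileTable", tiles = tiles, markers = markers)
}

#' FeatureMatrix: PCA-reduced log-proportion features
#'
#' Tile-level features fed to clustering: PCA scores of the centred
#' log2(proportion + epsilon) of the seven subtype markers, keeping the
#' components whose explained-variance ratio exceeds the configured
#' threshold. Component signs follow a fixed convention (the loading of
#' largest magnitude is positive) so results are reproducible.
#'
#' @slot scores tiles x components numeric matrix, rownames = tile ids.
#' @slot explainedVariance explained-variance ratio of each retained
#'   component.
#' @slot epsilon the log pseudo-count used.
#' @slot center the column means removed before PCA (log scale).
#' @slot rotation the loading matrix of retained components.
#' @seealso [preprocessFeatures()]
#' @export
setClass("FeatureMatrix",
  representation(scores = "matrix", explainedVariance = "numeric",
                 epsilon = "numeric", center = "numeric", rotation = "matrix")
)

setValidity("FeatureMatrix", function(object) {
  if (ncol(object@scores) < 1L) return("at least one component must be retained")
  if (ncol(object@scores) != length(object@explainedVariance)) {
    return("explainedVariance must match score columns")
  }
  if (object@epsilon <= 0) return("epsilon must be positive")
  TRUE
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d tiles x %d components (evr: %s), epsilon = %g\n",
              nrow(object@scores), ncol(object@scores),
              paste(sprintf("%.3f", object@explainedVariance), collapse = ", "),
              object@epsilon))
})

#' PhenotypeModel: fitted tile-phenotype clusters
#'
#' @slot k number of clusters.
#' @slot centroidsPCA k x components centroid matrix in feature space.
#' @slot centroidsRaw k x markers matrix of mean raw proportions per cluster
#'   (all panel channels), entries in [0, 1].
#' @slot clusterNames character of length k: each cluster's phenotype name
#'   (one of [phenotypeLevels()] or \code{"Unassigned"}); names other than
#'   Unassigned are unique.
#' @slot seed the master seed used for the k-means fit.
#' @seealso [fitPhenotypes()]
#' @export
setClass("PhenotypeModel",
  representation(k = "integer", centroidsPCA = "matrix", centroidsRaw = "matrix",
                 clusterNames = "character", seed = "integer")
)

setValidity("PhenotypeModel", function(object) {
  if (object@k < 1L) return("k must be >= 1")
  if (nrow(object@centroidsPCA) != object@k) return("centroidsPCA must have k rows")
  if (nrow(object@centroidsRaw) != object@k) return("centroidsRaw must have k rows")
  if (length(object@clusterNames) != object@k) return("need one name per cluster")
  named <- object@clusterNames[object@clusterNames != "Unassigned"]
  if (anyDuplicated(named)) return("phenotype names must be unique")
  if (!all(named %in% phenotypeLevels())) {
    return("names must be canonical phenotypes or 'Unassigned'")
  }
  rw <- object@centroidsRaw
  if (any(rw < -1e-9 | rw > 1 + 1e-9)) return("raw centroids must lie in [0, 1]")
  TRUE
})

setMethod("show", "PhenotypeModel", function(object) {
  cat(sprintf("PhenotypeModel: k = %d (seed %d)\n", object@k, object@seed))
  top <- apply(object@centroidsRaw[, setdiff(colnames(object@centroidsRaw), "PANCK"),
                                   drop = FALSE], 1, function(r) {
    names(r)[which.max(r)]
  })
  for (i in seq_len(object@k)) {
    cat(sprintf("  cluster %d -> %-13s (top marker %s)\n", i,
                object@clusterNames[i], top[i]))
  }
})

#' TumorComposition: per-tumor phenotype proportions and calls
#'
#' One row per tumor. Proportion columns (one per phenotype) sum to 1;
#' \code{present.*} flags are strict \code{> presenceMin} calls;
#' \code{predominant} is the argmax phenotype (ties broken in
#' [phenotypeLevels()] order) and \code{predominance_strict} records whether
#' it exceeds the predominance threshold; \code{basal_present} flags a summed
#' basal (Basal.MUC16 + Basal.S100A2) proportion strictly above the presence
#' threshold.
#'
#' @slot table data.frame as described.
#' @slot presenceMin,predominanceMin the thresholds used.
#' @seealso [composeTumors()]
#' @export
setClass("TumorComposition",
  representation(table = "data.frame", presenceMin = "numeric",
                 predominanceMin = "numeric")
)

setValidity("TumorComposition", function(object) {
  df <- object@table
  need <- c("tumor_id", "n_tiles", phenotypeLevels(),
            paste0("present.", phenotypeLevels()),
            "predominant", "predominance_strict", "basal_present")
  miss <- setdiff(need, names(df))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  s <- rowSums(df[, phenotypeLevels(), drop = FALSE])
  if (nrow(df) && any(abs(s - 1) > 1e-9)) {
    return("phenotype proportions must sum to 1 within 1e-9")
  }
  TRUE
})

setMethod("show", "TumorComposition", function(object) {
  cat(sprintf("TumorComposition: %d tumors (presence > %g, predominance > %g)\n",
              nrow(object@table), object@presenceMin, object@predominanceMin))
  cat(sprintf("  basal-present: %d\n", sum(object@table$basal_present)))
})

#' @describeIn TumorComposition-class the composition table as a data.frame.
#' @param x a TumorComposition.
#' @param row.names,optional,... S3 compatibility, unused.
#' @export
as.data.frame.TumorComposition <- function(x, row.names = NULL, optional = FALSE, ...) {
  x@table
}

setMethod("as.data.frame", "TumorComposition", as.data.frame.TumorComposition)
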