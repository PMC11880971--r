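#' Read a QuPath-style GeoJSON annotation
#'
#' Parses a FeatureCollection of Polygon/MultiPolygon features in pixel
#' coordinates. The first ring of each polygon is the outer boundary,
#' subsequent rings are holes. Rings with fewer than three distinct
#' vertices are rejected (\code{strict = TRUE}, default) or dropped.
#'
#' @param path GeoJSON file path.
#' @param strict reject (TRUE) or silently drop (FALSE) degenerate rings.
#' @return a [SlideAnnotation-class].
#' @export
readAnnotation <- function(path, strict = TRUE) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$type) || j$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection")
  }
  if (length(j$features) == 0L) stop("empty FeatureCollection")
  ringToMat <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p)[1:2])))
    m <- .closeRing(m)
    if (nrow(unique(m)) < 3L) {
      if (strict) stop("degenerate ring (fewer than 3 distinct vertices)")
      return(NULL)
    }
    m
  }
  polyFromRings <- function(rings) {
    mats <- lapply(rings, ringToMat)
    mats <- mats[!vapply(mats, is.null, logical(1))]
    if (length(mats) == 0L) return(NULL)
    list(outer = mats[[1]], holes = mats[-1])
  }
  polys <- list()
  for (ft in j$features) {
    g <- ft$geometry
    if (is.null(g$type)) stop("feature without geometry")
    if (g$type == "Polygon") {
      p <- polyFromRings(g$coordinates)
      if (!is.null(p)) polys[[length(polys) + 1L]] <- p
    } else if (g$type == "MultiPolygon") {
      for (rings in g$coordinates) {
        p <- polyFromRings(rings)
        if (!is.null(p)) polys[[length(polys) + 1L]] <- p
      }
    } else {
      stop("non-polygon geometry: ", g$type)
    }
  }
  if (length(polys) == 0L) stop("no usable polygons in annotation")
  new("SlideAnnotation", polygons = polys)
}

#' Write an annotation as GeoJSON
#'
#' @param annotation a [SlideAnnotation-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotation <- function(annotation, path) {
  feat <- lapply(annotation@polygons, function(p) {
    closeIt <- function(m) {
      m <- rbind(m, m[1, ])
      lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
    }
    list(type = "Feature", properties = list(objectType = "annotation"),
         geometry = list(type = "Polygon",
                         coordinates = c(list(closeIt(p$outer)),
                                         lapply(p$holes, closeIt))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read/write a binary channel mask as TIFF or PNG
#'
#' 8-bit single-channel images; any nonzero pixel reads back as 1.
#'
#' @param mask binary matrix.
#' @param path file path ending in \code{.tif}, \code{.tiff} or \code{.png}.
#' @return \code{readMask} returns an integer 0/1 matrix;
#'   \code{writeMask} returns \code{path} invisibly.
#' @export
writeMask <- function(mask, path) {
  img <- (mask != 0) + 0
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(img, path)
  } else {
    stop("unsupported mask format: .", ext)
  }
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else
    if (ext == "png") png::readPNG(path) else
      stop("unsupported mask format: .", ext)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  (img > 0.5) + 0L
}

#' Write/read a slide stack on disk
#'
#' One mask image per channel, a GeoJSON annotation, and a JSON sidecar with
#' the pixel size, the channel-slide map and (for synthetic stacks) the
#' planted ground truth.
#'
#' @param stack a [SlideStack-class].
#' @param dir output directory (created if needed).
#' @param format \code{"png"} (default) or \code{"tiff"}.
#' @return \code{dir}, invisibly; \code{readSlideStack} returns a
#'   [SlideStack-class] (without synthetic profiles, which are not
#'   serialized — only the planted transforms are).
#' @export
writeSlideStack <- function(stack, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "png") "png" else "tif"
  for (ch in names(stack@masks)) {
    writeMask(stack@masks[[ch]], file.path(dir, paste0(ch, ".", ext)))
  }
  writeAnnotation(stack@annotation, file.path(dir, "annotation.geojson"))
  gt <- stack@groundTruth
  side <- list(mpp = stack@mpp,
               channels = names(stack@masks),
               channelSlide = as.list(stack@channelSlide),
               format = ext,
               transforms = if (is.null(gt)) NULL else
                 lapply(gt$transforms, function(t)
                   list(dx = t@dx, dy = t@dy, theta = t@theta)))
  jsonlite::write_json(side, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname writeSlideStack
#' @export
readSlideStack <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "stack.json"))
  masks <- lapply(side$channels, function(ch) {
    readMask(file.path(dir, paste0(ch, ".", side$format)))
  })
  names(masks) <- unlist(side$channels)
  gt <- NULL
  if (!is.null(side$transforms)) {
    gt <- list(transforms = lapply(side$transforms, function(t)
      rigidTransform(t$dx, t$dy, t$theta)))
  }
  new("SlideStack", masks = masks,
      channelSlide = unlist(side$channelSlide),
      annotation = readAnnotation(file.path(dir, "annotation.geojson")),
      mpp = side$mpp, groundTruth = gt)
}

#' Write/read a TileTable as CSV
#'
#' Proportions are serialized with full precision (15 significant digits);
#' the round trip preserves every field.
#'
#' @param x a [TileTable-class].
#' @param path CSV path.
#' @return \code{readTileTable} returns a [TileTable-class];
#'   \code{writeTileTable} returns \code{path} invisibly.
#' @export
writeTileTable <- function(x, path) {
  df <- x@tiles
  for (m in x@markers) df[[m]] <- formatC(df[[m]], digits = 15, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTileTable
#' @export
readTileTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mk <- intersect(panelMarkers(), names(df))
  miss <- setdiff(panelMarkers(), mk)
  if (length(miss)) {
    stop("tile table missing marker column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$tile_id)) stop("duplicate tile ids")
  tileTable(df, markers = mk)
}

#' Serialize a fitted phenotype model as JSON
#'
#' @param model a [PhenotypeModel-class].
#' @param path JSON path.
#' @return \code{readPhenotypeModel} returns a [PhenotypeModel-class].
#' @export
writePhenotypeModel <- function(model, path) {
  jsonlite::write_json(
    list(k = model@k,
         clusterNames = model@clusterNames,
         centroidsPCA = model@centroidsPCA,
         centroidsRaw = model@centroidsRaw,
         markers = colnames(model@centroidsRaw),
         seed = model@seed),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname writePhenotypeModel
#' @export
readPhenotypeModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cr <- as.matrix(j$centroidsRaw)
  colnames(cr) <- j$markers
  new("PhenotypeModel", k = as.integer(j$k),
      centroidsPCA = as.matrix(j$centroidsPCA),
      centroidsRaw = cr,
      clusterNames = j$clusterNames, seed = as.integer(j$seed))
}

#' Run manifest
#'
#' Records the configuration snapshot, input file hashes, package version,
#' master seed and a timestamp alongside every pipeline run.
#'
#' @param cfg an [analysisConfig()].
#' @param inputs character vector of input paths to hash (md5).
#' @param seed master seed.
#' @return a list of class \code{RunManifest}.
#' @export
runManifest <- function(cfg, inputs = character(0), seed = cfg$seed) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  structure(list(config = unclass(cfg),
                 inputs = hashes,
                 package_version = as.character(utils::packageVersion("tilePheno")),
                 seed = as.integer(seed),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "RunManifest")
}

#' @rdname runManifest
#' @param manifest a RunManifest.
#' @param path JSON output path.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
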