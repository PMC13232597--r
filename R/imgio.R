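# Image, ROI and measurement I/O.
#
# Calibration contract: every CalibratedImage carries pixel_size_um (um per
# pixel edge, > 0); all polygon coordinates and all area/length parameters
# downstream are micrometres, converted as um = px * pixel_size_um.

#' Construct a calibrated multi-channel image
#'
#' @param channels Named list of numeric matrices (one per channel), all of
#'   identical dimension, intensities in relative fluorescence units (RFU,
#'   non-negative).
#' @param pixel_size_um Micrometres per pixel edge (> 0).
#' @param image_id Identifier used in measurement tables.
#' @return An object of class `CalibratedImage`.
#' @export
calibrated_image <- function(channels, pixel_size_um, image_id = "image") {
  if (!is.list(channels) || !length(channels)) {
    stop("'channels' must be a non-empty named list of matrices")
  }
  if (is.null(names(channels)) || anyNA(names(channels)) ||
      any(names(channels) == "") || anyDuplicated(names(channels))) {
    stop("channels must have unique non-empty names")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1)))) {
    stop("each channel must be a matrix")
  }
  d0 <- dims[[1]]
  if (!all(vapply(dims, function(d) all(d == d0), logical(1)))) {
    stop("all channels must share dimensions")
  }
  if (any(d0 == 0)) stop("zero-sized image")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("missing calibration: pixel_size_um must be a single positive number")
  }
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1)))) {
    stop("intensities must be non-negative")
  }
  structure(list(channels = channels,
                 channel_names = names(channels),
                 pixel_size_um = pixel_size_um,
                 height_px = d0[1], width_px = d0[2],
                 image_id = image_id),
            class = "CalibratedImage")
}

#' @export
print.CalibratedImage <- function(x, ...) {
  cat(sprintf("CalibratedImage '%s': %d x %d px @ %g um/px, channels: %s\n",
              x$image_id, x$width_px, x$height_px, x$pixel_size_um,
              paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' Extract one channel of a CalibratedImage
#' @param img A `CalibratedImage`.
#' @param name Channel name.
#' @return Numeric matrix.
#' @export
get_channel <- function(img, name) {
  stopifnot(inherits(img, "CalibratedImage"))
  if (!name %in% img$channel_names) {
    stop(sprintf("channel '%s' not present (have: %s)", name,
                 paste(img$channel_names, collapse = ", ")))
  }
  img$channels[[name]]
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a calibrated image from TIFF
#'
#' Pages of a multi-page TIFF become channels. Calibration is taken, in
#' order of precedence, from `pixel_size_override`, a JSON sidecar written
#' by [write_image()], or the TIFF resolution tags; if none is available
#' the read fails, because downstream measurements are meaningless without
#' a pixel size. Channel names come from the sidecar or default to
#' `ch0..chN`.
#'
#' @param path TIFF file path.
#' @param pixel_size_override Optional um/px, overriding file metadata.
#' @param channel_names Optional character vector naming the pages.
#' @param image_id Identifier; defaults to the file name.
#' @return A `CalibratedImage` with intensities in RFU.
#' @export
read_image <- function(path, pixel_size_override = NULL,
                       channel_names = NULL, image_id = NULL) {
  if (!file.exists(path)) stop(sprintf("unreadable file: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE,
                                   as.is = TRUE),
                    error = function(e) stop(sprintf(
                      "unreadable file: %s (%s)", path, conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  if (!length(pages)) stop("zero-sized image")
  meta <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- tryCatch(jsonlite::read_json(sp, simplifyVector = TRUE),
                     error = function(e) NULL)
  }
  pixel_size <- pixel_size_override
  if (is.null(pixel_size) && !is.null(meta$pixel_size_um)) {
    pixel_size <- as.numeric(meta$pixel_size_um)
  }
  if (is.null(pixel_size)) {
    a <- attributes(pages[[1]])
    if (!is.null(a$x.resolution) && is.finite(a$x.resolution) &&
        a$x.resolution > 0) {
      unit_um <- switch(if (is.null(a$resolution.unit)) "inch"
                        else a$resolution.unit,
                        cm = 1e4, inch = 25400, NA_real_)
      if (is.finite(unit_um)) pixel_size <- unit_um / a$x.resolution
    }
  }
  if (is.null(pixel_size)) {
    stop("missing calibration: no pixel size in metadata and no override given")
  }
  if (is.null(channel_names)) {
    if (!is.null(meta$channel_names) &&
        length(meta$channel_names) == length(pages)) {
      channel_names <- as.character(meta$channel_names)
    } else {
      channel_names <- paste0("ch", seq_along(pages) - 1L)
    }
  }
  if (length(channel_names) != length(pages)) {
    stop("channel_names length must match the number of pages")
  }
  chans <- lapply(pages, function(p) {
    m <- unclass(p)
    attributes(m) <- list(dim = dim(p))
    # drop an RGB(A) third dimension by taking the first plane
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m
  })
  names(chans) <- channel_names
  if (is.null(image_id)) image_id <- sub("\\.[^.]*$", "", basename(path))
  calibrated_image(chans, pixel_size, image_id = image_id)
}

#' Write a calibrated image to a 16-bit multi-page TIFF
#'
#' Intensities are stored as 16-bit samples (values clamped to
#' `[0, 65535]` and rounded); pixel size and channel names go to a JSON
#' sidecar `<path>.json`, which [read_image()] picks up automatically.
#'
#' @param img A `CalibratedImage`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "CalibratedImage"))
  pages <- lapply(img$channels, function(ch) {
    pmin(pmax(round(ch), 0), 65535) / 65535
  })
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(list(pixel_size_um = img$pixel_size_um,
                            channel_names = img$channel_names),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct an ROI set
#'
#' @param polygons List of polygons, each an n x 2 vertex matrix or a
#'   list(outer, holes) as produced by [mask_to_polygons()]; coordinates
#'   in um.
#' @param class_label Character vector of region classes, one per polygon
#'   (conventionally `tubule`, `tissue`, `background`).
#' @param image_id Source image identifier.
#' @param roi_id Optional identifiers; defaults to `roi_1..roi_n`.
#' @return An object of class `ROISet`; areas and perimeters are computed
#'   from the geometry.
#' @export
roi_set <- function(polygons, class_label, image_id = "image",
                    roi_id = NULL) {
  stopifnot(length(polygons) == length(class_label))
  polygons <- lapply(polygons, function(p) {
    if (is.matrix(p)) list(outer = p, holes = list()) else p
  })
  if (is.null(roi_id)) {
    roi_id <- if (length(polygons)) paste0("roi_", seq_along(polygons))
              else character(0)
  }
  structure(list(polygons = polygons,
                 class_label = as.character(class_label),
                 roi_id = as.character(roi_id),
                 area_um2 = vapply(polygons, poly_area, numeric(1)),
                 perimeter_um = vapply(polygons, poly_perimeter, numeric(1)),
                 image_id = image_id),
            class = "ROISet")
}

#' @export
length.ROISet <- function(x) length(x$polygons)

#' @export
print.ROISet <- function(x, ...) {
  cat(sprintf("ROISet '%s': %d ROIs (%s)\n", x$image_id, length(x),
              paste(sprintf("%s: %d", names(table(x$class_label)),
                            table(x$class_label)), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.ROISet <- function(x, ...) {
  data.frame(image_id = rep(x$image_id, length(x)),
             roi_id = x$roi_id,
             class = x$class_label,
             area_um2 = x$area_um2,
             perimeter_um = x$perimeter_um,
             stringsAsFactors = FALSE)
}

#' Subset an ROISet
#' @param x An `ROISet`.
#' @param i Indices or logical vector.
#' @export
subset_rois <- function(x, i) {
  stopifnot(inherits(x, "ROISet"))
  if (is.logical(i)) i <- which(i)
  roi_set(x$polygons[i], x$class_label[i], image_id = x$image_id,
          roi_id = x$roi_id[i])
}

close_ring <- function(ring) rbind(ring, ring[1, , drop = FALSE])

#' Write an ROI set as GeoJSON
#'
#' Emits an RFC 7946 FeatureCollection of Polygons; coordinates are
#' micrometres in the raster frame (x right, y down), recorded in the
#' collection's `crs_note` property. The class label is stored in each
#' feature's `properties.class`.
#'
#' @param rois An `ROISet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rois_geojson <- function(rois, path) {
  stopifnot(inherits(rois, "ROISet"))
  features <- lapply(seq_len(length(rois)), function(i) {
    poly <- rois$polygons[[i]]
    coords <- c(list(close_ring(poly$outer)),
                lapply(poly$holes, close_ring))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = coords),
         properties = list(class = rois$class_label[i],
                           roi_id = rois$roi_id[i],
                           image_id = rois$image_id,
                           area_um2 = rois$area_um2[i],
                           perimeter_um = rois$perimeter_um[i]))
  })
  obj <- list(type = "FeatureCollection",
              crs_note = "coordinates in micrometres, y-down raster frame",
              features = features)
  ok <- tryCatch({
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop(sprintf("unwritable path: %s", path))
  invisible(path)
}

#' Read an ROI set from GeoJSON
#'
#' Areas and perimeters are recomputed from the geometry, not trusted from
#' the file.
#'
#' @param path GeoJSON FeatureCollection of Polygons; every feature must
#'   carry a `class` property.
#' @param image_id Optional identifier override.
#' @return An `ROISet`.
#' @export
read_rois_geojson <- function(path, image_id = NULL) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection")
  }
  feats <- gj$features
  polys <- vector("list", length(feats))
  cls <- character(length(feats))
  ids <- character(length(feats))
  img <- image_id
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    g <- f$geometry
    if (is.null(g$type) || g$type != "Polygon") {
      stop(sprintf("feature %d: non-polygon geometry '%s'", i,
                   if (is.null(g$type)) "<none>" else g$type))
    }
    if (is.null(f$properties$class)) {
      stop(sprintf("feature %d: missing class property", i))
    }
    rings <- lapply(g$coordinates, function(rg) {
      m <- do.call(rbind, lapply(rg, function(v) as.numeric(unlist(v))))
      colnames(m) <- c("x", "y")
      if (nrow(m) > 1 && all(abs(m[1, ] - m[nrow(m), ]) < 1e-12)) {
        m <- m[-nrow(m), , drop = FALSE]
      }
      m
    })
    polys[[i]] <- list(outer = rings[[1]],
                       holes = if (length(rings) > 1) rings[-1] else list())
    cls[i] <- as.character(f$properties$class)
    ids[i] <- if (!is.null(f$properties$roi_id)) {
      as.character(f$properties$roi_id)
    } else sprintf("roi_%d", i)
    if (is.null(img) && !is.null(f$properties$image_id)) {
      img <- as.character(f$properties$image_id)
    }
  }
  roi_set(polys, cls, image_id = if (is.null(img)) "image" else img,
          roi_id = ids)
}

#' Write a measurement table as CSV
#'
#' Plain RFC 4180 CSV, UTF-8, one header row, columns in the order given.
#'
#' @param table A data.frame (annotation or detection measurements).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  stopifnot(is.data.frame(table))
  ok <- tryCatch({
    utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("unwritable path: %s", path))
  invisible(path)
}

#' Read a measurement table written by [write_measurements()]
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_measurements <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                  check.names = FALSE)
}
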