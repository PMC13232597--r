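# Nucleus segmentation (watershed on the counterstain) and cell expansion.

#' Watershed segmentation configuration
#'
#' @param blur_sigma_um Gaussian pre-smoothing of the counterstain, um.
#' @param threshold_method `otsu` (computed within the ROI) or `fixed`.
#' @param fixed_threshold_rfu Foreground threshold when
#'   `threshold_method = "fixed"`.
#' @param min_seed_separation_um Minimum separation of watershed seeds;
#'   closer distance-transform maxima are merged.
#' @param seed_tolerance Depth (in distance-transform pixels) below
#'   which a saddle between two maxima merges them. Kept small: distinct
#'   maxima separated by `min_seed_separation_um` are seeds even when a
#'   bright neighbour's blur skirt makes the saddle shallow.
#' @param nucleus_area_um2 Accepted nucleus area range (um^2); excludes
#'   debris and unsplit clumps.
#' @param cell_expansion_um Distance nuclei are dilated to estimate the
#'   cell boundary (Voronoi-partitioned so cells never overlap).
#' @param stat_erosion_um Nuclear intensity statistics are measured on
#'   the nucleus mask eroded by this distance (when the eroded mask is
#'   non-empty), which avoids partial-volume dilution where the
#'   thresholded mask overshoots the nuclear rim; geometry (area,
#'   polygon, centroid) always uses the full mask.
#' @return An object of class `WatershedConfig`.
#' @export
watershed_config <- function(blur_sigma_um = 1.5,
                             threshold_method = c("otsu", "fixed"),
                             fixed_threshold_rfu = NULL,
                             min_seed_separation_um = 7,
                             seed_tolerance = 0.3,
                             nucleus_area_um2 = c(10, 400),
                             cell_expansion_um = 5,
                             stat_erosion_um = 1.5) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(blur_sigma_um > 0, min_seed_separation_um > 0,
            seed_tolerance > 0,
            length(nucleus_area_um2) == 2,
            nucleus_area_um2[1] > 0,
            nucleus_area_um2[1] <= nucleus_area_um2[2],
            cell_expansion_um >= 0, stat_erosion_um >= 0)
  if (threshold_method == "fixed" &&
      (is.null(fixed_threshold_rfu) || fixed_threshold_rfu <= 0)) {
    stop("fixed threshold method needs a positive fixed_threshold_rfu")
  }
  structure(list(blur_sigma_um = blur_sigma_um,
                 threshold_method = threshold_method,
                 fixed_threshold_rfu = fixed_threshold_rfu,
                 min_seed_separation_um = min_seed_separation_um,
                 seed_tolerance = seed_tolerance,
                 nucleus_area_um2 = nucleus_area_um2,
                 cell_expansion_um = cell_expansion_um,
                 stat_erosion_um = stat_erosion_um),
            class = "WatershedConfig")
}

#' Otsu threshold of an intensity sample
#'
#' Maximises between-class variance on a fixed-width histogram;
#' deterministic.
#'
#' @param values Numeric vector (e.g. ROI pixel intensities).
#' @param n_bins Histogram resolution.
#' @return Threshold on the input scale.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- values[is.finite(values)]
  if (!length(v) || diff(range(v)) == 0) return(suppressWarnings(max(v)))
  lo <- min(v); hi <- max(v)
  h <- tabulate(pmin(n_bins, 1L + floor((v - lo) / (hi - lo) * n_bins)),
                n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  centres <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  mu <- cumsum(p * centres)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  centres[which.max(sigma_b)] + (hi - lo) / (2 * n_bins)
}

#' Segment nuclei within one ROI by watershed
#'
#' Pipeline: Gaussian blur of the counterstain; foreground threshold
#' (Otsu within the ROI, or fixed) restricted to the ROI; Euclidean
#' distance transform; watershed with seed maxima separated by at least
#' `min_seed_separation_um`; labels outside the nucleus area bounds
#' dropped.
#'
#' @param img A `CalibratedImage` containing the counterstain channel.
#' @param roi ROI polygon in um (vertex matrix or list(outer, holes)).
#' @param cfg A `WatershedConfig`.
#' @param counterstain Counterstain channel name (default `Hoechst`).
#' @return List: `labels` (integer matrix, full image size, 0 outside
#'   nuclei; labels are 1..n in raster order), `polygons`, `centroids`
#'   (n x 2 um), `areas_um2`.
#' @export
segment_nuclei_watershed <- function(img, roi, cfg = watershed_config(),
                                     counterstain = "Hoechst") {
  stopifnot(inherits(img, "CalibratedImage"))
  ch <- get_channel(img, counterstain)  # errors if counterstain missing
  px <- img$pixel_size_um
  d <- dim(ch)
  roi_mask <- rasterize_polygon(roi, d, px)
  if (!any(roi_mask)) stop("roi outside image or empty after rasterisation")

  blurred <- as.matrix(EBImage::gblur(ch, sigma = cfg$blur_sigma_um / px))
  empty <- list(labels = matrix(0L, d[1], d[2]), polygons = list(),
                centroids = matrix(numeric(0), 0, 2),
                areas_um2 = numeric(0))
  thr <- if (cfg$threshold_method == "otsu") {
    # Otsu on log intensities: robust to the long bright (mitotic) tail
    # that drags a linear-domain threshold above dim G1 nuclei
    v <- blurred[roi_mask]
    t0 <- exp(otsu_threshold(log(v[v > 0])))
    # contrast guard: on a structureless (noise-only) ROI Otsu splits
    # noise into two classes of nearly equal brightness; real nuclei are
    # several-fold brighter than the ROI background
    mu_fg <- mean(v[v > t0]); mu_bg <- mean(v[v <= t0])
    if (!is.finite(mu_fg) || !is.finite(mu_bg) ||
        mu_fg < 1.5 * mu_bg) return(empty)
    t0
  } else cfg$fixed_threshold_rfu
  fg <- blurred > thr & roi_mask
  if (!any(fg)) return(empty)

  dist <- EBImage::distmap(fg)
  sep_px <- cfg$min_seed_separation_um / px
  ws <- EBImage::watershed(dist, tolerance = cfg$seed_tolerance,
                           ext = max(1L, round(sep_px / 2)))
  ws <- matrix(as.integer(ws), d[1], d[2])

  sizes <- tabulate(ws)
  keep <- which(sizes * px^2 >= cfg$nucleus_area_um2[1] &
                sizes * px^2 <= cfg$nucleus_area_um2[2])
  if (!length(keep)) return(empty)
  # renumber kept labels by raster order of first occurrence
  inl <- which(ws > 0L)
  first_px <- vapply(split(inl, ws[inl]), min, numeric(1))
  keep <- keep[order(first_px[as.character(keep)])]
  relab <- integer(max(ws))
  relab[keep] <- seq_along(keep)
  labels <- matrix(0L, d[1], d[2])
  labels[inl] <- relab[ws[inl]]

  g <- label_geometry(labels, px)
  list(labels = labels, polygons = g$polygons, centroids = g$centroids,
       areas_um2 = g$areas_um2)
}

# polygons, centroids and areas for every positive label of a label map
label_geometry <- function(labels, px) {
  nr <- nrow(labels)
  idx <- which(labels > 0L)
  by_lab <- split(idx, labels[idx])
  n <- if (length(by_lab)) max(as.integer(names(by_lab))) else 0L
  polys <- vector("list", n)
  cents <- matrix(NA_real_, n, 2)
  areas <- numeric(n)
  for (nm in names(by_lab)) {
    l <- as.integer(nm)
    sel <- by_lab[[nm]]
    r <- ((sel - 1L) %% nr) + 1L
    c <- ((sel - 1L) %/% nr) + 1L
    cents[l, ] <- c(mean(c - 0.5) * px, mean(r - 0.5) * px)
    areas[l] <- length(sel) * px^2
    rr <- range(r); cc <- range(c)
    sub <- matrix(FALSE, rr[2] - rr[1] + 3L, cc[2] - cc[1] + 3L)
    sub[cbind(r - rr[1] + 2L, c - cc[1] + 2L)] <- TRUE
    pg <- mask_to_polygons(sub, px)[[1]]
    off <- c((cc[1] - 2L) * px, (rr[1] - 2L) * px)
    pg$outer <- sweep(pg$outer, 2, -off)
    pg$holes <- lapply(pg$holes, function(h) sweep(h, 2, -off))
    polys[[l]] <- pg
  }
  list(polygons = polys, centroids = cents, areas_um2 = areas)
}

#' Expand nuclei to cell boundaries
#'
#' Each nucleus is dilated by `expansion_um`, clipped to the ROI, and the
#' expansion region is partitioned by nearest nucleus (Voronoi propagation),
#' so cells within an ROI never overlap and each cell contains its nucleus.
#'
#' @param labels Integer nucleus label matrix (0 = background).
#' @param roi_mask Logical matrix delimiting the ROI (cells are clipped to
#'   it); `NULL` for no clipping.
#' @param expansion_um Expansion distance in um (>= 0).
#' @param pixel_size_um Calibration.
#' @return Integer cell label matrix, same labels as the nuclei.
#' @export
expand_cells <- function(labels, roi_mask, expansion_um, pixel_size_um) {
  if (expansion_um < 0) stop("negative expansion")
  if (expansion_um == 0) return(labels)
  nuc <- labels > 0
  if (!any(nuc)) return(labels)
  halo <- EBImage::distmap(!nuc) <= expansion_um / pixel_size_um
  if (!is.null(roi_mask)) halo <- halo & (roi_mask | nuc)
  cells <- EBImage::propagate(matrix(0, nrow(labels), ncol(labels)),
                              seeds = labels, mask = halo | nuc)
  matrix(as.integer(cells), nrow(labels), ncol(labels))
}

label_stats <- function(values, labels, n) {
  idx <- labels > 0
  v <- values[idx]; l <- labels[idx]
  out <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("mean", "sd", "max", "sum")))
  if (!length(v)) return(out)
  s <- rowsum(v, l); cnt <- rowsum(rep(1, length(v)), l)
  li <- as.integer(rownames(s))
  out[li, "sum"] <- s
  out[li, "mean"] <- s / cnt
  out[li, "max"] <- vapply(split(v, l), max, numeric(1))
  sq <- rowsum(v^2, l)
  var <- (sq - s^2 / cnt) / pmax(cnt - 1, 1)
  out[li, "sd"] <- sqrt(pmax(var, 0))
  out
}

# erode every label by one pixel (8-neighbourhood); labels whose eroded
# mask would be empty keep their full mask
erode_labels <- function(labels, iterations = 1L) {
  if (iterations <= 0L) return(labels)
  out <- labels
  nr <- nrow(labels); nc <- ncol(labels)
  for (it in seq_len(iterations)) {
    pad <- matrix(0L, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- out
    core <- out
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
      core[nb != out] <- 0L
    }
    # restore labels that vanished entirely
    gone <- setdiff(unique(out[out > 0L]), unique(core[core > 0L]))
    if (length(gone)) core[out %in% gone] <- out[out %in% gone]
    out <- core
  }
  out
}

#' Detect cells in tubule ROIs
#'
#' Runs nucleus segmentation and cell expansion per tubule ROI and
#' measures per-channel nuclear and cytosolic intensity statistics.
#' Detections are only produced inside ROIs of class `tubule`.
#'
#' @param img A `CalibratedImage`.
#' @param rois An `ROISet`; only `tubule`-class entries are processed.
#' @param backend `watershed`, or `plugin` with `plugin_fun` supplied.
#' @param cfg A `WatershedConfig`.
#' @param counterstain Counterstain channel name.
#' @param plugin_fun For `backend = "plugin"` (e.g. a star-convex CNN
#'   detector adapter): `function(img, roi)` returning an integer nucleus
#'   label matrix of full image size, which then goes through the same
#'   expansion and measurement path.
#' @return A detection data.frame (class `CellDetections`), one row per
#'   cell: ids, centroid (um), areas, per-channel `<ch>_nuc_<stat>` and
#'   `<ch>_cyt_<stat>` columns (stats mean, sd, max, sum), `class` and
#'   `region` (both `NA` until classification / region assignment).
#'   Nucleus and cell polygons are attached as attributes
#'   `nucleus_polygons`, `cell_polygons`.
#' @export
detect_cells <- function(img, rois, backend = c("watershed", "plugin"),
                         cfg = watershed_config(),
                         counterstain = "Hoechst", plugin_fun = NULL) {
  backend <- match.arg(backend)
  stopifnot(inherits(img, "CalibratedImage"), inherits(rois, "ROISet"))
  if (backend == "plugin" && !is.function(plugin_fun)) {
    stop("plugin backend not installed: supply plugin_fun")
  }
  px <- img$pixel_size_um
  tub <- which(rois$class_label == "tubule")
  res <- list(); nuc_polys <- list(); cell_polys <- list()
  for (ti in tub) {
    roi <- rois$polygons[[ti]]
    roi_mask <- rasterize_polygon(roi, c(img$height_px, img$width_px), px)
    if (backend == "watershed") {
      seg <- segment_nuclei_watershed(img, roi, cfg, counterstain)
    } else {
      labels <- plugin_fun(img, roi)
      stopifnot(is.matrix(labels),
                all(dim(labels) == c(img$height_px, img$width_px)))
      labels[!roi_mask] <- 0L
      seg <- relabel_with_geometry(labels, px)
    }
    n <- nrow(seg$centroids)
    if (!n) next
    cells <- expand_cells(seg$labels, roi_mask, cfg$cell_expansion_um, px)
    nuc_stat_lab <- erode_labels(seg$labels,
                                 round(cfg$stat_erosion_um / px))
    cyt <- cells
    cyt[seg$labels > 0L] <- 0L
    st <- list()
    for (ch in img$channel_names) {
      v <- img$channels[[ch]]
      ns <- label_stats(v, nuc_stat_lab, n)
      cs <- label_stats(v, cyt, n)
      for (s in colnames(ns)) {
        st[[paste0(ch, "_nuc_", s)]] <- ns[, s]
        st[[paste0(ch, "_cyt_", s)]] <- cs[, s]
      }
    }
    cell_areas <- tabulate(cells, nbins = n) * px^2
    df <- data.frame(
      image_id = img$image_id,
      roi_id = rois$roi_id[ti],
      cell_id = sprintf("%s_c%04d", rois$roi_id[ti], seq_len(n)),
      x_um = seg$centroids[, 1], y_um = seg$centroids[, 2],
      nucleus_area_um2 = seg$areas_um2,
      cell_area_um2 = cell_areas,
      stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(st, check.names = FALSE,
                                  optional = TRUE))
    res[[length(res) + 1L]] <- df
    nuc_polys <- c(nuc_polys, stats::setNames(seg$polygons, df$cell_id))
    cp <- label_geometry(cells, px)$polygons
    cell_polys <- c(cell_polys, stats::setNames(cp, df$cell_id))
  }
  out <- if (length(res)) do.call(rbind, res) else empty_detections(img)
  rownames(out) <- NULL
  out$class <- rep(NA_character_, nrow(out))
  out$region <- rep(NA_character_, nrow(out))
  attr(out, "nucleus_polygons") <- nuc_polys
  attr(out, "cell_polygons") <- cell_polys
  attr(out, "pixel_size_um") <- px
  class(out) <- c("CellDetections", "data.frame")
  out
}

empty_detections <- function(img) {
  cols <- c("image_id", "roi_id", "cell_id", "x_um", "y_um",
            "nucleus_area_um2", "cell_area_um2",
            as.vector(outer(img$channel_names,
                            as.vector(outer(c("nuc", "cyt"),
                                            c("mean", "sd", "max", "sum"),
                                            paste, sep = "_")),
                            paste, sep = "_")))
  out <- as.data.frame(stats::setNames(
    lapply(cols, function(x) {
      if (x %in% c("image_id", "roi_id", "cell_id")) character(0)
      else numeric(0)
    }), cols), check.names = FALSE)
  out
}

# geometry for an externally-supplied label map, mirroring
# segment_nuclei_watershed's return shape (labels renumbered 1..n)
relabel_with_geometry <- function(labels, px) {
  lv <- sort(unique(labels[labels > 0L]))
  relab <- integer(max(c(labels, 1L)))
  relab[lv] <- seq_along(lv)
  lab2 <- labels
  lab2[labels > 0L] <- relab[labels[labels > 0L]]
  g <- label_geometry(lab2, px)
  list(labels = lab2, polygons = g$polygons, centroids = g$centroids,
       areas_um2 = g$areas_um2)
}
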