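# Synthetic testis immunofluorescence scenes with full ground truth.
#
# A scene emulates a prepubertal testis section: elliptical seminiferous
# tubules bounded by a bright peritubular (PTM) rim, an interstitial band
# around them, and empty background. The counterstain (Hoechst) channel
# carries nuclei whose mean intensity encodes DNA content: G1 cells draw
# from a truncated normal (peak ~9,000 RFU, range 6,000-14,000), mitotic
# cells from a uniform tail up to ~30,000 RFU. Marker channels are
# rendered into the nucleus (nuclear markers) or a cytosolic annulus.

#' Specify a synthetic scene
#'
#' Defaults describe a 384 x 384 um field at 0.5 um/px with three tubules.
#' Zone cell densities and class mixes control membrane vs luminal
#' composition; luminal germ (MAGE-A) cells are laid down in compact
#' clusters to reproduce the clustered luminal organisation seen in
#' tissue, while membrane cells are dispersed.
#'
#' @param width_px,height_px Image size in pixels.
#' @param pixel_size_um Micrometres per pixel edge.
#' @param n_tubules Number of tubules to place.
#' @param tubule_radius_um Range (min, max) of tubule semi-axes in um.
#' @param tubule_aspect Range of minor/major axis ratio.
#' @param min_gap_um Minimum clearance between tubule boundaries in um.
#' @param margin_um Clearance between tubules and the image border.
#' @param ptm_ring_width_um Width of the bright peritubular rim (part of
#'   the tubule region).
#' @param interstitium_width_um Width of the tissue band around tubules;
#'   beyond it the scene is background.
#' @param membrane_depth_um Depth of the membrane-associated zone measured
#'   inward from the tubule boundary (shared convention with
#'   [partition_tubule()]).
#' @param cell_radius_um Cell radius in um (sets the packing distance).
#' @param nucleus_radius_um Rendered nucleus radius in um (< cell
#'   radius, as in tissue, leaving resolvable gaps between nuclei).
#' @param min_sep_factor Nuclei are placed with centre distance >=
#'   `min_sep_factor * cell_radius_um`; the default 2.1 keeps nuclei
#'   non-overlapping with a small clearance, so detection tests measure
#'   detection rather than clump splitting. Values below 2 allow fused
#'   nuclei and stress the watershed.
#' @param zone_density_per_1000um2 Named vector `c(membrane=, luminal=)`:
#'   cells per 1,000 um^2 in each tubule zone.
#' @param membrane_mix,luminal_mix Named class proportions per zone (must
#'   each sum to 1). Class `other` is marker-negative (unclassified
#'   downstream).
#' @param luminal_cluster_size Luminal MAGE-A cells are placed in clusters
#'   of this size (1 disables clustering).
#' @param interstitial_density_per_1000um2 Interstitial cell density in
#'   the tissue band.
#' @param markers Named list of marker channels; each entry is a list with
#'   `compartment` ("nuclear" or "cytosolic"), `positive_classes`,
#'   `pos_mean`, `pos_sd` (positive-cell intensity draw, truncated at
#'   `pos_min`).
#' @param hoechst_g1_mean,hoechst_g1_sd,hoechst_g1_range G1 nuclear
#'   intensity distribution (truncated normal), RFU.
#' @param hoechst_mitotic_range Mitotic nuclear intensity (uniform), RFU.
#' @param mitotic_fraction Named per-class probability that a cell is
#'   mitotic; unnamed scalar applies to all germ (MAGE-A) cells.
#' @param baseline_rfu Named vector of Hoechst-channel baselines for
#'   `background`, `tissue`, `tubule`, `ptm`.
#' @param marker_baseline_rfu Named vector of marker-channel baselines for
#'   `background` and `tissue` (tubules share the tissue baseline).
#' @param noise_sd Additive Gaussian read-noise standard deviation, RFU.
#' @param blur_sigma_px Optical blur applied to every channel, px.
#' @param cytosol_width_um Width of the cytosolic annulus for cytosolic
#'   markers.
#' @param seed Integer seed; scenes are bit-reproducible given the seed.
#' @return An object of class `SceneSpec`.
#' @export
scene_spec <- function(width_px = 768L, height_px = 768L,
                       pixel_size_um = 0.5,
                       n_tubules = 3L,
                       tubule_radius_um = c(45, 62),
                       tubule_aspect = c(0.85, 1),
                       min_gap_um = 15,
                       margin_um = 8,
                       ptm_ring_width_um = 5,
                       interstitium_width_um = 45,
                       membrane_depth_um = 35,
                       cell_radius_um = 4,
                       nucleus_radius_um = 3.2,
                       min_sep_factor = 2.1,
                       zone_density_per_1000um2 = c(membrane = 7,
                                                    luminal = 4),
                       membrane_mix = c(SOX9 = 0.35, `MAGE-A` = 0.35,
                                        other = 0.30),
                       luminal_mix = c(SOX9 = 0.15, `MAGE-A` = 0.70,
                                       other = 0.15),
                       luminal_cluster_size = 5L,
                       interstitial_density_per_1000um2 = 4,
                       markers = list(
                         SOX9 = list(compartment = "nuclear",
                                     positive_classes = "SOX9",
                                     pos_mean = 9000, pos_sd = 1500,
                                     pos_min = 5000),
                         `MAGE-A` = list(compartment = "nuclear",
                                         positive_classes = "MAGE-A",
                                         pos_mean = 9000, pos_sd = 1500,
                                         pos_min = 5000)),
                       hoechst_g1_mean = 9000,
                       hoechst_g1_sd = 1500,
                       hoechst_g1_range = c(6000, 14000),
                       hoechst_mitotic_range = c(14000, 30000),
                       mitotic_fraction = c(SOX9 = 0, `MAGE-A` = 0.30,
                                            other = 0.10,
                                            interstitial = 0),
                       baseline_rfu = c(background = 200, tissue = 1300,
                                        tubule = 2400, ptm = 3000),
                       marker_baseline_rfu = c(background = 150,
                                               tissue = 400),
                       noise_sd = 60,
                       blur_sigma_px = 0.6,
                       cytosol_width_um = 3,
                       seed = 1L) {
  spec <- as.list(environment())
  stopifnot(width_px >= 16, height_px >= 16, pixel_size_um > 0,
            n_tubules >= 0, all(tubule_radius_um > 0),
            diff(range(tubule_radius_um)) >= 0,
            all(tubule_aspect > 0 & tubule_aspect <= 1),
            min_gap_um >= 0, ptm_ring_width_um > 0,
            interstitium_width_um > 0, membrane_depth_um > 0,
            cell_radius_um > 0, nucleus_radius_um > 0,
            nucleus_radius_um <= cell_radius_um, min_sep_factor > 0,
            all(zone_density_per_1000um2 >= 0),
            interstitial_density_per_1000um2 >= 0,
            noise_sd >= 0, blur_sigma_px >= 0, cytosol_width_um > 0,
            all(mitotic_fraction >= 0 & mitotic_fraction <= 1))
  if (abs(sum(membrane_mix) - 1) > 1e-8 ||
      abs(sum(luminal_mix) - 1) > 1e-8) {
    stop("class mixes must sum to 1 per zone")
  }
  if (is.null(names(membrane_mix)) || is.null(names(luminal_mix))) {
    stop("class mixes must be named")
  }
  structure(spec, class = "SceneSpec")
}

# truncated-normal draw by rejection (vectorised)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- stats::rnorm(length(todo), mean, sd)
    ok <- x >= lo & x <= hi
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

mitotic_prob <- function(spec, cls) {
  mf <- spec$mitotic_fraction
  if (is.null(names(mf))) return(unname(mf[1]))
  if (cls %in% names(mf)) unname(mf[[cls]]) else 0
}

# place tubule ellipses without overlap; error when packing is infeasible
place_tubules <- function(spec) {
  w_um <- spec$width_px * spec$pixel_size_um
  h_um <- spec$height_px * spec$pixel_size_um
  centres <- matrix(numeric(0), 0, 2)
  rx <- ry <- numeric(0)
  tries <- 0L
  max_tries <- 400L * max(1L, spec$n_tubules)
  while (nrow(centres) < spec$n_tubules) {
    if (tries >= max_tries) {
      stop(sprintf(
        "infeasible packing: placed %d of %d tubules after %d tries",
        nrow(centres), spec$n_tubules, tries))
    }
    tries <- tries + 1L
    r1 <- stats::runif(1, spec$tubule_radius_um[1], spec$tubule_radius_um[2])
    asp <- stats::runif(1, spec$tubule_aspect[1], spec$tubule_aspect[2])
    rxi <- r1; ryi <- r1 * asp
    rmax <- max(rxi, ryi)
    lo_x <- spec$margin_um + rxi; hi_x <- w_um - spec$margin_um - rxi
    lo_y <- spec$margin_um + ryi; hi_y <- h_um - spec$margin_um - ryi
    if (lo_x >= hi_x || lo_y >= hi_y) next
    cx <- stats::runif(1, lo_x, hi_x)
    cy <- stats::runif(1, lo_y, hi_y)
    if (nrow(centres)) {
      d <- sqrt((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2)
      if (any(d < pmax(rx, ry) + rmax + spec$min_gap_um)) next
    }
    centres <- rbind(centres, c(cx, cy))
    rx <- c(rx, rxi); ry <- c(ry, ryi)
  }
  list(centres = centres, rx = rx, ry = ry)
}

# sample points inside a zone of one tubule, respecting minimum separation
sample_in_zone <- function(n, tub_poly, cx, cy, rx, ry, zone, spec,
                           placed, min_sep) {
  pts <- matrix(numeric(0), 0, 2)
  clear <- spec$cell_radius_um + spec$pixel_size_um
  tries <- 0L
  while (nrow(pts) < n && tries < 60L * n) {
    tries <- tries + 1L
    x <- stats::runif(1, cx - rx, cx + rx)
    y <- stats::runif(1, cy - ry, cy + ry)
    q <- ((x - cx) / rx)^2 + ((y - cy) / ry)^2
    if (q >= 1) next
    db <- dist_to_boundary(x, y, tub_poly)
    if (db < clear) next
    in_membrane <- db <= spec$membrane_depth_um
    if ((zone == "membrane") != in_membrane) next
    all_pts <- rbind(placed, pts)
    if (nrow(all_pts)) {
      if (min((all_pts[, 1] - x)^2 + (all_pts[, 2] - y)^2) < min_sep^2) next
    }
    pts <- rbind(pts, c(x, y))
  }
  pts
}

# luminal clusters: `size` cells on a regular ring whose circumradius keeps
# every pair at least min_sep and (at the default size) within ~15 um
sample_clusters <- function(n_cells, size, tub_poly, cx, cy, rx, ry, spec,
                            placed, min_sep) {
  pts <- matrix(numeric(0), 0, 2)
  n_clusters <- ceiling(n_cells / size)
  # circumradius: adjacent cells exactly at the packing minimum, which
  # keeps the widest pair (the pentagon diagonal, ~13.6 um at defaults)
  # inside the 15 um neighbour radius with margin for centroid error
  ring_r <- min_sep / (2 * sin(pi / size))
  clear <- spec$membrane_depth_um + ring_r + spec$cell_radius_um + 1
  tries <- 0L
  while (nrow(pts) < n_cells && tries < 80L * n_clusters) {
    tries <- tries + 1L
    x <- stats::runif(1, cx - rx, cx + rx)
    y <- stats::runif(1, cy - ry, cy + ry)
    if (((x - cx) / rx)^2 + ((y - cy) / ry)^2 >= 1) next
    if (dist_to_boundary(x, y, tub_poly) < clear) next
    rot <- stats::runif(1, 0, 2 * pi)
    k <- min(size, n_cells - nrow(pts))
    th <- rot + 2 * pi * seq_len(k) / size
    jit <- stats::runif(k, -0.2, 0.2)
    cand <- cbind(x + (ring_r + jit) * cos(th),
                  y + (ring_r + jit) * sin(th))
    all_pts <- rbind(placed, pts)
    ok <- TRUE
    if (nrow(all_pts)) {
      for (i in seq_len(nrow(cand))) {
        if (min((all_pts[, 1] - cand[i, 1])^2 +
                (all_pts[, 2] - cand[i, 2])^2) < min_sep^2) {
          ok <- FALSE; break
        }
      }
    }
    if (!ok) next
    pts <- rbind(pts, cand)
  }
  pts
}

paint_disc <- function(mat, cx_px, cy_px, r_px, value) {
  nr <- nrow(mat); nc <- ncol(mat)
  r1 <- max(1L, floor(cy_px - r_px)); r2 <- min(nr, ceiling(cy_px + r_px))
  c1 <- max(1L, floor(cx_px - r_px)); c2 <- min(nc, ceiling(cx_px + r_px))
  if (r1 > r2 || c1 > c2) return(mat)
  rows <- r1:r2; cols <- c1:c2
  dy <- (rows - 0.5) - cy_px
  dx <- (cols - 0.5) - cx_px
  d2 <- outer(dy^2, dx^2, "+")
  sub <- mat[rows, cols, drop = FALSE]
  sel <- d2 <= r_px^2 & sub < value
  sub[sel] <- value
  mat[rows, cols] <- sub
  mat
}

paint_annulus <- function(mat, cx_px, cy_px, r_in_px, r_out_px, value) {
  nr <- nrow(mat); nc <- ncol(mat)
  r1 <- max(1L, floor(cy_px - r_out_px))
  r2 <- min(nr, ceiling(cy_px + r_out_px))
  c1 <- max(1L, floor(cx_px - r_out_px))
  c2 <- min(nc, ceiling(cx_px + r_out_px))
  if (r1 > r2 || c1 > c2) return(mat)
  rows <- r1:r2; cols <- c1:c2
  dy <- (rows - 0.5) - cy_px
  dx <- (cols - 0.5) - cx_px
  d2 <- outer(dy^2, dx^2, "+")
  sub <- mat[rows, cols, drop = FALSE]
  sel <- d2 <= r_out_px^2 & d2 > r_in_px^2 & sub < value
  sub[sel] <- value
  mat[rows, cols] <- sub
  mat
}

#' Generate a synthetic scene with ground truth
#'
#' Deterministic given `spec$seed`: two calls with the same spec return
#' bit-identical images and identical ground truth.
#'
#' @param spec A `SceneSpec` from [scene_spec()].
#' @param mute_markers Internal: marker channels rendered without any
#'   positive staining (used by [render_control_image()]); random draws
#'   are unchanged so geometry and the counterstain stay bit-identical.
#' @return List with elements `image` (a `CalibratedImage` whose channels
#'   are `Hoechst` plus one channel per marker) and `truth` (a
#'   `GroundTruth`: `region` integer raster with 0 = background,
#'   1 = tissue, 2 = tubule; `cells` data.frame with true class, zone,
#'   cycle state and intensity draws; `tubules` list of boundary
#'   polygons).
#' @export
generate_scene <- function(spec, mute_markers = character(0)) {
  stopifnot(inherits(spec, "SceneSpec"))
  if (length(mute_markers) &&
      !all(mute_markers %in% names(spec$markers))) {
    stop("mute_markers must be a subset of the marker channels")
  }
  set.seed(spec$seed)
  px <- spec$pixel_size_um
  nr <- spec$height_px; nc <- spec$width_px

  tubs <- place_tubules(spec)
  n_tub <- nrow(tubs$centres)
  tub_polys <- lapply(seq_len(n_tub), function(i) {
    ellipse_polygon(tubs$centres[i, 1], tubs$centres[i, 2],
                    tubs$rx[i], tubs$ry[i], n = 128L)
  })

  # region raster: tubule / tissue band / background
  tub_mask <- matrix(FALSE, nr, nc)
  for (p in tub_polys) tub_mask <- tub_mask | rasterize_polygon(p, c(nr, nc), px)
  region <- matrix(0L, nr, nc)
  if (any(tub_mask)) {
    d_out <- EBImage::distmap(1 - tub_mask) * px  # distance to tubule
    region[d_out <= spec$interstitium_width_um] <- 1L
    region[tub_mask] <- 2L
    d_in <- EBImage::distmap(tub_mask) * px       # depth inside tubule
    ptm <- tub_mask & d_in <= spec$ptm_ring_width_um
  } else {
    # tubule-free scene: a central tissue band surrounded by background
    cy <- nr / 2
    band <- abs((row(region) - cy) * px) <= spec$interstitium_width_um
    region[band] <- 1L
    ptm <- matrix(FALSE, nr, nc)
  }

  # channel baselines
  bl <- spec$baseline_rfu
  hoechst <- matrix(bl[["background"]], nr, nc)
  hoechst[region == 1L] <- bl[["tissue"]]
  hoechst[region == 2L] <- bl[["tubule"]]
  hoechst[ptm] <- bl[["ptm"]]
  mbl <- spec$marker_baseline_rfu
  marker_chan <- lapply(spec$markers, function(m) {
    ch <- matrix(mbl[["background"]], nr, nc)
    ch[region >= 1L] <- mbl[["tissue"]]
    ch
  })

  # ---- cells ----------------------------------------------------------
  min_sep <- spec$min_sep_factor * spec$cell_radius_um
  cells <- list()
  add_cells <- function(pts, cls, zone, tub_id) {
    if (!nrow(pts)) return(NULL)
    data.frame(x_um = pts[, 1], y_um = pts[, 2],
               class = cls, zone = zone, tubule_id = tub_id,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_tub)) {
    poly <- tub_polys[[i]]
    cx <- tubs$centres[i, 1]; cy <- tubs$centres[i, 2]
    rx <- tubs$rx[i]; ry <- tubs$ry[i]
    area_tot <- poly_area(poly)
    lrx <- rx - spec$membrane_depth_um; lry <- ry - spec$membrane_depth_um
    area_lum <- if (lrx > 0 && lry > 0) pi * lrx * lry else 0
    area_mem <- area_tot - area_lum
    placed <- matrix(numeric(0), 0, 2)

    # membrane zone: dispersed mixture
    n_mem <- round(spec$zone_density_per_1000um2[["membrane"]] *
                   area_mem / 1000)
    mem_cls <- if (n_mem > 0) {
      sample(names(spec$membrane_mix), n_mem, replace = TRUE,
             prob = spec$membrane_mix)
    } else character(0)
    pts <- sample_in_zone(n_mem, poly, cx, cy, rx, ry, "membrane", spec,
                          placed, min_sep)
    mem_cls <- mem_cls[seq_len(nrow(pts))]
    cells[[length(cells) + 1L]] <- add_cells(pts, mem_cls, "membrane", i)
    placed <- rbind(placed, pts)

    if (area_lum > 0) {
      n_lum <- round(spec$zone_density_per_1000um2[["luminal"]] *
                     area_lum / 1000)
      lum_cls <- if (n_lum > 0) {
        sample(names(spec$luminal_mix), n_lum, replace = TRUE,
               prob = spec$luminal_mix)
      } else character(0)
      n_ga <- sum(lum_cls == "MAGE-A")
      n_rest <- n_lum - n_ga
      # clustered luminal germ cells
      if (n_ga > 0 && spec$luminal_cluster_size > 1L) {
        pts_ga <- sample_clusters(n_ga, spec$luminal_cluster_size, poly,
                                  cx, cy, rx, ry, spec, placed, min_sep)
        cells[[length(cells) + 1L]] <-
          add_cells(pts_ga, "MAGE-A", "luminal", i)
        placed <- rbind(placed, pts_ga)
      } else if (n_ga > 0) {
        pts_ga <- sample_in_zone(n_ga, poly, cx, cy, rx, ry, "luminal",
                                 spec, placed, min_sep)
        cells[[length(cells) + 1L]] <-
          add_cells(pts_ga, "MAGE-A", "luminal", i)
        placed <- rbind(placed, pts_ga)
      }
      if (n_rest > 0) {
        rest_cls <- lum_cls[lum_cls != "MAGE-A"]
        pts_r <- sample_in_zone(n_rest, poly, cx, cy, rx, ry, "luminal",
                                spec, placed, min_sep)
        cells[[length(cells) + 1L]] <-
          add_cells(pts_r, rest_cls[seq_len(nrow(pts_r))], "luminal", i)
        placed <- rbind(placed, pts_r)
      }
    }
  }

  # interstitial cells scattered in the tissue band
  tissue_px <- which(region == 1L)
  if (length(tissue_px) && spec$interstitial_density_per_1000um2 > 0) {
    area_tissue <- length(tissue_px) * px^2
    n_int <- round(spec$interstitial_density_per_1000um2 *
                   area_tissue / 1000)
    pts <- matrix(numeric(0), 0, 2)
    tries <- 0L
    clear_px <- ceiling((spec$cell_radius_um + px) / px)
    d_tis <- if (n_tub > 0) EBImage::distmap(region != 2L) else NULL
    while (nrow(pts) < n_int && tries < 40L * max(1L, n_int)) {
      tries <- tries + 1L
      k <- tissue_px[sample.int(length(tissue_px), 1L)]
      r <- ((k - 1L) %% nr) + 1L
      c <- ((k - 1L) %/% nr) + 1L
      if (!is.null(d_tis) && d_tis[r, c] <= clear_px) next
      x <- (c - 0.5) * px; y <- (r - 0.5) * px
      if (x < spec$cell_radius_um || y < spec$cell_radius_um ||
          x > nc * px - spec$cell_radius_um ||
          y > nr * px - spec$cell_radius_um) next
      if (nrow(pts) &&
          min((pts[, 1] - x)^2 + (pts[, 2] - y)^2) < min_sep^2) next
      pts <- rbind(pts, c(x, y))
    }
    cells[[length(cells) + 1L]] <-
      add_cells(pts, "interstitial", "interstitial", NA_integer_)
  }

  cells <- if (length(cells)) do.call(rbind, cells) else {
    data.frame(x_um = numeric(0), y_um = numeric(0), class = character(0),
               zone = character(0), tubule_id = integer(0))
  }
  n_cells <- nrow(cells)
  if (n_cells) {
    cells$cell_id <- seq_len(n_cells)
    cells$radius_um <- spec$nucleus_radius_um
    p_mit <- vapply(cells$class, function(cl) mitotic_prob(spec, cl),
                    numeric(1))
    cells$cycle <- ifelse(stats::runif(n_cells) < p_mit, "mitotic", "G1")
    hk <- numeric(n_cells)
    g1 <- cells$cycle == "G1"
    hk[g1] <- rtrunc_norm(sum(g1), spec$hoechst_g1_mean, spec$hoechst_g1_sd,
                          spec$hoechst_g1_range[1], spec$hoechst_g1_range[2])
    hk[!g1] <- stats::runif(sum(!g1), spec$hoechst_mitotic_range[1],
                            spec$hoechst_mitotic_range[2])
    cells$hoechst_rfu <- hk
    for (mk in names(spec$markers)) {
      m <- spec$markers[[mk]]
      pos <- cells$class %in% m$positive_classes
      v <- rep(NA_real_, n_cells)
      if (any(pos)) {
        v[pos] <- rtrunc_norm(sum(pos), m$pos_mean, m$pos_sd, m$pos_min, Inf)
      }
      cells[[paste0("marker_", mk)]] <- v
    }
    cells <- cells[, c("cell_id", "tubule_id", "x_um", "y_um", "radius_um",
                       "class", "zone", "cycle", "hoechst_rfu",
                       paste0("marker_", names(spec$markers)))]
    rownames(cells) <- NULL
  }

  # ---- render ---------------------------------------------------------
  r_px <- spec$nucleus_radius_um / px
  if (n_cells) {
    for (j in seq_len(n_cells)) {
      cx_px <- cells$x_um[j] / px; cy_px <- cells$y_um[j] / px
      hoechst <- paint_disc(hoechst, cx_px, cy_px, r_px,
                            cells$hoechst_rfu[j])
    }
    for (mk in names(spec$markers)) {
      if (mk %in% mute_markers) next
      m <- spec$markers[[mk]]
      v <- cells[[paste0("marker_", mk)]]
      for (j in which(!is.na(v))) {
        cx_px <- cells$x_um[j] / px; cy_px <- cells$y_um[j] / px
        if (m$compartment == "nuclear") {
          marker_chan[[mk]] <- paint_disc(marker_chan[[mk]], cx_px, cy_px,
                                          r_px, v[j])
        } else {
          marker_chan[[mk]] <- paint_annulus(
            marker_chan[[mk]], cx_px, cy_px, r_px,
            r_px + spec$cytosol_width_um / px, v[j])
        }
      }
    }
  }

  finish <- function(ch) {
    if (spec$blur_sigma_px > 0) {
      ch <- as.matrix(EBImage::gblur(ch, sigma = spec$blur_sigma_px))
    }
    if (spec$noise_sd > 0) {
      ch <- ch + stats::rnorm(length(ch), 0, spec$noise_sd)
    }
    round(pmin(pmax(ch, 0), 65535))
  }
  chans <- c(list(Hoechst = finish(hoechst)),
             lapply(marker_chan, finish))
  img <- calibrated_image(chans, px,
                          image_id = sprintf("scene_seed%d", spec$seed))
  truth <- structure(list(region = region,
                          cells = cells,
                          tubules = tub_polys,
                          tubule_centres = tubs$centres,
                          tubule_rx = tubs$rx, tubule_ry = tubs$ry,
                          pixel_size_um = px,
                          spec = spec),
                     class = "GroundTruth")
  list(image = img, truth = truth)
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf("GroundTruth: %d tubules, %d cells (%s)\n",
              length(x$tubules), nrow(x$cells),
              paste(sprintf("%s: %d", names(table(x$cells$class)),
                            table(x$cells$class)), collapse = ", ")))
  invisible(x)
}

#' Sparse training annotations drawn from ground truth
#'
#' Emulates the manual training input of the pixel-classification stage:
#' a few small disc annotations per region class, each placed fully inside
#' a correctly-labelled region.
#'
#' @param gt A `GroundTruth`.
#' @param k_per_class Number of annotations per class (default 3).
#' @param radius_um Annotation disc radius.
#' @param seed Seed for placement.
#' @return An `ROISet` with classes `tubule`, `tissue`, `background`.
#' @export
sparse_annotations_from_truth <- function(gt, k_per_class = 3L,
                                          radius_um = 10, seed = 1L) {
  stopifnot(inherits(gt, "GroundTruth"), k_per_class >= 1)
  set.seed(seed)
  px <- gt$pixel_size_um
  codes <- c(background = 0L, tissue = 1L, tubule = 2L)
  polys <- list(); cls <- character(0)
  for (nm in names(codes)) {
    mask <- gt$region == codes[[nm]]
    if (!any(mask)) stop(sprintf("class absent from scene: %s", nm))
    # eligible centres: deep enough inside the region for the whole disc
    d <- EBImage::distmap(mask) * px
    elig <- which(d > radius_um + px)
    if (!length(elig)) {
      stop(sprintf("class %s has no area wide enough for a %g um annotation",
                   nm, radius_um))
    }
    centres <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centres) < k_per_class && tries < 200L * k_per_class) {
      tries <- tries + 1L
      k <- elig[sample.int(length(elig), 1L)]
      r <- ((k - 1L) %% nrow(mask)) + 1L
      c <- ((k - 1L) %/% nrow(mask)) + 1L
      x <- (c - 0.5) * px; y <- (r - 0.5) * px
      if (nrow(centres) &&
          min((centres[, 1] - x)^2 + (centres[, 2] - y)^2) <
            (2 * radius_um)^2) next
      centres <- rbind(centres, c(x, y))
    }
    if (nrow(centres) < k_per_class) {
      stop(sprintf("could not place %d separated annotations in class %s",
                   k_per_class, nm))
    }
    for (i in seq_len(k_per_class)) {
      polys[[length(polys) + 1L]] <-
        ellipse_polygon(centres[i, 1], centres[i, 2], radius_um, n = 48L)
      cls <- c(cls, nm)
    }
  }
  roi_set(polys, cls, image_id = "annotations")
}

#' Render an antibody-control image
#'
#' Same geometry, cells and counterstain as [generate_scene()] at the same
#' seed, but the listed marker channels carry only baseline plus noise
#' (no positive staining), emulating primary-antibody controls.
#'
#' @param spec A `SceneSpec`.
#' @param omit_markers Character vector of marker channels to silence.
#' @return Same structure as [generate_scene()].
#' @export
render_control_image <- function(spec, omit_markers) {
  stopifnot(inherits(spec, "SceneSpec"))
  if ("Hoechst" %in% omit_markers) {
    stop("the counterstain cannot be omitted")
  }
  out <- generate_scene(spec, mute_markers = omit_markers)
  out$image$image_id <- sprintf("%s_ctrl_%s", out$image$image_id,
                                paste(omit_markers, collapse = "_"))
  out
}

#' Write a scene to disk (TIFF image + ground-truth GeoJSON and CSV)
#'
#' @param scene Output of [generate_scene()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- scene$image$image_id
  p_img <- file.path(dir, paste0(id, ".tif"))
  write_image(scene$image, p_img)
  rois <- roi_set(scene$truth$tubules,
                  rep("tubule", length(scene$truth$tubules)),
                  image_id = id)
  p_roi <- file.path(dir, paste0(id, "_tubules.geojson"))
  write_rois_geojson(rois, p_roi)
  p_cells <- file.path(dir, paste0(id, "_cells.csv"))
  write_measurements(scene$truth$cells, p_cells)
  invisible(c(image = p_img, tubules = p_roi, cells = p_cells))
}
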