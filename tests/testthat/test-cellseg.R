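make_disc_image <- function(centres_um, radius_um, value = 9000,
                            baseline = 2000, dim_px = c(200, 200),
                            px = 0.5) {
  m <- matrix(baseline, dim_px[1], dim_px[2])
  for (i in seq_len(nrow(centres_um))) {
    m <- tubuleseg:::paint_disc(m, centres_um[i, 1] / px,
                                centres_um[i, 2] / px, radius_um / px,
                                value)
  }
  calibrated_image(list(Hoechst = m), px)
}

test_that("a noise-only counterstain yields no detections", {
  set.seed(9)
  noise <- matrix(pmax(rnorm(512 * 512, 200, 60), 0), 512, 512)
  img <- calibrated_image(list(Hoechst = round(noise)), 0.5)
  seg <- segment_nuclei_watershed(img, ellipse_polygon(128, 128, 100,
                                                       n = 64L))
  expect_equal(nrow(seg$centroids), 0L)
  expect_error(segment_nuclei_watershed(img, ellipse_polygon(
    1000, 1000, 50, n = 32L)), "outside image")
  img2 <- calibrated_image(list(SOX9 = round(noise)), 0.5)
  expect_error(segment_nuclei_watershed(img2, ellipse_polygon(
    128, 128, 100, n = 64L)), "channel 'Hoechst' not present")
})

test_that("sparse synthetic nuclei are each recovered near their true centroid", {
  # sparse, widely separated nuclei: the premise is detection, not
  # clump splitting, so spacing is generous (12 um centre distance)
  sp <- scene_spec(width_px = 512L, height_px = 512L, n_tubules = 1L,
                   tubule_radius_um = c(80, 85),
                   zone_density_per_1000um2 = c(membrane = 3,
                                                luminal = 2),
                   luminal_cluster_size = 1L, min_sep_factor = 3,
                   interstitial_density_per_1000um2 = 0,
                   seed = 51)
  sc <- generate_scene(sp)
  truth <- sc$truth$cells[sc$truth$cells$zone != "interstitial", ]
  rois <- roi_set(sc$truth$tubules, "tubule")
  det <- detect_cells(sc$image, rois)
  expect_equal(nrow(det), nrow(truth))
  d <- sqrt(outer(truth$x_um, det$x_um, "-")^2 +
            outer(truth$y_um, det$y_um, "-")^2)
  expect_lt(max(apply(d, 1, min)), 2)
})

test_that("two fused nuclei are split into two labels", {
  # discs of radius 6 um whose centres are 12 um apart touch and fuse
  img <- make_disc_image(rbind(c(38, 50), c(50, 50)), 6)
  seg <- segment_nuclei_watershed(img, ellipse_polygon(44, 50, 25,
                                                       n = 64L),
                                  watershed_config(
                                    nucleus_area_um2 = c(10, 600)))
  expect_equal(nrow(seg$centroids), 2L)
  cent <- seg$centroids[order(seg$centroids[, 1]), ]
  expect_lt(max(abs(cent - rbind(c(38, 50), c(50, 50)))), 2)
})

test_that("cell expansion matches analytic and nearest-nucleus oracles", {
  px <- 0.5
  lab <- matrix(0L, 200, 200)
  # isolated disc nucleus, radius 4 um at (50, 50) um
  dx <- (col(lab) - 0.5) * px - 50
  dy <- (row(lab) - 0.5) * px - 50
  lab[dx^2 + dy^2 <= 16] <- 1L
  cells <- expand_cells(lab, NULL, 5, px)
  area <- sum(cells == 1L) * px^2
  expect_lt(abs(area - pi * 81) / (pi * 81), 0.05)
  expect_true(all(cells[lab == 1L] == 1L))  # nucleus inside cell
  # zero expansion is the identity
  expect_identical(expand_cells(lab, NULL, 0, px), lab)
  expect_error(expand_cells(lab, NULL, -1, px), "negative")

  # two nuclei 10 um apart with 8 um expansion: disjoint Voronoi halves
  lab2 <- matrix(0L, 200, 200)
  x <- (col(lab2) - 0.5) * px; y <- (row(lab2) - 0.5) * px
  lab2[(x - 45)^2 + (y - 50)^2 <= 16] <- 1L
  lab2[(x - 55)^2 + (y - 50)^2 <= 16] <- 2L
  cells2 <- expand_cells(lab2, NULL, 8, px)
  expect_true(all(cells2[lab2 == 1L] == 1L))
  expect_true(all(cells2[lab2 == 2L] == 2L))
  # pixelwise nearest-nucleus-centre oracle, away from the midline
  d1 <- sqrt((x - 45)^2 + (y - 50)^2)
  d2 <- sqrt((x - 55)^2 + (y - 50)^2)
  claimed <- cells2 > 0
  margin <- abs(d1 - d2) > 1.5 * px
  oracle <- ifelse(d1 < d2, 1L, 2L)
  expect_true(all(cells2[claimed & margin] ==
                  oracle[claimed & margin]))
})

test_that("detections stay inside tubule ROIs and conserve counts within 5%", {
  sc <- fx_scene(21)
  det <- fx_det(21)
  truth <- sc$truth$cells
  n_true <- sum(truth$zone != "interstitial")
  expect_gt(nrow(det), 0.95 * n_true)
  expect_lt(nrow(det), 1.05 * n_true)
  # no detection centroid outside a tubule polygon
  inside <- rep(FALSE, nrow(det))
  for (p in sc$truth$tubules) {
    inside <- inside | point_in_polygon(det$x_um, det$y_um, p)
  }
  expect_true(all(inside))
  # nuclei within one ROI do not overlap: total nucleus area is the sum
  rois <- fx_truth_rois(21)
  seg <- segment_nuclei_watershed(sc$image, rois$polygons[[1]])
  expect_equal(sum(seg$labels > 0) * sc$image$pixel_size_um^2,
               sum(seg$areas_um2))
  # empty ROI set yields an empty detection table
  det0 <- detect_cells(sc$image, roi_set(list(), character(0)))
  expect_equal(nrow(det0), 0L)
})

test_that("raising the lower nucleus-area bound never increases the count", {
  sc <- fx_scene(21)
  roi <- fx_truth_rois(21)$polygons[[1]]
  counts <- vapply(c(10, 40, 60, 80), function(lo) {
    nrow(segment_nuclei_watershed(
      sc$image, roi,
      watershed_config(nucleus_area_um2 = c(lo, 400)))$centroids)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], 0)
})

test_that("the plugin backend accepts an external label map and errors cleanly", {
  sc <- fx_scene(21)
  rois <- fx_truth_rois(21)
  expect_error(detect_cells(sc$image, rois, backend = "plugin"),
               "plugin backend not installed")
  # a plugin that reuses the watershed labels must reproduce its counts
  plug <- function(img, roi) {
    segment_nuclei_watershed(img, roi)$labels
  }
  det_w <- detect_cells(sc$image, subset_rois(rois, 1))
  det_p <- detect_cells(sc$image, subset_rois(rois, 1),
                        backend = "plugin", plugin_fun = plug)
  expect_equal(nrow(det_p), nrow(det_w))
  expect_equal(det_p$Hoechst_nuc_mean, det_w$Hoechst_nuc_mean)
})

test_that("intensity statistics are non-negative and nucleus lies inside cell", {
  det <- fx_det(21)
  stat_cols <- grep("_nuc_|_cyt_", names(det), value = TRUE)
  for (cl in stat_cols) {
    expect_true(all(is.na(det[[cl]]) | det[[cl]] >= 0), info = cl)
  }
  expect_true(all(det$cell_area_um2 >= det$nucleus_area_um2))
  # centroid inside the nucleus polygon bounding box
  np <- attr(det, "nucleus_polygons")
  for (i in seq_len(min(nrow(det), 50))) {
    pg <- np[[det$cell_id[i]]]$outer
    expect_true(det$x_um[i] >= min(pg[, 1]) &&
                det$x_um[i] <= max(pg[, 1]) &&
                det$y_um[i] >= min(pg[, 2]) &&
                det$y_um[i] <= max(pg[, 2]))
  }
})
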