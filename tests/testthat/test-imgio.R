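test_that("polygon geometry matches analytic values", {
  sq <- cbind(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100))
  expect_equal(poly_area(sq), 10000)
  expect_equal(poly_perimeter(sq), 400)
  # circle with >= 64 vertices within 1% of pi r^2
  circ <- ellipse_polygon(50, 50, 30, n = 64L)
  expect_lt(abs(poly_area(circ) - pi * 900) / (pi * 900), 0.01)
  expect_lt(abs(poly_perimeter(circ) - 2 * pi * 30) / (2 * pi * 30), 0.01)
  # hole subtraction: outer 100x100 with 10x10 hole
  hole <- cbind(x = c(40, 50, 50, 40), y = c(40, 40, 50, 50))
  expect_equal(poly_area(list(outer = sq, holes = list(hole))), 9900)
})

test_that("TIFF write/read round-trips pixels, names and calibration", {
  set.seed(1)
  chans <- list(Hoechst = matrix(sample(0:30000, 64 * 48), 64, 48),
                SOX9 = matrix(sample(0:30000, 64 * 48), 64, 48))
  img <- calibrated_image(chans, 0.5, image_id = "t")
  path <- file.path(tempdir(), "rt.tif")
  write_image(img, path)
  r <- read_image(path)
  expect_identical(r$channel_names, c("Hoechst", "SOX9"))
  expect_equal(r$pixel_size_um, 0.5)
  expect_equal(r$channels$Hoechst, chans$Hoechst)
  expect_equal(r$width_px, 48)
  expect_equal(r$height_px, 64)
})

test_that("calibration rules: override wins, absence errors", {
  img <- calibrated_image(list(ch = matrix(100, 8, 8)), 0.5)
  path <- file.path(tempdir(), "cal.tif")
  write_image(img, path)
  # strip the sidecar: no metadata left in the TIFF itself
  unlink(paste0(path, ".json"))
  expect_error(read_image(path), "missing calibration")
  r <- read_image(path, pixel_size_override = 0.325)
  expect_equal(r$pixel_size_um, 0.325)
  expect_identical(r$channel_names, "ch0")
  expect_error(read_image(file.path(tempdir(), "nope.tif")),
               "unreadable")
  expect_error(calibrated_image(list(ch = matrix(1, 4, 4)), -1),
               "calibration")
  expect_error(calibrated_image(list(a = matrix(1, 4, 4),
                                     b = matrix(1, 5, 4)), 0.5),
               "share dimensions")
})

test_that("GeoJSON ROI round-trip preserves geometry and classes", {
  set.seed(7)
  polys <- lapply(1:10, function(i) {
    ellipse_polygon(runif(1, 50, 200), runif(1, 50, 200),
                    runif(1, 10, 40), runif(1, 10, 40), n = 24L)
  })
  rois <- roi_set(polys, rep(c("tubule", "tissue"), 5), image_id = "rt")
  path <- file.path(tempdir(), "rois.geojson")
  write_rois_geojson(rois, path)
  back <- read_rois_geojson(path)
  expect_equal(length(back), 10L)
  expect_identical(back$class_label, rois$class_label)
  for (i in 1:10) {
    expect_equal(back$polygons[[i]]$outer, rois$polygons[[i]]$outer,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # areas/perimeters recomputed from geometry
  expect_equal(back$area_um2, rois$area_um2, tolerance = 1e-9)
})

test_that("GeoJSON reader enforces polygon geometry and class property", {
  path <- file.path(tempdir(), "bad.geojson")
  # square side 100 um with a 10x10 hole: area 9,900, perimeter computed
  sq <- cbind(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100))
  hole <- cbind(x = c(40, 50, 50, 40), y = c(40, 40, 50, 50))
  rois <- roi_set(list(list(outer = sq, holes = list(hole))), "tubule")
  write_rois_geojson(rois, path)
  back <- read_rois_geojson(path)
  expect_equal(back$area_um2, 9900)
  # missing class property
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  gj$features[[1]]$properties$class <- NULL
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_rois_geojson(path), "missing class")
  # non-polygon geometry
  gj$features[[1]]$properties$class <- "tubule"
  gj$features[[1]]$geometry <- list(type = "Point",
                                    coordinates = list(1, 2))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_rois_geojson(path), "non-polygon")
  # empty collection round-trips
  empty <- roi_set(list(), character(0))
  write_rois_geojson(empty, path)
  expect_equal(length(read_rois_geojson(path)), 0L)
})

test_that("measurement CSV round-trips values and shape", {
  set.seed(3)
  tb <- data.frame(image_id = "i1", object_id = sprintf("o%d", 1:5),
                   `MAGE-A_nuc_mean` = runif(5, 0, 3e4),
                   area = rnorm(5), check.names = FALSE)
  path <- file.path(tempdir(), "meas.csv")
  write_measurements(tb, path)
  expect_length(readLines(path), 6L)  # header + 5 rows
  back <- read_measurements(path)
  expect_identical(names(back), names(tb))
  expect_equal(back$`MAGE-A_nuc_mean`, tb$`MAGE-A_nuc_mean`,
               tolerance = 1e-6)
  # empty table: header only
  write_measurements(tb[0, ], path)
  expect_length(readLines(path), 1L)
})

test_that("mask tracing and rasterisation are consistent", {
  sq <- cbind(x = c(10, 60, 60, 10), y = c(10, 10, 40, 40))
  m <- rasterize_polygon(sq, c(120, 160), 0.5)
  expect_equal(sum(m) * 0.25, 50 * 30)
  pg <- mask_to_polygons(m, 0.5)
  expect_length(pg, 1L)
  expect_lt(abs(poly_area(pg[[1]]) - 1500) / 1500, 0.005)
  # re-rasterising the traced polygon reproduces the mask
  m2 <- rasterize_polygon(pg[[1]], c(120, 160), 0.5)
  expect_identical(m2, m)
  # 8-connectivity: diagonal pixels form one component
  d <- matrix(0, 4, 4); d[1, 1] <- 1; d[2, 2] <- 1; d[4, 4] <- 1
  l <- label8(d)
  expect_equal(l[1, 1], l[2, 2])
  expect_false(l[4, 4] == l[1, 1])
})
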