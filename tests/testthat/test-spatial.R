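test_that("the 35 um partition of a circular tubule matches the analytic annulus", {
  circ <- ellipse_polygon(150, 150, 100, n = 256L)
  part <- partition_tubule(circ, membrane_depth_um = 35)
  lum_true <- pi * 65^2
  mem_true <- pi * (100^2 - 65^2)
  expect_lt(abs(part$luminal_area_um2 - lum_true) / lum_true, 0.01)
  expect_lt(abs(part$membrane_area_um2 - mem_true) / mem_true, 0.01)
  # exact additive identity
  expect_equal(part$membrane_area_um2 + part$luminal_area_um2,
               part$tubule_area_um2, tolerance = 1e-9)
  expect_length(part$luminal_polygons, 1L)
})

test_that("tubules narrower than twice the depth have no luminal zone", {
  small <- ellipse_polygon(60, 60, 30, n = 128L)
  part <- partition_tubule(small, membrane_depth_um = 35)
  expect_equal(part$luminal_area_um2, 0)
  expect_length(part$luminal_polygons, 0L)
  expect_equal(part$membrane_area_um2, part$tubule_area_um2)
  expect_error(partition_tubule(cbind(x = c(0, 1), y = c(0, 1))),
               "invalid polygon")
})

test_that("region assignment follows centroid distance with membrane ties", {
  circ <- ellipse_polygon(150, 150, 100, n = 256L)
  rois <- roi_set(list(circ), "tubule", roi_id = "t1")
  det <- data.frame(
    cell_id = c("a", "b", "c"),
    roi_id = "t1",
    # 10 um from boundary; at the centre; exactly on the 35 um line
    x_um = c(150 + 90, 150, 150 + 65), y_um = 150,
    stringsAsFactors = FALSE)
  out <- assign_regions(det, rois, membrane_depth_um = 35)
  expect_identical(out$region[1:2], c("membrane", "luminal"))
  # the 256-gon boundary lies marginally inside the circle, so allow the
  # exact-tie case to be asserted against the polygon itself
  d <- dist_to_boundary(det$x_um[3], det$y_um[3], circ)
  expect_identical(out$region[3],
                   if (d <= 35) "membrane" else "luminal")
  expect_error(assign_regions(
    data.frame(cell_id = "z", roi_id = "missing", x_um = 1, y_um = 1),
    rois), "no parent tubule")
})

test_that("membrane and luminal cells partition each tubule's detections", {
  det <- fx_det(21)
  expect_true(all(det$region %in% c("membrane", "luminal")))
  tb <- table(det$roi_id, det$region)
  expect_equal(unname(rowSums(tb)),
               unname(as.vector(table(det$roi_id))))
})

test_that("neighbour graph equals the brute-force pairwise oracle", {
  set.seed(12)
  n <- 200
  det <- data.frame(
    cell_id = sprintf("c%03d", 1:n),
    x_um = runif(n, 0, 250), y_um = runif(n, 0, 250),
    class = sample(c("SOX9", "MAGE-A", "unclassified"), n,
                   replace = TRUE),
    stringsAsFactors = FALSE)
  g <- build_neighbour_graph(det, neighbour_config(15))
  expect_identical(edge_key(g$edges), brute_force_edges(det, 15))
  # symmetry / no self-edges
  expect_false(any(g$edges$from == g$edges$to))
  # degree accounting: sum of degrees = 2 |E|
  expect_equal(sum(g$degree), 2L * nrow(g$edges))
  # unclassified cells excluded from the graph
  expect_false(any(g$class == "unclassified"))
  # unclassified-only input gives an empty graph, not an error
  det_u <- det; det_u$class <- "unclassified"
  g0 <- build_neighbour_graph(det_u)
  expect_equal(length(g0$nodes), 0L)
  expect_equal(nrow(g0$edges), 0L)
})

test_that("constructed configurations give the expected degrees", {
  # single cell: degree 0
  one <- data.frame(cell_id = "a", x_um = 0, y_um = 0, class = "SOX9",
                    stringsAsFactors = FALSE)
  g1 <- build_neighbour_graph(one)
  expect_equal(unname(g1$degree), 0L)
  # three collinear same-class cells spaced 10 um: degrees 1, 2, 1
  tri <- data.frame(cell_id = c("a", "b", "c"),
                    x_um = c(0, 10, 20), y_um = 0, class = "SOX9",
                    stringsAsFactors = FALSE)
  g3 <- build_neighbour_graph(tri)
  expect_equal(unname(g3$degree[c("a", "b", "c")]), c(1L, 2L, 1L))
  # cross-class pairs are not neighbours under same_class_only
  mixed <- tri; mixed$class <- c("SOX9", "MAGE-A", "SOX9")
  gm <- build_neighbour_graph(mixed)
  expect_equal(sum(gm$degree), 0L)
  gm2 <- build_neighbour_graph(mixed, neighbour_config(
    15, same_class_only = FALSE))
  expect_equal(unname(gm2$degree[c("a", "b", "c")]), c(1L, 2L, 1L))
})

test_that("degree is monotone in the neighbour radius", {
  det <- fx_det(21)
  g10 <- build_neighbour_graph(det, neighbour_config(10))
  g15 <- build_neighbour_graph(det, neighbour_config(15))
  g25 <- build_neighbour_graph(det, neighbour_config(25))
  expect_true(all(g15$degree[g10$nodes] >= g10$degree))
  expect_true(all(g25$degree[g15$nodes] >= g15$degree))
})

test_that("a luminal 5-clique yields degree 4 for every member", {
  th <- 2 * pi * (0:4) / 5
  cl <- data.frame(cell_id = sprintf("k%d", 1:5),
                   x_um = 100 + 7.4 * cos(th),
                   y_um = 100 + 7.4 * sin(th),
                   class = "MAGE-A", region = "luminal",
                   stringsAsFactors = FALSE)
  g <- build_neighbour_graph(cl)
  expect_equal(unname(g$degree), rep(4L, 5))
  nd <- neighbour_distribution(g, cl, "MAGE-A", "luminal")
  expect_equal(nd$mode, 4L)
  expect_equal(nd$n, 5L)
})

test_that("degree histograms select by region but count all same-class neighbours", {
  det <- data.frame(
    cell_id = c("m1", "l1", "l2"),
    x_um = c(0, 10, 20), y_um = 0, class = "MAGE-A",
    region = c("membrane", "luminal", "luminal"),
    stringsAsFactors = FALSE)
  g <- build_neighbour_graph(det)
  # l1's membrane neighbour still counts towards its degree
  nd <- neighbour_distribution(g, det, "MAGE-A", "luminal")
  expect_equal(unname(nd$degrees[c("l1", "l2")]), c(2L, 1L))
  expect_equal(nd$mode, 1L)  # tie between degree 1 and 2 -> smallest
  # all isolated -> mode 0
  iso <- data.frame(cell_id = c("a", "b"), x_um = c(0, 100), y_um = 0,
                    class = "SOX9", region = "membrane",
                    stringsAsFactors = FALSE)
  gi <- build_neighbour_graph(iso)
  expect_equal(neighbour_distribution(gi, iso, "SOX9", "total")$mode, 0L)
  # empty subset signals and returns an undefined mode
  expect_warning(
    nd0 <- neighbour_distribution(gi, iso, "SOX9", "luminal"),
    "empty subset")
  expect_true(is.na(nd0$mode))
})

test_that("clustered luminal germ cells out-cluster dispersed membrane cells", {
  fx <- fx_cluster_det()
  det <- fx$det
  g <- build_neighbour_graph(det)
  lum <- neighbour_distribution(g, det, "MAGE-A", "luminal")
  mem <- neighbour_distribution(g, det, "MAGE-A", "membrane")
  expect_gt(lum$n, 20)
  expect_gt(lum$mode, mem$mode)
  expect_equal(lum$mode, 4L)
})
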