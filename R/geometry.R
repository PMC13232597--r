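# Coordinate convention used throughout:
#   * rasters are matrices indexed [row, col] with row = y (down), col = x;
#   * continuous coordinates are micrometres with origin at the top-left
#     pixel corner, so the centre of pixel (r, c) is
#     x = (c - 0.5) * pixel_size_um, y = (r - 0.5) * pixel_size_um;
#   * polygons are n x 2 matrices with columns (x, y) in um, implicitly
#     closed (last vertex joins the first).

#' Signed area of a polygon ring (shoelace formula)
#' @param ring n x 2 matrix of (x, y) vertices.
#' @return Signed area in squared input units; positive for
#'   counter-clockwise rings in a y-down frame.
#' @keywords internal
ring_area_signed <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Area of a polygon with optional holes
#'
#' @param poly Either an n x 2 vertex matrix or a list with elements
#'   `outer` (vertex matrix) and `holes` (list of vertex matrices).
#' @return Area in squared input units (holes subtracted).
#' @export
poly_area <- function(poly) {
  if (is.matrix(poly)) return(abs(ring_area_signed(poly)))
  a <- abs(ring_area_signed(poly$outer))
  for (h in poly$holes) a <- a - abs(ring_area_signed(h))
  a
}

#' Perimeter of a polygon (outer ring plus hole boundaries)
#' @inheritParams poly_area
#' @return Total boundary length in input units.
#' @export
poly_perimeter <- function(poly) {
  per <- function(ring) {
    x <- ring[, 1]; y <- ring[, 2]
    sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  }
  if (is.matrix(poly)) return(per(poly))
  per(poly$outer) + sum(vapply(poly$holes, per, numeric(1)))
}

#' Centroid of a polygon ring
#' @keywords internal
ring_centroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

#' Point-in-ring test (crossing number), vectorised over points
#' @param px,py Point coordinates.
#' @param ring n x 2 vertex matrix.
#' @return Logical vector; points exactly on an edge may fall either side.
#' @keywords internal
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Point-in-polygon test honouring holes
#' @inheritParams point_in_ring
#' @inheritParams poly_area
#' @export
point_in_polygon <- function(px, py, poly) {
  if (is.matrix(poly)) return(point_in_ring(px, py, poly))
  inside <- point_in_ring(px, py, poly$outer)
  for (h in poly$holes) inside <- inside & !point_in_ring(px, py, h)
  inside
}

#' Minimum distance from points to a polygon boundary
#'
#' Distance to the closed outline (outer ring and holes), irrespective of
#' whether the points lie inside or outside.
#' @inheritParams point_in_polygon
#' @return Numeric vector of distances in input units.
#' @export
dist_to_boundary <- function(px, py, poly) {
  rings <- if (is.matrix(poly)) list(poly) else c(list(poly$outer), poly$holes)
  d2 <- rep(Inf, length(px))
  for (ring in rings) {
    n <- nrow(ring)
    x1 <- ring[, 1]; y1 <- ring[, 2]
    x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
    ex <- x2 - x1; ey <- y2 - y1
    len2 <- ex^2 + ey^2
    for (i in seq_len(n)) {
      if (len2[i] < .Machine$double.eps) {
        dd <- (px - x1[i])^2 + (py - y1[i])^2
      } else {
        t <- ((px - x1[i]) * ex[i] + (py - y1[i]) * ey[i]) / len2[i]
        t <- pmin(1, pmax(0, t))
        dd <- (px - (x1[i] + t * ex[i]))^2 + (py - (y1[i] + t * ey[i]))^2
      }
      d2 <- pmin(d2, dd)
    }
  }
  sqrt(d2)
}

#' Regular polygon approximating a circle or axis-aligned ellipse
#' @param cx,cy Centre in um.
#' @param rx Radius along x in um.
#' @param ry Radius along y in um (defaults to `rx`).
#' @param n Number of vertices (>= 8).
#' @return n x 2 vertex matrix.
#' @export
ellipse_polygon <- function(cx, cy, rx, ry = rx, n = 128L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = cx + rx * cos(th), y = cy + ry * sin(th))
}

#' Rasterise a polygon onto a pixel grid
#'
#' A pixel is set when its centre lies inside the polygon.
#' @inheritParams poly_area
#' @param dim c(rows, cols) of the target raster.
#' @param pixel_size_um Pixel edge in um.
#' @return Logical matrix of dimension `dim`.
#' @export
rasterize_polygon <- function(poly, dim, pixel_size_um) {
  nr <- dim[1]; nc <- dim[2]
  ring <- if (is.matrix(poly)) poly else poly$outer
  # restrict the point-in-polygon test to the bounding box
  r1 <- max(1L, floor(min(ring[, 2]) / pixel_size_um))
  r2 <- min(nr, ceiling(max(ring[, 2]) / pixel_size_um) + 1L)
  c1 <- max(1L, floor(min(ring[, 1]) / pixel_size_um))
  c2 <- min(nc, ceiling(max(ring[, 1]) / pixel_size_um) + 1L)
  out <- matrix(FALSE, nr, nc)
  if (r1 > r2 || c1 > c2) return(out)
  rows <- r1:r2; cols <- c1:c2
  px <- rep((cols - 0.5) * pixel_size_um, each = length(rows))
  py <- rep((rows - 0.5) * pixel_size_um, times = length(cols))
  out[rows, cols] <- point_in_polygon(px, py, poly)
  out
}

#' Trace the boundary polygons of a binary mask
#'
#' Runs marching squares at the 0.5 level on the zero-padded mask, so ring
#' vertices lie on pixel edges and the enclosed area matches the pixel
#' count up to corner cuts (1/8 px^2 per convex corner). Rings are
#' classified as outer boundaries or holes by containment nesting.
#'
#' @param mask Logical or 0/1 matrix (a single connected component with
#'   optional holes, or any mask if only raw rings are needed).
#' @param pixel_size_um Pixel edge in um.
#' @return List of polygons, each a list(outer = matrix, holes = list).
#' @export
mask_to_polygons <- function(mask, pixel_size_um) {
  m <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.numeric(mask)
  # contourLines' x runs over rows of z; our rows are y
  yy <- ((0:(nrow(mask) + 1L)) - 0.5) * pixel_size_um
  xx <- ((0:(ncol(mask) + 1L)) - 0.5) * pixel_size_um
  cl <- grDevices::contourLines(yy, xx, m, levels = 0.5)
  if (!length(cl)) return(list())
  rings <- lapply(cl, function(ct) {
    ring <- cbind(x = ct$y, y = ct$x)
    # drop duplicated closing vertex if present
    if (nrow(ring) > 1 &&
        all(abs(ring[1, ] - ring[nrow(ring), ]) < 1e-12)) {
      ring <- ring[-nrow(ring), , drop = FALSE]
    }
    ring
  })
  rings <- rings[vapply(rings, nrow, 1L) >= 3L]
  if (!length(rings)) return(list())
  # nesting depth: even => outer boundary, odd => hole
  depth <- vapply(seq_along(rings), function(i) {
    p <- rings[[i]][1, ]
    sum(vapply(seq_along(rings), function(j) {
      j != i && point_in_ring(p[1], p[2], rings[[j]])
    }, logical(1)))
  }, integer(1))
  outers <- which(depth %% 2L == 0L)
  holes <- which(depth %% 2L == 1L)
  polys <- lapply(outers, function(i) list(outer = rings[[i]], holes = list()))
  for (h in holes) {
    p <- rings[[h]][1, ]
    parent <- which(vapply(outers, function(i) {
      point_in_ring(p[1], p[2], rings[[i]])
    }, logical(1)))
    if (length(parent)) {
      # innermost enclosing outer ring
      if (length(parent) > 1L) {
        areas <- vapply(outers[parent],
                        function(i) abs(ring_area_signed(rings[[i]])),
                        numeric(1))
        parent <- parent[which.min(areas)]
      }
      polys[[parent]]$holes <- c(polys[[parent]]$holes, list(rings[[h]]))
    }
  }
  polys
}

#' 8-connected component labelling of a binary mask
#'
#' EBImage's `bwlabel` uses 4-connectivity; tubule extraction specifies
#' 8-connectivity, so components are built over the 8-neighbour pixel
#' graph. Labels are assigned in raster (column-major) order of each
#' component's first pixel, which makes the labelling deterministic.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Integer matrix of labels, 0 for background.
#' @export
label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask != 0)
  out <- matrix(0L, nr, nc)
  if (!length(fg)) return(out)
  id <- matrix(0L, nr, nc)
  id[fg] <- seq_along(fg)
  edge_to <- function(dr, dc) {
    r <- ((fg - 1L) %% nr) + 1L
    c <- ((fg - 1L) %/% nr) + 1L
    r2 <- r + dr; c2 <- c + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- id[cbind(r2[ok], c2[ok])]
    src <- id[fg][ok]
    keep <- nb > 0L
    cbind(src[keep], nb[keep])
  }
  edges <- rbind(edge_to(1L, 0L), edge_to(0L, 1L),
                 edge_to(1L, 1L), edge_to(-1L, 1L))
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # relabel so that label k is the k-th component met in raster order
  first <- !duplicated(memb)
  relab <- integer(max(memb))
  relab[memb[first]] <- seq_len(sum(first))
  out[fg] <- relab[memb]
  out
}
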