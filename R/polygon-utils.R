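# Pixel/polygon geometry shared by detection, matching and tracking.
#
# Conventions (stated once, used everywhere): pixel coordinates are 0-based,
# x to the right, y downward; a pixel (x, y) covers the unit square
# [x, x+1) x [y, y+1); bounding boxes are half-open [x0, x1) x [y0, y1).
# Polygons are n x 2 matrices with columns x, y, implicitly closed.

#' Polygon area (shoelace formula)
#'
#' @param poly n x 2 numeric matrix of vertices (columns x, y).
#' @return Non-negative area in px^2.
#' @export
polygon_area <- function(poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Polygon centroid
#'
#' Area-weighted centroid; falls back to the vertex mean for degenerate
#' (near-zero-area) polygons.
#'
#' @inheritParams polygon_area
#' @return Numeric length-2 vector (x, y).
#' @export
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(c(mean(x), mean(y)))
  c(sum((x + xs) * cr) / (6 * a), sum((y + ys) * cr) / (6 * a))
}

#' Polygon bounding box
#'
#' @inheritParams polygon_area
#' @return Half-open box c(x0, y0, x1, y1) snapped to integer pixel bounds.
#' @export
polygon_bbox <- function(poly) {
  # pixel (x, y) is inside iff its centre (x+.5, y+.5) is: a polygon
  # spanning [0, 29] covers pixels 0..28, giving the half-open box [0, 29)
  c(floor(min(poly[, 1])), floor(min(poly[, 2])),
    max(ceiling(max(poly[, 1])), floor(min(poly[, 1])) + 1),
    max(ceiling(max(poly[, 2])), floor(min(poly[, 2])) + 1))
}

# Even-odd (crossing number) point-in-polygon test, vectorised over points.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    crosses <- ((y[k] > py) != (yn[k] > py))
    if (any(crosses)) {
      xint <- x[k] + (py[crosses] - y[k]) / (yn[k] - y[k]) * (xn[k] - x[k])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
  }
  inside
}

#' Rasterize a polygon to a logical pixel mask
#'
#' Membership is tested at pixel centres (x + 0.5, y + 0.5) with the even-odd
#' rule, which is exact for the pixel-defined contours this package produces.
#'
#' @inheritParams polygon_area
#' @param bbox optional half-open box c(x0, y0, x1, y1); defaults to the
#'   polygon's own integer bounding box.
#' @return List with `mask` (logical matrix, rows = x, cols = y, matching the
#'   EBImage image layout) and `offset` (c(x0, y0) of the mask origin).
#' @export
rasterize_polygon <- function(poly, bbox = NULL) {
  if (is.null(bbox)) bbox <- polygon_bbox(poly)
  nx <- bbox[3] - bbox[1]; ny <- bbox[4] - bbox[2]
  gx <- rep(seq_len(nx) - 1 + bbox[1] + 0.5, times = ny)
  gy <- rep(seq_len(ny) - 1 + bbox[2] + 0.5, each = nx)
  m <- matrix(points_in_polygon(gx, gy, poly), nrow = nx, ncol = ny)
  list(mask = m, offset = c(bbox[1], bbox[2]))
}

# Pixel set of an instance as a 2-column integer matrix, either cached from
# segmentation or rasterized from the polygon.
instance_pixels <- function(inst) {
  if (!is.null(inst$pixels)) return(inst$pixels)
  r <- rasterize_polygon(inst$polygon)
  idx <- which(r$mask, arr.ind = TRUE)
  cbind(idx[, 1] - 1 + r$offset[1], idx[, 2] - 1 + r$offset[2])
}

#' Jaccard index of two detection instances
#'
#' Intersection over union of the rasterized masks at native resolution.
#'
#' @param a,b detection instances (see [new_instance()]).
#' @return J in \[0, 1\]; 0 when either mask is empty.
#' @export
jaccard_index <- function(a, b) {
  pa <- instance_pixels(a); pb <- instance_pixels(b)
  if (nrow(pa) == 0L || nrow(pb) == 0L) return(0)
  ka <- pa[, 1] * 1e6 + pa[, 2]
  kb <- pb[, 1] * 1e6 + pb[, 2]
  inter <- length(intersect(ka, kb))
  inter / (length(ka) + length(kb) - inter)
}

translate_polygon <- function(poly, dx, dy) {
  poly[, 1] <- poly[, 1] + dx
  poly[, 2] <- poly[, 2] + dy
  poly
}

# Regular-polygon approximation of an ellipse (used by the simulator and as
# ground-truth masks).
ellipse_polygon <- function(cx, cy, a, b, angle = 0, n = 32) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(th); y <- b * sin(th)
  ca <- cos(angle); sa <- sin(angle)
  cbind(cx + x * ca - y * sa, cy + x * sa + y * ca)
}
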