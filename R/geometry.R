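#' Polygon area by the Shoelace formula
#'
#' Computes the area enclosed by a simple polygon from its ordered vertices,
#' \deqn{A = \tfrac12 | \sum_i x_i y_{i+1} - \sum_i y_i x_{i+1} |}
#' with cyclic wraparound. The absolute value makes the result independent of
#' vertex orientation.
#'
#' @param polygon numeric matrix with two columns (x, y), at least 3 rows; the
#'   polygon is implicitly closed (do not repeat the first vertex).
#' @return area in squared coordinate units (pixels^2 for pixel polygons).
#' @examples
#' shoelace_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))  # unit square -> 1
#' @export
shoelace_area <- function(polygon) {
  polygon <- as_polygon(polygon)
  abs(signed_area(polygon))
}

# Signed area (positive for one orientation, negative for the other);
# internal because downstream code only relies on the sign for orientation.
signed_area <- function(polygon) {
  x <- polygon[, 1L]
  y <- polygon[, 2L]
  xn <- c(x[-1L], x[1L])
  yn <- c(y[-1L], y[1L])
  0.5 * sum(x * yn - y * xn)
}

#' Validate and canonicalize a polygon
#'
#' @param polygon two-column matrix, data.frame, or list with x/y components.
#' @return numeric matrix with columns named x, y; duplicate closing vertex
#'   removed.
#' @export
as_polygon <- function(polygon) {
  if (is.list(polygon) && !is.data.frame(polygon) && all(c("x", "y") %in% names(polygon))) {
    polygon <- cbind(polygon$x, polygon$y)
  }
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L) stop("polygon must have two columns (x, y)")
  storage.mode(polygon) <- "double"
  n <- nrow(polygon)
  if (n >= 2L && all(polygon[1L, ] == polygon[n, ])) polygon <- polygon[-n, , drop = FALSE]
  if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices")
  colnames(polygon) <- c("x", "y")
  polygon
}

# Orient a polygon so its signed area is positive (consistent vertex order).
orient_polygon <- function(polygon) {
  if (signed_area(polygon) < 0) polygon[rev(seq_len(nrow(polygon))), , drop = FALSE] else polygon
}

#' Tight axis-aligned bounding box of a polygon
#'
#' @param polygon two-column vertex matrix.
#' @return numeric vector c(xmin, ymin, xmax, ymax) in the 0-based half-open
#'   convention used throughout the package.
#' @export
polygon_bbox <- function(polygon) {
  polygon <- as_polygon(polygon)
  c(xmin = min(polygon[, 1L]), ymin = min(polygon[, 2L]),
    xmax = max(polygon[, 1L]), ymax = max(polygon[, 2L]))
}

polygon_centroid <- function(polygon) {
  polygon <- as_polygon(polygon)
  x <- polygon[, 1L]; y <- polygon[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Test points against a polygon
#'
#' Thin wrapper over \code{mgcv::in.out} (compiled crossing test).
#'
#' @param polygon two-column vertex matrix.
#' @param pts two-column matrix of query points.
#' @return logical vector, TRUE for points inside.
#' @export
points_in_polygon <- function(polygon, pts) {
  polygon <- as_polygon(polygon)
  bnd <- rbind(polygon, polygon[1L, , drop = FALSE])
  mgcv::in.out(bnd, as.matrix(pts))
}

# Rasterize a polygon onto a height x width pixel grid (no anti-aliasing):
# a pixel belongs to the polygon iff its center lies inside. Pixel (row r,
# col c) covers [c-1, c) x [r-1, r) with center (c - 0.5, r - 0.5).
rasterize_polygon <- function(polygon, width, height) {
  polygon <- as_polygon(polygon)
  bb <- polygon_bbox(polygon)
  c0 <- max(1L, floor(bb["xmin"] + 0.5) + 1L)
  c1 <- min(as.integer(width), ceiling(bb["xmax"] + 0.5))
  r0 <- max(1L, floor(bb["ymin"] + 0.5) + 1L)
  r1 <- min(as.integer(height), ceiling(bb["ymax"] + 0.5))
  mask <- matrix(FALSE, height, width)
  if (c1 < c0 || r1 < r0) return(mask)
  cols <- c0:c1
  rows <- r0:r1
  pts <- cbind(rep(cols - 0.5, each = length(rows)), rep(rows - 0.5, length(cols)))
  inside <- points_in_polygon(polygon, pts)
  mask[rows, cols] <- matrix(inside, nrow = length(rows))
  mask
}

# Trace the boundaries of a binary mask as closed polygons in 0-based pixel
# coordinates. The 0.5-level contour of the (zero-padded) indicator runs
# midway between foreground and background pixel centers, so a traced
# rectangle of k pixels has Shoelace area k - 0.5 (four corner cuts); the
# sub-pixel boundary error this carries is covered by the module tolerances.
trace_mask_contours <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  z <- matrix(0, w + 2L, h + 2L)
  z[2:(w + 1L), 2:(h + 1L)] <- t(mask * 1)
  xs <- (0:(w + 1L)) - 0.5
  ys <- (0:(h + 1L)) - 0.5
  loops <- grDevices::contourLines(x = xs, y = ys, z = z, levels = 0.5)
  lapply(loops, function(l) orient_polygon(as_polygon(cbind(l$x, l$y))))
}

# Clip a polygon against a convex clip polygon (Sutherland-Hodgman).
# Returns NULL when the intersection is empty or degenerate.
clip_polygon_convex <- function(subject, clip) {
  subject <- as_polygon(subject)
  clip <- orient_polygon(as_polygon(clip))
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) < 3L) return(NULL)
    p1 <- clip[i, ]
    p2 <- clip[if (i == nc) 1L else i + 1L, ]
    ex <- p2[1L] - p1[1L]; ey <- p2[2L] - p1[2L]
    side <- ex * (out[, 2L] - p1[2L]) - ey * (out[, 1L] - p1[1L])
    # cross(p2-p1, q-p1) >= 0 is the interior side for a positively oriented clip
    inside <- side >= -1e-12
    if (all(inside)) next
    n <- nrow(out)
    nxt <- c(2:n, 1L)
    res_x <- numeric(0); res_y <- numeric(0)
    for (k in seq_len(n)) {
      j <- nxt[k]
      if (inside[k]) { res_x <- c(res_x, out[k, 1L]); res_y <- c(res_y, out[k, 2L]) }
      if (inside[k] != inside[j]) {
        t <- side[k] / (side[k] - side[j])
        res_x <- c(res_x, out[k, 1L] + t * (out[j, 1L] - out[k, 1L]))
        res_y <- c(res_y, out[k, 2L] + t * (out[j, 2L] - out[k, 2L]))
      }
    }
    if (length(res_x) < 3L) return(NULL)
    out <- cbind(x = res_x, y = res_y)
  }
  if (is.null(out) || nrow(out) < 3L || abs(signed_area(out)) < 1e-9) NULL else out
}

#' Construct a bounding box
#'
#' Boxes are axis-aligned, 0-based and half-open: the box covers
#' \code{[xmin, xmax) x [ymin, ymax)} in pixel coordinates with the origin at
#' the top-left corner, x rightward and y downward.
#'
#' @param xmin,ymin,xmax,ymax box edges in pixels.
#' @return named numeric vector of class \code{bbox}.
#' @export
bbox <- function(xmin, ymin, xmax, ymax) {
  if (xmax <= xmin || ymax <= ymin) stop("bbox must have positive width and height")
  structure(c(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax), class = "bbox")
}

bbox_area <- function(b) (b[["xmax"]] - b[["xmin"]]) * (b[["ymax"]] - b[["ymin"]])

clip_bbox <- function(b, width, height) {
  x0 <- max(0, b[["xmin"]]); y0 <- max(0, b[["ymin"]])
  x1 <- min(width, b[["xmax"]]); y1 <- min(height, b[["ymax"]])
  if (x1 <= x0 || y1 <= y0) return(NULL)
  bbox(x0, y0, x1, y1)
}
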