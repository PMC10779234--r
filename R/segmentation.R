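#' Otsu threshold of an 8-bit intensity sample
#'
#' Exhaustively evaluates every split of the 256-level histogram and returns
#' the threshold maximizing the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2}. When several consecutive
#' splits tie (an empty gap between two populations), the midpoint of the
#' maximizing plateau is returned, so the cut falls strictly between the
#' populations. Foreground is the \code{value > threshold} side.
#'
#' @param values integer intensities in 0..255.
#' @return integer threshold in 0..254.
#' @export
otsu_threshold <- function(values) {
  values <- as.integer(round(values))
  if (any(values < 0L | values > 255L)) stop("intensities must be in 0..255")
  h <- tabulate(values + 1L, nbins = 256L)
  n <- sum(h)
  if (sum(h > 0L) < 2L) stop("degenerate histogram")
  lev <- 0:255
  w0 <- cumsum(h) / n              # class weight for t = 0..255 (<= t side)
  s0 <- cumsum(h * lev)
  mu_t <- s0[256L] / n
  mu0 <- s0 / pmax(cumsum(h), 1L)
  w1 <- 1 - w0
  mu1 <- (s0[256L] - s0) / pmax(n - cumsum(h), 1L)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  bcv <- bcv[1:255]
  plateau <- which(bcv >= max(bcv) * (1 - 1e-12))
  as.integer(round(mean(plateau))) - 1L
}

# Scalar channel for thresholding. "bgdist": Euclidean RGB distance from the
# background color estimated as the median of the 1-px image border (robust
# across black/grey/brown mats, and invariant under intensity negation).
# "luma": Rec.601 grayscale.
scalar_channel <- function(image, channel_strategy = c("bgdist", "luma")) {
  channel_strategy <- match.arg(channel_strategy)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (channel_strategy == "luma") {
    v <- 0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
    return(round(v))
  }
  border <- c(1L, h)
  bg <- vapply(1:3, function(k) {
    ch <- image[, , k]
    stats::median(c(ch[border, ], ch[, c(1L, w)]))
  }, numeric(1))
  d2 <- (image[, , 1L] - bg[1L])^2 + (image[, , 2L] - bg[2L])^2 +
    (image[, , 3L] - bg[3L])^2
  round(sqrt(d2) / sqrt(3))   # max RGB distance 255*sqrt(3) -> 0..255
}

label_components <- function(mask) {
  t(EBImage::bwlabel(t(mask * 1)))
}

# Score a candidate foreground mask by the size of its largest connected
# component restricted to the central window (central half of the image).
central_component_score <- function(mask) {
  if (!any(mask)) return(0L)
  lab <- label_components(mask)
  h <- nrow(mask); w <- ncol(mask)
  win <- lab[max(1L, floor(h / 4)):ceiling(3 * h / 4),
             max(1L, floor(w / 4)):ceiling(3 * w / 4)]
  counts <- tabulate(win[win > 0])
  if (length(counts) == 0L) 0L else max(counts)
}

#' Segment the leaf from the background
#'
#' Applies automatic (Otsu) thresholding to a scalar channel of the image
#' and picks the side of the threshold containing the leaf, decided by the
#' larger connected component in the central image window.
#'
#' @param image height x width x 3 array, 0-255.
#' @param channel_strategy "bgdist" (default; color distance from the
#'   border-median background estimate) or "luma".
#' @return logical matrix (TRUE = leaf candidate foreground).
#' @export
to_binary_mask <- function(image, channel_strategy = c("bgdist", "luma")) {
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("image must be a height x width x 3 array")
  v <- scalar_channel(image, channel_strategy)
  thr <- otsu_threshold(v)
  high <- v > thr
  if (central_component_score(high) >= central_component_score(!high)) high else !high
}

#' Morphological cleanup of a binary mask
#'
#' Erosion then dilation with an elliptical (disc) structuring element, for
#' noise reduction and edge smoothing before contour extraction.
#'
#' @param mask logical matrix.
#' @param kernel_radius disc radius in pixels (>= 1).
#' @param erode_iters,dilate_iters iteration counts (0 = skip).
#' @return logical matrix of the same dimensions.
#' @export
clean_mask <- function(mask, kernel_radius = 1L, erode_iters = 2L, dilate_iters = 2L) {
  if (kernel_radius < 1) stop("kernel_radius must be >= 1")
  if (erode_iters < 0 || dilate_iters < 0) stop("iteration counts must be >= 0")
  if (erode_iters == 0L && dilate_iters == 0L) return(mask)
  brush <- EBImage::makeBrush(2L * kernel_radius + 1L, "disc")
  m <- t(mask * 1)
  for (i in seq_len(erode_iters)) m <- EBImage::erode(m, brush)
  for (i in seq_len(dilate_iters)) m <- EBImage::dilate(m, brush)
  t(m) > 0.5
}

largest_component_mask <- function(mask) {
  lab <- label_components(mask)
  counts <- tabulate(lab[lab > 0])
  if (length(counts) == 0L) stop("no leaf found")
  lab == which.max(counts)
}

#' Extract the outer contour of the leaf blade
#'
#' Returns the boundary polygon of the largest foreground component, traced
#' along the half-pixel crack between foreground and background, vertices in
#' consistent (positive signed area) order.
#'
#' @param mask logical matrix from \code{\link{to_binary_mask}} /
#'   \code{\link{clean_mask}}.
#' @return polygon matrix (x, y), 0-based pixel coordinates.
#' @export
extract_leaf_contour <- function(mask) {
  comp <- largest_component_mask(mask)
  loops <- trace_mask_contours(comp)
  if (length(loops) == 0L) stop("no leaf found")
  areas <- vapply(loops, shoelace_area, numeric(1))
  loops[[which.max(areas)]]
}

# TRUE where pixels look like the yellow halo ring rather than lesion tissue.
# The cut sits at the midpoint between typical lesion (~20) and halo (~140)
# yellowness so that, under edge blur, the lesion/halo boundary is localized
# without bias: a lower cut would claim the blurred transition ring for the
# halo and systematically shrink every ringed lesion.
halo_pixels <- function(image) {
  r <- image[, , 1L]; g <- image[, , 2L]; b <- image[, , 3L]
  pmin(r, g) - b > 85
}

#' Extract interior damage contours and marginal defoliation
#'
#' Three detectors run inside the segmented blade:
#' \itemize{
#'   \item \strong{holes} — background-classified regions strictly inside
#'     the blade (children of the outer contour in the containment
#'     hierarchy);
#'   \item \strong{lesions} — connected regions whose color deviates from
#'     the estimated healthy-blade color (median RGB over the blade) by more
#'     than \code{color_dist}; yellowish halo pixels are excluded when
#'     \code{exclude_halo} so the halo ring is not counted as damage;
#'   \item \strong{margin notches} — convex-deficiency regions of the leaf
#'     outline (convex hull minus blade), reported when
#'     \code{detect_notches}.
#' }
#' Regions smaller than \code{min_area_frac} times the leaf area are dropped.
#'
#' @param image the RGB image the mask came from.
#' @param mask cleaned binary mask.
#' @param leaf outer contour from \code{\link{extract_leaf_contour}}.
#' @param min_area_frac minimum region area as a fraction of leaf area.
#' @param color_dist RGB distance threshold for lesion pixels.
#' @param detect_notches report marginal defoliation.
#' @param exclude_halo do not count yellow halo pixels as lesion area.
#' @return list of regions, each a list(kind, polygon); empty for a healthy
#'   leaf.
#' @export
extract_damage_contours <- function(image, mask, leaf, min_area_frac = 0.0005,
                                    color_dist = 60, detect_notches = TRUE,
                                    exclude_halo = TRUE) {
  h <- nrow(mask); w <- ncol(mask)
  comp <- largest_component_mask(mask)
  leaf_area <- shoelace_area(leaf)
  min_area <- min_area_frac * leaf_area
  out <- list()

  # interior damage = anything inside the filled blade that is not healthy
  # tissue: background-classified pixels (holes, mat-colored lesions) or
  # pixels far from the healthy-blade color (lesions). Detecting both under
  # one mask draws every region boundary at the healthy-tissue transition
  # and keeps the hole and lesion sets disjoint.
  filled <- t(EBImage::fillHull(t(comp * 1))) > 0.5
  med <- vapply(1:3, function(k) stats::median(image[, , k][comp]), numeric(1))
  d2 <- (image[, , 1L] - med[1L])^2 + (image[, , 2L] - med[2L])^2 +
    (image[, , 3L] - med[3L])^2
  offcolor <- sqrt(d2) > color_dist
  if (exclude_halo) offcolor <- offcolor & !halo_pixels(image)
  unhealthy <- filled & (!comp | offcolor)
  unhealthy <- clean_mask(unhealthy, 1L, 1L, 1L)  # opening: drop specks/rims
  if (any(unhealthy)) {
    lab <- label_components(unhealthy)
    counts <- tabulate(lab[lab > 0])
    for (l in which(counts >= max(min_area, 3))) {
      m <- lab == l
      kind <- if (mean(!comp[m]) > 0.5) "hole" else "lesion"
      loops <- trace_mask_contours(m)
      areas <- vapply(loops, shoelace_area, numeric(1))
      out[[length(out) + 1L]] <- list(kind = kind,
                                      polygon = loops[[which.max(areas)]])
    }
    out <- order_regions(out)
  }

  if (detect_notches) {
    hull <- leaf[grDevices::chull(leaf[, 1L], leaf[, 2L]), , drop = FALSE]
    hull_mask <- rasterize_polygon(hull, w, h)
    notch <- hull_mask & !filled   # interior holes are not marginal defoliation
    notch <- clean_mask(notch, 1L, 1L, 1L)  # strip discretization slivers
    out <- c(out, mask_regions(notch, "margin_notch", min_area))
  }
  out
}

# Label a binary mask, keep components >= min_area, trace each component's
# outer boundary polygon; deterministic order (by top-left of bbox).
mask_regions <- function(mask, kind, min_area) {
  if (!any(mask)) return(list())
  lab <- label_components(mask)
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts >= max(min_area, 3))
  regs <- lapply(keep, function(l) {
    loops <- trace_mask_contours(lab == l)
    areas <- vapply(loops, shoelace_area, numeric(1))
    list(kind = kind, polygon = loops[[which.max(areas)]])
  })
  order_regions(regs)
}

# Deterministic region order: by bbox top-left corner.
order_regions <- function(regs) {
  if (length(regs) <= 1L) return(regs)
  key <- vapply(regs, function(r) {
    b <- polygon_bbox(r$polygon); b[["ymin"]] * 1e6 + b[["xmin"]]
  }, numeric(1))
  regs[order(key)]
}
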