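# Independent oracles and fixture builders shared across test files.
# Everything here is deliberately naive (loops, enumeration, supersampling)
# and independent of the package's computation paths.

# Random star-shaped polygon around a center: jittered evenly spaced angles
# keep every angular gap below pi, which guarantees simplicity.
random_simple_polygon <- function(n_vertices = 12, center = c(0, 0),
                                  radius = c(5, 20)) {
  ang <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices +
    stats::runif(n_vertices, -0.45, 0.45) * 2 * pi / n_vertices
  r <- stats::runif(n_vertices, radius[1], radius[2])
  cbind(x = center[1] + r * cos(ang), y = center[2] + r * sin(ang))
}

# Polygon area by supersampled point counting (even-odd crossing test,
# written out longhand so it shares no code with shoelace_area).
supersampled_area <- function(poly, step = 0.1) {
  xs <- seq(min(poly[, 1]) - step, max(poly[, 1]) + step, by = step)
  ys <- seq(min(poly[, 2]) - step, max(poly[, 2]) + step, by = step)
  pts_x <- rep(xs, times = length(ys))
  pts_y <- rep(ys, each = length(xs))
  n <- nrow(poly)
  inside <- rep(FALSE, length(pts_x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > pts_y) != (yj > pts_y)) &
      (pts_x < (xj - xi) * (pts_y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  sum(inside) * step^2
}

# Otsu by brute force: evaluate the between-class variance at every split;
# ties (empty gap bins) resolved to the plateau midpoint, the documented
# convention.
naive_otsu <- function(values) {
  values <- as.integer(round(values))
  v <- rep(-Inf, 255)
  for (t in 0:254) {
    lo <- values[values <= t]; hi <- values[values > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(values); w1 <- 1 - w0
    v[t + 1] <- w0 * w1 * (mean(lo) - mean(hi))^2
  }
  round(mean(which(v >= max(v) * (1 - 1e-12)))) - 1
}

naive_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  un <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (un > 0) inter / un else 0
}

# Exhaustive optimal assignment: the maximum number of detection/ground-truth
# pairs with IoU >= alpha (and equal class when class_aware), one-to-one.
brute_force_match <- function(detections, ground_truths, alpha,
                              class_aware = TRUE) {
  nd <- nrow(detections); ng <- nrow(ground_truths)
  allowed <- matrix(FALSE, nd, ng)
  for (i in seq_len(nd)) for (j in seq_len(ng)) {
    if (detections$image_id[i] != ground_truths$image_id[j]) next
    if (class_aware && detections$label[i] != ground_truths$label[j]) next
    allowed[i, j] <- naive_iou(
      as.numeric(detections[i, c("xmin", "ymin", "xmax", "ymax")]),
      as.numeric(ground_truths[j, c("xmin", "ymin", "xmax", "ymax")])) >= alpha
  }
  best <- 0
  recurse <- function(i, used) {
    if (i > nd) return(0)
    top <- recurse(i + 1, used)  # detection i unmatched
    for (j in seq_len(ng)) {
      if (allowed[i, j] && !used[j]) {
        used[j] <- TRUE
        top <- max(top, 1 + recurse(i + 1, used))
        used[j] <- FALSE
      }
    }
    top
  }
  tp <- if (nd == 0) 0 else recurse(1, rep(FALSE, ng))
  list(tp = tp, fp = nd - tp, fn = ng - tp)
}

# AP recomputed longhand: rank by confidence, build the raw PR points, then
# integrate max-precision-at-recall>=r over the recall partition.
naive_ap <- function(tp_in_conf_order, n_gt) {
  tp_c <- 0; fp_c <- 0
  rec <- numeric(0); prec <- numeric(0)
  for (flag in tp_in_conf_order) {
    if (flag) tp_c <- tp_c + 1 else fp_c <- fp_c + 1
    rec <- c(rec, tp_c / n_gt)
    prec <- c(prec, tp_c / (tp_c + fp_c))
  }
  ap <- 0; r_prev <- 0
  for (k in seq_along(rec)) {
    p_interp <- max(prec[rec >= rec[k]])
    ap <- ap + (rec[k] - r_prev) * p_interp
    r_prev <- rec[k]
  }
  ap
}

# Detection fixtures: data.frame builders.
det_df <- function(image_id, label, confidence, xmin, ymin, xmax, ymax) {
  data.frame(image_id = image_id, label = label, confidence = confidence,
             xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax,
             stringsAsFactors = FALSE)
}

gt_df <- function(image_id, label, xmin, ymin, xmax, ymax) {
  data.frame(image_id = image_id, label = label, xmin = xmin, ymin = ymin,
             xmax = xmax, ymax = ymax, stringsAsFactors = FALSE)
}

# Smaller canvases keep the image-pipeline tests fast; ranges scale with it.
small_canvas <- c(300, 200)

small_ranges <- function() synth_ranges(small_canvas)

# A quick single-lesion leaf for segmentation tests.
quick_leaf <- function(lesions = list(), seed = 7, background = "black",
                       blur_sigma = 0.6, noise_sd = 4) {
  leaf_spec(canvas_size = small_canvas,
            background_color = leaf_palette()$mats[[background]],
            blade = list(center = small_canvas / 2, semi_axes = c(85, 55)),
            lesions = lesions, blur_sigma = blur_sigma, noise_sd = noise_sd,
            seed = seed)
}

# An annotation object built directly from boxes (for the format tests).
manual_annotation <- function(boxes, image_size = c(600, 400),
                              leaf_area = 50000, kinds = NULL,
                              image_id = "img.png") {
  n <- nrow(boxes)
  areas <- (boxes$xmax - boxes$xmin) * (boxes$ymax - boxes$ymin) * 0.7
  dp <- damage_percent(areas, leaf_area)
  df <- data.frame(kind = if (is.null(kinds)) rep("lesion", n) else kinds,
                   xmin = boxes$xmin, ymin = boxes$ymin, xmax = boxes$xmax,
                   ymax = boxes$ymax, area = areas, dp = dp,
                   severity = classify_severity(pmax(dp, 1e-6)),
                   stringsAsFactors = FALSE)
  structure(list(image_id = image_id, image_size = as.numeric(image_size),
                 leaf_area = leaf_area, reference_area = leaf_area,
                 reference = "self", regions = df, polygons = NULL,
                 total_dp = sum(df$dp), healthy = n == 0L),
            class = "leaf_annotation")
}
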