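#' Five-level severity bins
#'
#' The default boundaries grade the per-defect damage percentage Dp into
#' five classes: ClassOne (0 < Dp < 1.1), ClassTwo (1.1 <= Dp < 2.4),
#' ClassThree (2.4 <= Dp < 4.1), ClassFour (4.1 <= Dp < 6.7) and ClassFive
#' (Dp >= 6.7). Bins are half-open \code{[lower, upper)} so every positive
#' Dp maps to exactly one class.
#'
#' @param boundaries strictly increasing upper boundaries of the first four
#'   classes (percent).
#' @param labels five class labels.
#' @return a \code{severity_bins} list.
#' @export
severity_bins <- function(boundaries = c(1.1, 2.4, 4.1, 6.7),
                          labels = c("ClassOne", "ClassTwo", "ClassThree",
                                     "ClassFour", "ClassFive")) {
  if (length(boundaries) + 1L != length(labels))
    stop("need one more label than boundary")
  if (any(diff(boundaries) <= 0) || any(boundaries <= 0))
    stop("boundaries must be positive and strictly increasing")
  structure(list(boundaries = as.numeric(boundaries), labels = labels),
            class = "severity_bins")
}

#' Classify damage percentages into severity classes
#'
#' @param dp vector of damage percentages; all must be > 0 (zero-damage
#'   regions are never created by the pipeline).
#' @param bins a \code{\link{severity_bins}} object.
#' @return character vector of class labels.
#' @export
classify_severity <- function(dp, bins = severity_bins()) {
  if (any(dp <= 0)) stop("dp must be positive")
  bins$labels[findInterval(dp, bins$boundaries) + 1L]
}

#' Average leaf area over a dataset
#'
#' Arithmetic mean of the per-image blade areas, the dataset-wide reference
#' area AT used by the batch damage-percentage convention.
#'
#' @param leaf_areas numeric vector of blade areas in pixels^2.
#' @return mean area.
#' @export
average_leaf_area <- function(leaf_areas) {
  if (length(leaf_areas) == 0L) stop("no leaf areas supplied")
  if (any(leaf_areas <= 0)) stop("leaf areas must be positive")
  mean(leaf_areas)
}

#' Damage percentage of a defect
#'
#' \code{Dp = defect_area / reference_area * c * 10}. With the default scale
#' constant \code{c = 10} this is the defect area as a percentage of the
#' reference leaf area.
#'
#' @param defect_area defect area in pixels^2 (>= 0).
#' @param reference_area reference leaf area (per-image blade area or the
#'   dataset average), > 0.
#' @param c scale constant.
#' @return damage percentage.
#' @export
damage_percent <- function(defect_area, reference_area, c = 10) {
  if (any(reference_area <= 0)) stop("reference_area must be positive")
  if (any(defect_area < 0)) stop("defect_area must be non-negative")
  defect_area / reference_area * c * 10
}

#' Annotation pipeline configuration
#'
#' @param channel_strategy Otsu scalar channel, see
#'   \code{\link{to_binary_mask}}.
#' @param kernel_radius,erode_iters,dilate_iters morphology, see
#'   \code{\link{clean_mask}}.
#' @param min_area_frac,color_dist,detect_notches,exclude_halo damage
#'   detection, see \code{\link{extract_damage_contours}}.
#' @param c scale constant of the damage-percentage formula.
#' @param bins severity bins.
#' @param reference "self" (the image's own blade area) or "dataset" (the
#'   mean blade area over a batch, supplied as \code{reference_area}).
#' @param reference_area dataset-average blade area, required when
#'   \code{reference = "dataset"}.
#' @return an \code{annotate_config} list.
#' @export
annotate_config <- function(channel_strategy = "bgdist", kernel_radius = 1L,
                            erode_iters = 2L, dilate_iters = 2L,
                            min_area_frac = 0.0005, color_dist = 60,
                            detect_notches = TRUE, exclude_halo = TRUE,
                            c = 10, bins = severity_bins(),
                            reference = c("self", "dataset"),
                            reference_area = NULL) {
  reference <- match.arg(reference)
  if (reference == "dataset" && is.null(reference_area))
    stop("reference = 'dataset' needs a reference_area")
  structure(list(channel_strategy = channel_strategy,
                 kernel_radius = kernel_radius, erode_iters = erode_iters,
                 dilate_iters = dilate_iters, min_area_frac = min_area_frac,
                 color_dist = color_dist, detect_notches = detect_notches,
                 exclude_halo = exclude_halo, c = c, bins = bins,
                 reference = reference, reference_area = reference_area),
            class = "annotate_config")
}

#' Annotate one leaf image
#'
#' Runs the full single-image pipeline: Otsu segmentation, morphological
#' cleanup, outer-contour extraction, damage-contour extraction, Shoelace
#' areas, damage percentages and severity classes.
#'
#' Under the per-image reference convention (\code{reference = "self"}) the
#' reference area is the recovered outer-contour area plus any recovered
#' margin-notch areas, i.e. an estimate of the intact blade: a margin notch
#' removes tissue from the outer contour, so the contour area alone would
#' understate the blade of exactly the leaves being graded.
#'
#' @param image an RGB array (0-255) or a path to a PNG file.
#' @param config an \code{\link{annotate_config}}.
#' @param image_id identifier stored in the annotation (defaults to the file
#'   path, or "image" for in-memory arrays).
#' @return a \code{leaf_annotation}: image_id, image_size, leaf_area,
#'   reference_area, reference mode, regions (kind, bbox, area, dp,
#'   severity), polygons, total_dp, healthy flag.
#' @export
annotate_image <- function(image, config = annotate_config(), image_id = NULL) {
  if (is.character(image)) {
    if (is.null(image_id)) image_id <- image
    image <- read_leaf_image(image)
  }
  if (is.null(image_id)) image_id <- "image"
  res <- tryCatch({
    mask <- to_binary_mask(image, config$channel_strategy)
    mask <- clean_mask(mask, config$kernel_radius, config$erode_iters,
                       config$dilate_iters)
    leaf <- extract_leaf_contour(mask)
    regions <- extract_damage_contours(image, mask, leaf,
                                       min_area_frac = config$min_area_frac,
                                       color_dist = config$color_dist,
                                       detect_notches = config$detect_notches,
                                       exclude_halo = config$exclude_halo)
    list(mask = mask, leaf = leaf, regions = regions)
  }, error = function(e) {
    stop(sprintf("annotate_image [%s]: %s", image_id, conditionMessage(e)),
         call. = FALSE)
  })
  leaf_area <- shoelace_area(res$leaf)
  areas <- vapply(res$regions, function(r) shoelace_area(r$polygon), numeric(1))
  kinds <- vapply(res$regions, function(r) r$kind, character(1))
  notch_area <- sum(areas[kinds == "margin_notch"])
  reference_area <- if (config$reference == "dataset") config$reference_area
                    else leaf_area + notch_area
  build_annotation(image_id, c(ncol(image[, , 1L]), nrow(image[, , 1L])),
                   leaf_area, reference_area, config$reference,
                   res$regions, areas, config)
}

build_annotation <- function(image_id, image_size, leaf_area, reference_area,
                             reference_mode, regions, areas, config) {
  n <- length(regions)
  if (n > 0L) {
    dp <- damage_percent(areas, reference_area, config$c)
    bbs <- t(vapply(regions, function(r) polygon_bbox(r$polygon), numeric(4)))
    df <- data.frame(kind = vapply(regions, `[[`, character(1), "kind"),
                     xmin = bbs[, 1L], ymin = bbs[, 2L],
                     xmax = bbs[, 3L], ymax = bbs[, 4L],
                     area = areas, dp = dp,
                     severity = classify_severity(dp, config$bins),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(kind = character(), xmin = numeric(), ymin = numeric(),
                     xmax = numeric(), ymax = numeric(), area = numeric(),
                     dp = numeric(), severity = character(),
                     stringsAsFactors = FALSE)
  }
  structure(list(image_id = image_id, image_size = as.numeric(image_size),
                 leaf_area = leaf_area, reference_area = reference_area,
                 reference = reference_mode, regions = df,
                 polygons = lapply(regions, `[[`, "polygon"),
                 total_dp = sum(df$dp), healthy = n == 0L),
            class = "leaf_annotation")
}

#' @export
print.leaf_annotation <- function(x, ...) {
  cat(sprintf("Leaf annotation: %s (%d x %d)\n", x$image_id,
              x$image_size[1L], x$image_size[2L]))
  cat(sprintf("  leaf area %.0f px^2, reference %.0f px^2 (%s)\n",
              x$leaf_area, x$reference_area, x$reference))
  if (x$healthy) {
    cat("  healthy: no damage regions\n")
  } else {
    cat(sprintf("  %d damage region(s), total Dp = %.2f%%\n",
                nrow(x$regions), x$total_dp))
    for (i in seq_len(nrow(x$regions)))
      cat(sprintf("    [%d] %s area %.0f px^2 Dp %.2f%% -> %s\n", i,
                  x$regions$kind[i], x$regions$area[i], x$regions$dp[i],
                  x$regions$severity[i]))
  }
  invisible(x)
}

#' Annotate a batch of images with the dataset-average reference area
#'
#' Two passes: the first recovers each image's blade area (self reference),
#' the second rescales damage percentages to the dataset mean blade area AT
#' and re-grades severities.
#'
#' @param paths character vector of PNG paths.
#' @param config an \code{\link{annotate_config}}; its \code{reference}
#'   field selects the convention ("dataset" by default for batches).
#' @param reference overrides \code{config$reference}.
#' @return list of \code{leaf_annotation} objects.
#' @export
annotate_dataset <- function(paths, config = annotate_config(),
                             reference = "dataset") {
  config$reference <- "self"
  config$reference_area <- NULL
  anns <- lapply(paths, annotate_image, config = config)
  if (reference != "dataset") return(anns)
  at <- average_leaf_area(vapply(anns, function(a) a$reference_area, numeric(1)))
  lapply(anns, function(a) {
    a$reference <- "dataset"
    a$reference_area <- at
    if (nrow(a$regions) > 0L) {
      a$regions$dp <- damage_percent(a$regions$area, at, config$c)
      a$regions$severity <- classify_severity(a$regions$dp, config$bins)
    }
    a$total_dp <- sum(a$regions$dp)
    a
  })
}

#' Read a PNG leaf image as a 0-255 RGB array
#'
#' @param path PNG file.
#' @return height x width x 3 numeric array.
#' @export
read_leaf_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Match recovered damage regions to ground truth
#'
#' Pairs each ground-truth region with the recovered region of maximal
#' bounding-box IoU (greedy, one-to-one) and tabulates severity agreement
#' and damage-percentage errors; used by the parameter-recovery experiment.
#'
#' @param annotation a \code{leaf_annotation}.
#' @param truth_regions data.frame with xmin/ymin/xmax/ymax/true_dp/severity.
#' @param min_iou minimum bbox IoU to accept a pairing.
#' @return data.frame, one row per ground-truth region: matched flag,
#'   recovered dp, dp_error, severity_match.
#' @export
region_recovery_stats <- function(annotation, truth_regions, min_iou = 0.25) {
  n <- nrow(truth_regions)
  out <- data.frame(matched = logical(n), dp = NA_real_,
                    dp_error = NA_real_, severity_match = FALSE)
  if (n == 0L) return(out)
  rec <- annotation$regions
  taken <- rep(FALSE, nrow(rec))
  for (i in seq_len(n)) {
    if (nrow(rec) == 0L) break
    tb <- as.numeric(truth_regions[i, c("xmin", "ymin", "xmax", "ymax")])
    ious <- vapply(seq_len(nrow(rec)), function(j)
      iou(tb, as.numeric(rec[j, c("xmin", "ymin", "xmax", "ymax")])), numeric(1))
    ious[taken] <- -1
    j <- which.max(ious)
    if (ious[j] >= min_iou) {
      taken[j] <- TRUE
      out$matched[i] <- TRUE
      out$dp[i] <- rec$dp[j]
      out$dp_error[i] <- rec$dp[j] - truth_regions$true_dp[i]
      out$severity_match[i] <- rec$severity[j] == truth_regions$severity[i]
    }
  }
  out
}
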