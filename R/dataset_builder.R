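# Nearest-neighbor resample of an RGB array to (width, height); exact box
# scaling, no interpolation artifacts in masks or ground truth.
resize_image <- function(image, target_size) {
  W <- as.integer(target_size[1L]); H <- as.integer(target_size[2L])
  h0 <- dim(image)[1L]; w0 <- dim(image)[2L]
  rows <- pmin(h0, floor((seq_len(H) - 0.5) * h0 / H) + 1L)
  cols <- pmin(w0, floor((seq_len(W) - 0.5) * w0 / W) + 1L)
  image[rows, cols, , drop = FALSE]
}

#' Resize an image and rescale its annotation
#'
#' Box coordinates scale by (W_new/W_old, H_new/H_old); region and leaf
#' areas scale by the product of the two factors and damage percentages are
#' recomputed from the scaled areas. The annotation is flagged
#' \code{resized} because polygon-level quantities re-measured on the
#' resampled raster would differ slightly from the scaled ones.
#'
#' @param image RGB array (0-255).
#' @param annotation a \code{leaf_annotation} (or NULL).
#' @param target_size c(width, height); aspect ratio is not preserved.
#' @return list(image, annotation).
#' @export
resize_with_boxes <- function(image, annotation, target_size) {
  if (any(target_size < 1)) stop("target size must be >= 1 pixel")
  h0 <- dim(image)[1L]; w0 <- dim(image)[2L]
  sx <- target_size[1L] / w0; sy <- target_size[2L] / h0
  out_img <- resize_image(image, target_size)
  if (is.null(annotation)) return(list(image = out_img, annotation = NULL))
  a <- annotation
  a$image_size <- as.numeric(target_size)
  if (nrow(a$regions) > 0L) {
    a$regions$xmin <- a$regions$xmin * sx; a$regions$xmax <- a$regions$xmax * sx
    a$regions$ymin <- a$regions$ymin * sy; a$regions$ymax <- a$regions$ymax * sy
    a$regions$area <- a$regions$area * sx * sy
  }
  a$leaf_area <- a$leaf_area * sx * sy
  a$reference_area <- a$reference_area * sx * sy
  if (nrow(a$regions) > 0L)
    a$regions$dp <- damage_percent(a$regions$area, a$reference_area)
  a$total_dp <- sum(a$regions$dp)
  a$polygons <- lapply(a$polygons, function(p) {
    p[, 1L] <- p[, 1L] * sx; p[, 2L] <- p[, 2L] * sy; p
  })
  a$resized <- TRUE
  list(image = out_img, annotation = a)
}

#' Split items into train / validation / test sets
#'
#' Items are shuffled by seed, then each split receives
#' \code{floor(n * fraction)} items; leftover items go first to train, any
#' further by largest fractional remainder. The partition is disjoint,
#' exhaustive, and deterministic given the seed.
#'
#' @param items vector or list of items (e.g. file paths).
#' @param fractions three positive fractions summing to 1
#'   (train, val, test).
#' @param seed integer.
#' @return list(split = named character vector ("train"/"val"/"test") per
#'   item index, counts, fractions, seed, items).
#' @export
split_dataset <- function(items, fractions = c(0.7, 0.2, 0.1), seed = 1L) {
  n <- length(items)
  if (length(fractions) != 3L || any(fractions <= 0))
    stop("need three positive fractions")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (n < 3L) stop("need at least as many items as splits")
  base <- floor(n * fractions)
  rem <- n - sum(base)
  if (rem > 0) { base[1L] <- base[1L] + 1L; rem <- rem - 1L }
  if (rem > 0) {
    frac <- n * fractions - floor(n * fractions)
    for (k in order(-frac)) {
      if (rem == 0) break
      base[k] <- base[k] + 1L; rem <- rem - 1L
    }
  }
  ord <- with_seed(seed, sample.int(n))
  lab <- rep(c("train", "val", "test"), times = base)
  split <- character(n)
  split[ord] <- lab
  structure(list(split = split,
                 counts = c(train = base[1L], val = base[2L], test = base[3L]),
                 fractions = fractions, seed = seed, items = items),
            class = "dataset_split")
}

annotation_boxes <- function(annotation) {
  if (is.data.frame(annotation)) {
    stopifnot(all(c("label", "xmin", "ymin", "xmax", "ymax") %in% names(annotation)))
    return(annotation[, c("label", "xmin", "ymin", "xmax", "ymax")])
  }
  reg <- annotation$regions
  data.frame(label = reg$severity, xmin = reg$xmin, ymin = reg$ymin,
             xmax = reg$xmax, ymax = reg$ymax, stringsAsFactors = FALSE)
}

paste_region <- function(canvas, image, off) {
  H2 <- dim(canvas)[1L]; W2 <- dim(canvas)[2L]
  h <- dim(image)[1L]; w <- dim(image)[2L]
  dx0 <- max(0L, floor(off[1L])); dy0 <- max(0L, floor(off[2L]))
  dx1 <- min(W2, floor(off[1L]) + w); dy1 <- min(H2, floor(off[2L]) + h)
  if (dx1 <= dx0 || dy1 <= dy0) return(canvas)
  sx <- (dx0 - floor(off[1L])) + 1L
  sy <- (dy0 - floor(off[2L])) + 1L
  canvas[(dy0 + 1L):dy1, (dx0 + 1L):dx1, ] <-
    image[sy:(sy + (dy1 - dy0) - 1L), sx:(sx + (dx1 - dx0) - 1L), , drop = FALSE]
  canvas
}

#' Mosaic augmentation: fuse four images into one
#'
#' A 2W x 2H canvas is divided at a random center (uniform in the central
#' jitter window); each input is anchored at the center in one quadrant
#' (top-left, top-right, bottom-left, bottom-right), cropped to fit. Boxes
#' are translated, clipped to the canvas, and dropped when the clipped area
#' falls below \code{min_visibility} times the original area. The canvas is
#' finally rescaled to \code{canvas_size}.
#'
#' @param images list of exactly 4 RGB arrays of equal size (W x H).
#' @param annotations list of 4 \code{leaf_annotation}s or box data.frames
#'   (label, xmin, ymin, xmax, ymax).
#' @param canvas_size output size c(width, height); defaults to the input
#'   size.
#' @param center_jitter half-width of the center window as a fraction of the
#'   half-canvas: 0.5 means the center falls in the central 50% of the
#'   canvas; 0 pins it to the exact middle.
#' @param min_visibility minimum surviving area fraction for a clipped box.
#' @param seed integer.
#' @return list(image, boxes) where boxes is a data.frame(label, xmin, ymin,
#'   xmax, ymax).
#' @export
mosaic <- function(images, annotations, canvas_size = NULL, center_jitter = 0.5,
                   min_visibility = 0.1, seed = 1L) {
  if (length(images) != 4L || length(annotations) != 4L)
    stop("mosaic needs exactly 4 images and 4 annotations")
  H <- dim(images[[1L]])[1L]; W <- dim(images[[1L]])[2L]
  for (im in images)
    if (!all(dim(im)[1:2] == c(H, W))) stop("mosaic inputs must share one size")
  if (is.null(canvas_size)) canvas_size <- c(W, H)
  ctr <- with_seed(seed, c(
    stats::runif(1, W * (1 - center_jitter), W * (1 + center_jitter)),
    stats::runif(1, H * (1 - center_jitter), H * (1 + center_jitter))))
  canvas <- array(114, dim = c(2L * H, 2L * W, 3L))  # neutral grey fill
  offs <- list(c(ctr[1L] - W, ctr[2L] - H), c(ctr[1L], ctr[2L] - H),
               c(ctr[1L] - W, ctr[2L]), c(ctr[1L], ctr[2L]))
  rows <- list()
  for (q in 1:4) {
    canvas <- paste_region(canvas, images[[q]], offs[[q]])
    bx <- annotation_boxes(annotations[[q]])
    for (i in seq_len(nrow(bx))) {
      b0 <- bbox(bx$xmin[i] + offs[[q]][1L], bx$ymin[i] + offs[[q]][2L],
                 bx$xmax[i] + offs[[q]][1L], bx$ymax[i] + offs[[q]][2L])
      orig <- bbox_area(b0)
      b <- clip_bbox(b0, 2 * W, 2 * H)
      if (is.null(b) || bbox_area(b) < min_visibility * orig) next
      rows[[length(rows) + 1L]] <- data.frame(
        label = bx$label[i], xmin = b[["xmin"]], ymin = b[["ymin"]],
        xmax = b[["xmax"]], ymax = b[["ymax"]], stringsAsFactors = FALSE)
    }
  }
  boxes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), xmin = numeric(), ymin = numeric(),
               xmax = numeric(), ymax = numeric(), stringsAsFactors = FALSE)
  out <- resize_image(canvas, canvas_size)
  sx <- canvas_size[1L] / (2 * W); sy <- canvas_size[2L] / (2 * H)
  boxes$xmin <- boxes$xmin * sx; boxes$xmax <- boxes$xmax * sx
  boxes$ymin <- boxes$ymin * sy; boxes$ymax <- boxes$ymax * sy
  list(image = out, boxes = boxes)
}

#' Basic image augmentations with consistent box handling
#'
#' Supported ops: \code{hflip}, \code{vflip}, \code{rotate90} (clockwise),
#' \code{crop}, \code{scale}, \code{translate} (geometric: boxes transform
#' with the image) and \code{blur}, \code{color_jitter}, \code{noise}
#' (photometric: boxes untouched). Arbitrary-angle rotation is deliberately
#' not offered — only right-angle rotations keep axis-aligned boxes exact.
#'
#' @param image RGB array (0-255).
#' @param boxes data.frame(label, xmin, ymin, xmax, ymax) or a
#'   \code{leaf_annotation}.
#' @param ops character vector of operations, applied in order.
#' @param seed integer driving the stochastic ops.
#' @param params optional overrides: crop_frac (default 0.8), scale_range
#'   (c(0.8, 1.2)), translate_frac (0.1), blur_sigma (1), jitter_amp (20),
#'   noise_sd (5), min_visibility (0.25).
#' @return list(image, boxes).
#' @export
basic_augment <- function(image, boxes, ops, seed = 1L, params = list()) {
  supported <- c("hflip", "vflip", "rotate90", "crop", "scale", "translate",
                 "blur", "color_jitter", "noise")
  bad <- setdiff(ops, supported)
  if (length(bad)) stop(sprintf("unsupported augmentation op '%s'", bad[1L]))
  p <- utils::modifyList(list(crop_frac = 0.8, scale_range = c(0.8, 1.2),
                              translate_frac = 0.1, blur_sigma = 1,
                              jitter_amp = 20, noise_sd = 5,
                              min_visibility = 0.25), params)
  bx <- annotation_boxes(boxes)
  with_seed(seed, {
    for (op in ops) {
      H <- dim(image)[1L]; W <- dim(image)[2L]
      if (op == "hflip") {
        image <- image[, rev(seq_len(W)), , drop = FALSE]
        if (nrow(bx)) {
          x0 <- W - bx$xmax; bx$xmax <- W - bx$xmin; bx$xmin <- x0
        }
      } else if (op == "vflip") {
        image <- image[rev(seq_len(H)), , , drop = FALSE]
        if (nrow(bx)) {
          y0 <- H - bx$ymax; bx$ymax <- H - bx$ymin; bx$ymin <- y0
        }
      } else if (op == "rotate90") {
        image <- aperm(image, c(2L, 1L, 3L))[, rev(seq_len(H)), , drop = FALSE]
        if (nrow(bx)) {
          nx0 <- H - bx$ymax; nx1 <- H - bx$ymin
          ny0 <- bx$xmin; ny1 <- bx$xmax
          bx$xmin <- nx0; bx$xmax <- nx1; bx$ymin <- ny0; bx$ymax <- ny1
        }
      } else if (op == "crop") {
        cw <- round(W * p$crop_frac); ch <- round(H * p$crop_frac)
        ox <- sample.int(W - cw + 1L, 1L) - 1L
        oy <- sample.int(H - ch + 1L, 1L) - 1L
        image <- image[(oy + 1L):(oy + ch), (ox + 1L):(ox + cw), , drop = FALSE]
        bx <- shift_clip_boxes(bx, -ox, -oy, cw, ch, p$min_visibility)
      } else if (op == "scale") {
        s <- stats::runif(1, p$scale_range[1L], p$scale_range[2L])
        nw <- max(1L, round(W * s)); nh <- max(1L, round(H * s))
        image <- resize_image(image, c(nw, nh))
        bx$xmin <- bx$xmin * nw / W; bx$xmax <- bx$xmax * nw / W
        bx$ymin <- bx$ymin * nh / H; bx$ymax <- bx$ymax * nh / H
      } else if (op == "translate") {
        dx <- round(stats::runif(1, -p$translate_frac, p$translate_frac) * W)
        dy <- round(stats::runif(1, -p$translate_frac, p$translate_frac) * H)
        shifted <- array(114, dim = dim(image))
        shifted <- paste_region(shifted, image, c(dx, dy))
        image <- shifted
        bx <- shift_clip_boxes(bx, dx, dy, W, H, p$min_visibility)
      } else if (op == "blur") {
        for (k in 1:3)
          image[, , k] <- t(EBImage::gblur(t(image[, , k]), sigma = p$blur_sigma))
      } else if (op == "color_jitter") {
        off <- stats::runif(3, -p$jitter_amp, p$jitter_amp)
        for (k in 1:3) image[, , k] <- image[, , k] + off[k]
        image[image < 0] <- 0; image[image > 255] <- 255
      } else if (op == "noise") {
        image <- image + array(stats::rnorm(length(image), 0, p$noise_sd),
                               dim = dim(image))
        image[image < 0] <- 0; image[image > 255] <- 255
      }
    }
    list(image = image, boxes = bx)
  })
}

shift_clip_boxes <- function(bx, dx, dy, W, H, min_visibility) {
  if (nrow(bx) == 0L) return(bx)
  keep <- logical(nrow(bx)); rows <- vector("list", nrow(bx))
  for (i in seq_len(nrow(bx))) {
    b0 <- bbox(bx$xmin[i] + dx, bx$ymin[i] + dy, bx$xmax[i] + dx, bx$ymax[i] + dy)
    b <- clip_bbox(b0, W, H)
    if (is.null(b) || bbox_area(b) < min_visibility * bbox_area(b0)) next
    keep[i] <- TRUE
    rows[[i]] <- data.frame(label = bx$label[i], xmin = b[["xmin"]],
                            ymin = b[["ymin"]], xmax = b[["xmax"]],
                            ymax = b[["ymax"]], stringsAsFactors = FALSE)
  }
  if (!any(keep)) return(bx[0, , drop = FALSE])
  do.call(rbind, rows[keep])
}

#' Build a training-ready YOLO dataset directory
#'
#' Resizes images, writes YOLO labels, splits into train/val/test
#' directories (images/ and labels/ subtrees), optionally appends mosaic
#' composites to the training split, and writes a manifest JSON.
#'
#' @param in_dir directory of PNG images with a \code{ground_truth.jsonl}
#'   sidecar (from \code{\link{generate_dataset}}) or VOC XML files next to
#'   the images.
#' @param out_dir output root.
#' @param target_size c(width, height) for uniform resizing.
#' @param fractions train/val/test fractions.
#' @param seed integer.
#' @param n_mosaic number of mosaic composites appended to train.
#' @param config annotation config used when annotations must be computed
#'   from the images (no sidecar or XML present).
#' @return invisibly, the manifest list.
#' @export
build_yolo_dataset <- function(in_dir, out_dir, target_size = c(600, 400),
                               fractions = c(0.7, 0.2, 0.1), seed = 1L,
                               n_mosaic = 0L, config = annotate_config()) {
  paths <- sort(list.files(in_dir, pattern = "\\.png$", full.names = TRUE))
  if (length(paths) == 0L) stop(sprintf("no PNG images found in '%s'", in_dir))
  anns <- load_or_compute_annotations(in_dir, paths, config)
  sp <- split_dataset(paths, fractions, seed)
  for (s in c("train", "val", "test")) {
    dir.create(file.path(out_dir, "images", s), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "labels", s), recursive = TRUE, showWarnings = FALSE)
  }
  resized <- list()
  for (i in seq_along(paths)) {
    img <- read_leaf_image(paths[i])
    rs <- resize_with_boxes(img, anns[[i]], target_size)
    s <- sp$split[i]
    stem <- tools::file_path_sans_ext(basename(paths[i]))
    png::writePNG(rs$image / 255, file.path(out_dir, "images", s,
                                            paste0(stem, ".png")))
    write_yolo_txt(to_yolo(rs$annotation),
                   file.path(out_dir, "labels", s, paste0(stem, ".txt")))
    resized[[i]] <- rs
  }
  train_idx <- which(sp$split == "train")
  n_mosaic <- if (length(train_idx) >= 4L) n_mosaic else 0L
  for (m in seq_len(n_mosaic)) {
    pick <- with_seed(seed + 1000L + m, sample(train_idx, 4L))
    mz <- mosaic(lapply(resized[pick], `[[`, "image"),
                 lapply(resized[pick], `[[`, "annotation"),
                 canvas_size = target_size, seed = seed + 2000L + m)
    stem <- sprintf("mosaic_%04d", m)
    png::writePNG(mz$image / 255, file.path(out_dir, "images", "train",
                                            paste0(stem, ".png")))
    cls <- severity_class_names()
    rec <- data.frame(class_index = match(mz$boxes$label, cls) - 1L,
                      xc = (mz$boxes$xmin + mz$boxes$xmax) / 2 / target_size[1L],
                      yc = (mz$boxes$ymin + mz$boxes$ymax) / 2 / target_size[2L],
                      w = (mz$boxes$xmax - mz$boxes$xmin) / target_size[1L],
                      h = (mz$boxes$ymax - mz$boxes$ymin) / target_size[2L])
    write_yolo_txt(rec, file.path(out_dir, "labels", "train", paste0(stem, ".txt")))
  }
  manifest <- list(n_images = length(paths), target_size = target_size,
                   fractions = fractions, seed = seed, n_mosaic = n_mosaic,
                   counts = as.list(sp$counts),
                   split = stats::setNames(sp$split, basename(paths)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

load_or_compute_annotations <- function(in_dir, paths, config) {
  sidecar <- file.path(in_dir, "ground_truth.jsonl")
  if (file.exists(sidecar)) {
    gt <- read_ground_truth(sidecar)
    names(gt) <- vapply(gt, `[[`, character(1), "path")
    return(lapply(paths, function(p) truth_to_annotation(gt[[basename(p)]], p)))
  }
  lapply(paths, annotate_image, config = config)
}

# Promote a ground-truth sidecar record to a leaf_annotation.
truth_to_annotation <- function(rec, path) {
  if (is.null(rec)) stop(sprintf("no ground truth for '%s'", path))
  regs <- rec$regions
  n <- if (is.data.frame(regs)) nrow(regs) else 0L
  df <- if (n > 0L)
    data.frame(kind = regs$kind, xmin = regs$xmin, ymin = regs$ymin,
               xmax = regs$xmax, ymax = regs$ymax, area = regs$true_area,
               dp = regs$true_dp, severity = regs$severity,
               stringsAsFactors = FALSE)
  else
    data.frame(kind = character(), xmin = numeric(), ymin = numeric(),
               xmax = numeric(), ymax = numeric(), area = numeric(),
               dp = numeric(), severity = character(), stringsAsFactors = FALSE)
  structure(list(image_id = path, image_size = c(rec$width, rec$height),
                 leaf_area = rec$leaf_area, reference_area = rec$leaf_area,
                 reference = "self", regions = df, polygons = NULL,
                 total_dp = rec$total_dp, healthy = n == 0L),
            class = "leaf_annotation")
}
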