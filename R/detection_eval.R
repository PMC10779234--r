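#' Intersection over union of two boxes
#'
#' \code{|A intersect B| / |A union B|}; 0 for disjoint boxes. Boxes are
#' c(xmin, ymin, xmax, ymax).
#'
#' @param a,b boxes (numeric length-4 vectors, or 4-column matrices for
#'   row-wise evaluation).
#' @return IoU in [0, 1].
#' @export
iou <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  ix <- pmax(0, pmin(a[, 3L], b[, 3L]) - pmax(a[, 1L], b[, 1L]))
  iy <- pmax(0, pmin(a[, 4L], b[, 4L]) - pmax(a[, 2L], b[, 2L]))
  inter <- ix * iy
  area_a <- (a[, 3L] - a[, 1L]) * (a[, 4L] - a[, 2L])
  area_b <- (b[, 3L] - b[, 1L]) * (b[, 4L] - b[, 2L])
  un <- area_a + area_b - inter
  unname(ifelse(un > 0, inter / un, 0))
}

#' Generalized IoU of two boxes
#'
#' \code{IoU - |C \\ (A union B)| / |C|} where C is the smallest enclosing
#' axis-aligned box. Ranges over (-1, 1]; negative for well-separated boxes,
#' equal to IoU when C coincides with the union's bounding box.
#'
#' @inheritParams iou
#' @return GIoU in (-1, 1].
#' @export
giou <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  ix <- pmax(0, pmin(a[, 3L], b[, 3L]) - pmax(a[, 1L], b[, 1L]))
  iy <- pmax(0, pmin(a[, 4L], b[, 4L]) - pmax(a[, 2L], b[, 2L]))
  inter <- ix * iy
  area_a <- (a[, 3L] - a[, 1L]) * (a[, 4L] - a[, 2L])
  area_b <- (b[, 3L] - b[, 1L]) * (b[, 4L] - b[, 2L])
  un <- area_a + area_b - inter
  cw <- pmax(a[, 3L], b[, 3L]) - pmin(a[, 1L], b[, 1L])
  ch <- pmax(a[, 4L], b[, 4L]) - pmin(a[, 2L], b[, 2L])
  cc <- cw * ch
  unname(ifelse(un > 0, inter / un, 0) - ifelse(cc > 0, (cc - un) / cc, 0))
}

det_cols <- c("xmin", "ymin", "xmax", "ymax")

#' Greedy matching of detections to ground truths
#'
#' Per image, detections are visited in descending confidence (ties broken
#' by larger best-IoU, then input order); each claims the still-unmatched
#' ground truth (same class when \code{class_aware}) of highest IoU >=
#' \code{alpha}, otherwise it is a false positive. Unmatched ground truths
#' are false negatives.
#'
#' @param detections data.frame(image_id, label, confidence, xmin, ymin,
#'   xmax, ymax).
#' @param ground_truths data.frame(image_id, label, xmin, ymin, xmax, ymax).
#' @param alpha IoU threshold.
#' @param class_aware match only within the same class.
#' @return list: \code{detections} with tp flag and matched gt row index
#'   (into \code{ground_truths}), \code{gt_matched} logical per ground
#'   truth, and the TP/FP/FN counts.
#' @export
match_detections <- function(detections, ground_truths, alpha = 0.5,
                             class_aware = TRUE) {
  nd <- nrow(detections); ng <- nrow(ground_truths)
  tp <- logical(nd); match_idx <- rep(NA_integer_, nd)
  gt_matched <- logical(ng)
  if (nd > 0L) {
    best_static <- vapply(seq_len(nd), function(i) {
      cand <- which(ground_truths$image_id == detections$image_id[i] &
                      (!class_aware | ground_truths$label == detections$label[i]))
      if (length(cand) == 0L) return(0)
      max(iou(matrix(rep(as.numeric(detections[i, det_cols]), length(cand)),
                     ncol = 4L, byrow = TRUE),
              as.matrix(ground_truths[cand, det_cols])))
    }, numeric(1))
    ord <- order(-detections$confidence, -best_static, seq_len(nd))
    for (i in ord) {
      cand <- which(ground_truths$image_id == detections$image_id[i] &
                      !gt_matched &
                      (!class_aware | ground_truths$label == detections$label[i]))
      if (length(cand) == 0L) next
      ious <- iou(matrix(rep(as.numeric(detections[i, det_cols]), length(cand)),
                         ncol = 4L, byrow = TRUE),
                  as.matrix(ground_truths[cand, det_cols]))
      j <- which.max(ious)
      if (ious[j] >= alpha) {
        tp[i] <- TRUE
        match_idx[i] <- cand[j]
        gt_matched[cand[j]] <- TRUE
      }
    }
  }
  det <- detections
  det$tp <- tp
  det$gt_index <- match_idx
  list(detections = det, gt_matched = gt_matched, alpha = alpha,
       tp = sum(tp), fp = sum(!tp), fn = sum(!gt_matched))
}

#' Precision, recall, accuracy and F1 from detection counts
#'
#' R = TP/(TP+FN), P = TP/(TP+FP), A = (TP+TN)/(TP+TN+FP+FN),
#' F1 = 2PR/(P+R). True negatives are ill-defined for detectors; accuracy is
#' computed with the TN count as given (default 0) and reported as such.
#' Zero-denominator conventions: P = 0 when TP+FP = 0, R = 0 when
#' TP+FN = 0, F1 = 0 when P+R = 0, A = 0 when all counts are 0.
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @return list(precision, recall, accuracy, f1).
#' @export
precision_recall_accuracy_f1 <- function(tp, fp, fn, tn = 0) {
  if (any(c(tp, fp, fn, tn) < 0)) stop("counts must be non-negative")
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  a <- if (tp + tn + fp + fn > 0) (tp + tn) / (tp + tn + fp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, accuracy = a, f1 = f1)
}

#' Precision-recall curve from matched detections
#'
#' Sweeps the confidence threshold over the ranked detections and reports
#' the running precision and recall at each detection.
#'
#' @param match result of \code{\link{match_detections}} (single class).
#' @param n_gt number of ground truths for the class.
#' @return data.frame(confidence, recall, precision) in descending
#'   confidence order.
#' @export
pr_curve <- function(match, n_gt) {
  det <- match$detections
  ord <- order(-det$confidence)
  tp_c <- cumsum(det$tp[ord])
  fp_c <- cumsum(!det$tp[ord])
  data.frame(confidence = det$confidence[ord],
             recall = if (n_gt > 0) tp_c / n_gt else tp_c * 0,
             precision = tp_c / (tp_c + fp_c))
}

#' Average precision for one class
#'
#' Area under the monotone-envelope precision-recall curve (precision made
#' non-increasing in recall) by all-point summation
#' \eqn{\sum_k (r_k - r_{k-1}) \, p_{interp}(r_k)} — the continuous AP
#' used in modern detector toolkits.
#'
#' @param match result of \code{\link{match_detections}} for one class.
#' @param n_gt number of ground truths (> 0).
#' @return AP in [0, 1].
#' @export
average_precision <- function(match, n_gt) {
  if (n_gt <= 0) stop("AP undefined without ground truths")
  pr <- pr_curve(match, n_gt)
  if (nrow(pr) == 0L) return(0)
  p_env <- rev(cummax(rev(pr$precision)))
  r_prev <- c(0, pr$recall[-nrow(pr)])
  sum((pr$recall - r_prev) * p_env)
}

#' Per-class AP and mean average precision
#'
#' mAP@alpha is the mean over classes of AP@alpha; mAP@0.5-0.95 averages
#' alpha over 0.50, 0.55, ..., 0.95. Classes without any ground truth are
#' excluded from the mean (and reported in \code{skipped}).
#'
#' @param detections,ground_truths as in \code{\link{match_detections}}.
#' @param alphas IoU thresholds to evaluate.
#' @return list(per_class data.frame(label, alpha, ap, n_gt),
#'   map named vector (one entry per alpha), map_range mean over the alpha
#'   grid, skipped classes).
#' @export
mean_average_precision <- function(detections, ground_truths,
                                   alphas = seq(0.5, 0.95, by = 0.05)) {
  classes <- sort(unique(c(detections$label, ground_truths$label)))
  with_gt <- classes[classes %in% ground_truths$label]
  skipped <- setdiff(classes, with_gt)
  if (length(with_gt) == 0L) stop("no class has ground truth")
  rows <- list()
  for (cl in with_gt) {
    d <- detections[detections$label == cl, , drop = FALSE]
    g <- ground_truths[ground_truths$label == cl, , drop = FALSE]
    for (a in alphas) {
      m <- match_detections(d, g, alpha = a, class_aware = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        label = cl, alpha = a, ap = average_precision(m, nrow(g)),
        n_gt = nrow(g), stringsAsFactors = FALSE)
    }
  }
  per_class <- do.call(rbind, rows)
  map <- vapply(alphas, function(a) mean(per_class$ap[per_class$alpha == a]),
                numeric(1))
  names(map) <- sprintf("mAP@%.2f", alphas)
  list(per_class = per_class, map = map, map_range = mean(map),
       skipped = skipped)
}

#' Background-aware confusion matrix for detections
#'
#' Detections above the confidence threshold are matched to ground truths
#' class-agnostically (cross-class matches count as confusion). Matched
#' pairs increment (predicted class, true class); unmatched ground truths
#' fall in the background row of their true-class column (background false
#' negatives); unmatched detections fall in the background column of their
#' predicted-class row (background false positives).
#'
#' @param detections,ground_truths as in \code{\link{match_detections}}.
#' @param alpha IoU threshold.
#' @param conf_threshold minimum detection confidence.
#' @param classes class order for the axes.
#' @param normalize divide each true-class column by its total.
#' @return (K+1) x (K+1) matrix, rows = predicted, columns = true, last
#'   row/column = background.
#' @export
detection_confusion_matrix <- function(detections, ground_truths, alpha = 0.5,
                                       conf_threshold = 0.25,
                                       classes = severity_class_names(),
                                       normalize = FALSE) {
  det <- detections[detections$confidence >= conf_threshold, , drop = FALSE]
  m <- match_detections(det, ground_truths, alpha = alpha, class_aware = FALSE)
  k <- length(classes)
  cm <- matrix(0, k + 1L, k + 1L,
               dimnames = list(pred = c(classes, "background"),
                               true = c(classes, "background")))
  d <- m$detections
  for (i in seq_len(nrow(d))) {
    pi <- match(d$label[i], classes)
    if (is.na(pi)) stop(sprintf("unknown class '%s'", d$label[i]))
    if (d$tp[i]) {
      ti <- match(ground_truths$label[d$gt_index[i]], classes)
      cm[pi, ti] <- cm[pi, ti] + 1
    } else {
      cm[pi, k + 1L] <- cm[pi, k + 1L] + 1
    }
  }
  for (j in which(!m$gt_matched)) {
    ti <- match(ground_truths$label[j], classes)
    cm[k + 1L, ti] <- cm[k + 1L, ti] + 1
  }
  if (normalize) {
    tot <- colSums(cm)
    for (j in which(tot > 0)) cm[, j] <- cm[, j] / tot[j]
  }
  cm
}

#' F1 versus confidence threshold
#'
#' Evaluates the micro-averaged F1 (class-aware matching pooled over all
#' classes and images) at each distinct detection confidence used as the
#' threshold, and reports the maximizing threshold (lowest threshold on
#' ties).
#'
#' @param detections,ground_truths as in \code{\link{match_detections}}.
#' @param alpha IoU threshold.
#' @return list(curve data.frame(confidence, tp, fp, fn, f1), best_f1,
#'   best_confidence).
#' @export
f1_confidence_curve <- function(detections, ground_truths, alpha = 0.5) {
  if (nrow(detections) == 0L) stop("need at least one detection")
  thr <- sort(unique(detections$confidence))
  rows <- lapply(thr, function(t) {
    d <- detections[detections$confidence >= t, , drop = FALSE]
    m <- match_detections(d, ground_truths, alpha = alpha, class_aware = TRUE)
    f1 <- precision_recall_accuracy_f1(m$tp, m$fp, m$fn)$f1
    data.frame(confidence = t, tp = m$tp, fp = m$fp, fn = m$fn, f1 = f1)
  })
  curve <- do.call(rbind, rows)
  best <- which.max(curve$f1)
  list(curve = curve, best_f1 = curve$f1[best],
       best_confidence = curve$confidence[best])
}

#' Full evaluation summary for a set of predictions
#'
#' @param detections,ground_truths as in \code{\link{match_detections}}.
#' @param alpha IoU threshold for the headline metrics.
#' @param conf_threshold confidence threshold for the point metrics and the
#'   confusion matrix.
#' @param classes class order.
#' @return list with per-class AP, mAP@alpha, mAP@0.5-0.95, point
#'   precision/recall/accuracy/F1, PR curves, F1-confidence curve with its
#'   best point, and the background-aware confusion matrix.
#' @export
evaluate_detections <- function(detections, ground_truths, alpha = 0.5,
                                conf_threshold = 0.25,
                                classes = severity_class_names()) {
  maps <- mean_average_precision(detections, ground_truths)
  dthr <- detections[detections$confidence >= conf_threshold, , drop = FALSE]
  m <- match_detections(dthr, ground_truths, alpha = alpha, class_aware = TRUE)
  pt <- precision_recall_accuracy_f1(m$tp, m$fp, m$fn)
  f1c <- if (nrow(detections) > 0L)
    f1_confidence_curve(detections, ground_truths, alpha) else NULL
  list(per_class_ap = maps$per_class,
       map50 = unname(maps$map["mAP@0.50"]),
       map50_95 = maps$map_range,
       point = c(pt, tp = m$tp, fp = m$fp, fn = m$fn,
                 conf_threshold = conf_threshold),
       f1_curve = f1c$curve, best_f1 = f1c$best_f1,
       best_confidence = f1c$best_confidence,
       confusion = detection_confusion_matrix(detections, ground_truths,
                                              alpha, conf_threshold, classes),
       alpha = alpha)
}

#' Load YOLO-format labels or predictions from a directory
#'
#' One txt file per image; predictions carry a sixth confidence column.
#'
#' @param dir directory of YOLO txt files.
#' @param image_size c(width, height) used to denormalize the boxes.
#' @param class_names class order.
#' @return detections/ground-truth data.frame; a confidence column is
#'   present when the files carry one.
#' @export
read_yolo_dir <- function(dir, image_size, class_names = severity_class_names()) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  rows <- lapply(files, function(f) {
    rec <- read_yolo_txt(f)
    if (nrow(rec) == 0L) return(NULL)
    bx <- from_yolo(rec, image_size, class_names)
    bx$image_id <- tools::file_path_sans_ext(basename(f))
    if (!is.null(rec$confidence)) bx$confidence <- rec$confidence
    bx
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(image_id = character(), label = character(),
                      xmin = numeric(), ymin = numeric(), xmax = numeric(),
                      ymax = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
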