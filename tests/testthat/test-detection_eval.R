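test_that("iou matches hand-enumerated cases", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1.0)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0.0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)  # inter 1, union 7
})

test_that("giou matches hand-enumerated cases and is bounded by iou", {
  expect_equal(giou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1.0)
  expect_equal(giou(c(0, 0, 1, 1), c(2, 2, 3, 3)), -7 / 9)  # C = 9, union 2
  withr::with_seed(15, {
    for (rep in 1:50) {
      a <- sort(stats::runif(4, 0, 100)); b <- sort(stats::runif(4, 0, 100))
      ba <- c(a[1], a[3], a[2], a[4])[c(1, 2, 3, 4)]
      boxa <- c(a[1], a[2], a[1] + stats::runif(1, 1, 20), a[2] + stats::runif(1, 1, 20))
      boxb <- c(b[1], b[2], b[1] + stats::runif(1, 1, 20), b[2] + stats::runif(1, 1, 20))
      expect_lte(giou(boxa, boxb), iou(boxa, boxb) + 1e-12)
      expect_gt(giou(boxa, boxb), -1)
      expect_lte(iou(boxa, boxb), 1)
      expect_gte(iou(boxa, boxb), 0)
      expect_equal(iou(boxa, boxb), naive_iou(boxa, boxb))
    }
  })
})

test_that("matching handles the canonical single and double detection cases", {
  gt <- gt_df("a", "ClassOne", 0, 0, 10, 10)
  d1 <- det_df("a", "ClassOne", 0.9, 0, 0, 10, 10)
  m <- match_detections(d1, gt)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))
  # two detections on one ground truth: the higher confidence wins
  d2 <- det_df(c("a", "a"), "ClassOne", c(0.6, 0.9),
               c(0.5, 0), c(0.5, 0), c(10, 10), c(10, 10))
  m2 <- match_detections(d2, gt)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1, 1, 0))
  expect_true(m2$detections$tp[2])   # the 0.9 one
  expect_false(m2$detections$tp[1])
})

test_that("greedy matching agrees with exhaustive assignment on fixtures", {
  fixtures <- list(
    list(det = det_df("a", c("ClassOne", "ClassOne", "ClassTwo"),
                      c(0.9, 0.8, 0.7), c(0, 12, 30), c(0, 0, 0),
                      c(10, 22, 40), c(10, 10, 10)),
         gt = gt_df("a", c("ClassOne", "ClassTwo"), c(0, 30), c(0, 0),
                    c(10, 40), c(10, 10))),
    list(det = det_df("a", "ClassOne", c(0.9, 0.85, 0.8, 0.7, 0.6),
                      c(0, 1, 20, 21, 50), c(0, 0, 0, 0, 0),
                      c(10, 11, 30, 31, 60), c(10, 10, 10, 10, 10)),
         gt = gt_df("a", "ClassOne", c(0, 20, 40, 80), c(0, 0, 0, 0),
                    c(10, 30, 50, 90), c(10, 10, 10, 10))),
    list(det = det_df(c("a", "a", "b", "b", "b", "b"), "ClassThree",
                      c(0.95, 0.5, 0.9, 0.8, 0.4, 0.3),
                      c(0, 100, 5, 40, 42, 200), c(0, 100, 5, 40, 44, 200),
                      c(10, 110, 15, 50, 52, 210), c(10, 110, 15, 50, 54, 210)),
         gt = gt_df(c("a", "b", "b"), "ClassThree", c(0, 5, 40), c(0, 5, 40),
                    c(10, 15, 50), c(10, 15, 50))))
  for (fx in fixtures) {
    m <- match_detections(fx$det, fx$gt, alpha = 0.5)
    bf <- brute_force_match(fx$det, fx$gt, alpha = 0.5)
    expect_equal(m$tp, bf$tp)
    expect_equal(m$fp, bf$fp)
    expect_equal(m$fn, bf$fn)
  }
})

test_that("greedy matching never beats the optimal assignment", {
  withr::with_seed(44, {
    for (rep in 1:20) {
      nd <- sample(1:6, 1); ng <- sample(1:4, 1)
      det <- det_df("a", sample(c("ClassOne", "ClassTwo"), nd, replace = TRUE),
                    stats::runif(nd), stats::runif(nd, 0, 40),
                    stats::runif(nd, 0, 40), 0, 0)
      det$xmax <- det$xmin + stats::runif(nd, 5, 20)
      det$ymax <- det$ymin + stats::runif(nd, 5, 20)
      gt <- gt_df("a", sample(c("ClassOne", "ClassTwo"), ng, replace = TRUE),
                  stats::runif(ng, 0, 40), stats::runif(ng, 0, 40), 0, 0)
      gt$xmax <- gt$xmin + stats::runif(ng, 5, 20)
      gt$ymax <- gt$ymin + stats::runif(ng, 5, 20)
      m <- match_detections(det, gt, alpha = 0.3)
      bf <- brute_force_match(det, gt, alpha = 0.3)
      expect_lte(m$tp, bf$tp)
      expect_equal(m$tp + m$fp, nd)
      expect_equal(m$tp + m$fn, ng)
    }
  })
})

test_that("precision/recall/accuracy/F1 follow the count formulas", {
  r <- precision_recall_accuracy_f1(1, 0, 0, 0)
  expect_equal(unlist(r), c(precision = 1, recall = 1, accuracy = 1, f1 = 1))
  r2 <- precision_recall_accuracy_f1(3, 1, 2, 0)
  expect_equal(r2$precision, 0.75)
  expect_equal(r2$recall, 0.6)
  expect_equal(r2$f1, 2 / 3)
  expect_equal(r2$accuracy, 0.5)
  r3 <- precision_recall_accuracy_f1(0, 0, 5, 0)
  expect_equal(r3$precision, 0)  # stated zero-denominator convention
  expect_equal(r3$f1, 0)
  expect_error(precision_recall_accuracy_f1(-1, 0, 0, 0), "non-negative")
})

test_that("average precision reproduces hand-derived and oracle values", {
  gt <- gt_df("a", "ClassOne", c(0, 20), c(0, 0), c(10, 30), c(10, 10))
  det <- det_df("a", "ClassOne", c(0.9, 0.8, 0.7),
                c(0, 50, 20), c(0, 50, 0), c(10, 60, 30), c(10, 60, 10))
  m <- match_detections(det, gt, alpha = 0.5)
  expect_equal(average_precision(m, 2), 5 / 6)
  expect_equal(naive_ap(c(TRUE, FALSE, TRUE), 2), 5 / 6)
  # single perfect detection
  m1 <- match_detections(det[1, ], gt[1, ], alpha = 0.5)
  expect_equal(average_precision(m1, 1), 1.0)
  expect_error(average_precision(m1, 0), "undefined")
})

test_that("AP is invariant under order-preserving confidence rescaling", {
  withr::with_seed(8, {
    gt <- gt_df("a", "ClassOne", c(0, 20, 40), c(0, 0, 0), c(10, 30, 50),
                c(10, 10, 10))
    det <- det_df("a", "ClassOne", c(0.9, 0.7, 0.5, 0.3),
                  c(0, 20, 100, 41), c(0, 0, 100, 0),
                  c(10, 30, 110, 51), c(10, 10, 110, 10))
    ap1 <- average_precision(match_detections(det, gt), 3)
    det$confidence <- det$confidence * 0.3 + 0.05
    ap2 <- average_precision(match_detections(det, gt), 3)
    expect_equal(ap1, ap2)
    # and equals the longhand oracle
    m <- match_detections(det, gt)
    ord <- order(-m$detections$confidence)
    expect_equal(ap1, naive_ap(m$detections$tp[ord], 3))
  })
})

test_that("mAP averages per-class AP", {
  gt <- gt_df(c("a", "a"), c("ClassOne", "ClassTwo"), c(0, 20), c(0, 0),
              c(10, 30), c(10, 10))
  det <- det_df(c("a", "a", "a"), c("ClassOne", "ClassTwo", "ClassTwo"),
                c(0.9, 0.8, 0.7), c(0, 50, 20), c(0, 50, 0),
                c(10, 60, 30), c(10, 60, 10))
  # ClassOne AP = 1; ClassTwo: FP then TP -> AP = 0.5
  res <- mean_average_precision(det, gt, alphas = 0.5)
  expect_equal(unname(res$map), 0.75)
  one <- mean_average_precision(det[1, ], gt[1, ], alphas = 0.5)
  expect_equal(unname(one$map),
               one$per_class$ap[one$per_class$label == "ClassOne"])
})

test_that("a perfect detector scores mAP 1.0 across the alpha range", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(6, dir, ranges = small_ranges(), seed = 10,
                         canvas_size = small_canvas)
  gt_rows <- list()
  for (i in seq_along(ds$items)) {
    tr <- ds$items[[i]]$truth$regions
    if (nrow(tr) > 0)
      gt_rows[[i]] <- gt_df(sprintf("img%d", i), tr$severity, tr$xmin, tr$ymin,
                            tr$xmax, tr$ymax)
  }
  gts <- do.call(rbind, gt_rows)
  det <- gts; det$confidence <- 0.99
  res <- mean_average_precision(det, gts)
  expect_equal(res$map_range, 1.0)
  expect_equal(unname(res$map["mAP@0.50"]), 1.0)
})

test_that("per-class AP is non-increasing in alpha; range mAP <= mAP@0.5", {
  withr::with_seed(27, {
    gts <- gt_df("a", sample(severity_class_names()[1:3], 8, replace = TRUE),
                 stats::runif(8, 0, 200), stats::runif(8, 0, 200), 0, 0)
    gts$xmax <- gts$xmin + stats::runif(8, 10, 40)
    gts$ymax <- gts$ymin + stats::runif(8, 10, 40)
    det <- gts
    det$confidence <- stats::runif(8, 0.3, 1)
    jit <- function(v) v + stats::runif(8, -4, 4)
    det$xmin <- jit(det$xmin); det$ymin <- jit(det$ymin)
    det$xmax <- jit(det$xmax); det$ymax <- jit(det$ymax)
  })
  res <- mean_average_precision(det, gts)
  for (cl in unique(res$per_class$label)) {
    ap <- res$per_class$ap[res$per_class$label == cl]
    expect_true(all(diff(ap) <= 1e-12))
  }
  expect_lte(res$map_range, unname(res$map["mAP@0.50"]) + 1e-12)
})

test_that("confusion matrix matches hand tabulation and conserves counts", {
  gts <- gt_df(c("a", "a", "b", "b"),
               c("ClassOne", "ClassTwo", "ClassOne", "ClassFive"),
               c(0, 20, 0, 40), c(0, 20, 0, 40), c(10, 30, 10, 50),
               c(10, 30, 10, 50))
  det <- det_df(c("a", "a", "b", "b"),
                c("ClassOne", "ClassThree", "ClassTwo", "ClassFour"),
                c(0.9, 0.8, 0.7, 0.6),
                c(0, 20, 0, 100), c(0, 20, 0, 100),
                c(10, 30, 5, 110), c(10, 30, 10, 110))
  cm <- detection_confusion_matrix(det, gts, alpha = 0.5, conf_threshold = 0.25)
  expect_equal(cm["ClassOne", "ClassOne"], 1)       # exact match
  expect_equal(cm["ClassThree", "ClassTwo"], 1)     # cross-class confusion
  expect_equal(cm["ClassTwo", "ClassOne"], 1)       # half-box still IoU 0.5
  expect_equal(cm["ClassFour", "background"], 1)    # background false positive
  expect_equal(cm["background", "ClassFive"], 1)    # background false negative
  expect_equal(sum(cm), 5)
  expect_equal(sum(cm), nrow(gts) + 1)  # GT count + unmatched detections
})

test_that("confusion matrix normalization and edge cases", {
  gts <- gt_df(c("a", "a"), c("ClassOne", "ClassTwo"), c(0, 20), c(0, 20),
               c(10, 30), c(10, 30))
  det <- det_df(c("a", "a"), c("ClassOne", "ClassTwo"), c(0.9, 0.9),
                c(0, 20), c(0, 20), c(10, 30), c(10, 30))
  cm <- detection_confusion_matrix(det, gts, normalize = TRUE)
  expect_equal(cm["ClassOne", "ClassOne"], 1)
  expect_equal(cm["ClassTwo", "ClassTwo"], 1)
  # no detections: all ground-truth mass in the background row
  cm0 <- detection_confusion_matrix(det[0, ], gts)
  expect_equal(cm0["background", "ClassOne"], 1)
  expect_equal(cm0["background", "ClassTwo"], 1)
  expect_equal(sum(cm0), 2)
})

test_that("F1-confidence curve equals exhaustive recomputation", {
  gts <- gt_df("a", "ClassOne", c(0, 20, 40), c(0, 0, 0), c(10, 30, 50),
               c(10, 10, 10))
  det <- det_df("a", "ClassOne", c(0.9, 0.7, 0.5, 0.2),
                c(0, 20, 100, 40), c(0, 0, 100, 0),
                c(10, 30, 110, 50), c(10, 10, 110, 10))
  out <- f1_confidence_curve(det, gts)
  for (k in seq_len(nrow(out$curve))) {
    t <- out$curve$confidence[k]
    kept <- det[det$confidence >= t, , drop = FALSE]
    bf <- brute_force_match(kept, gts, alpha = 0.5)
    p <- if (bf$tp + bf$fp > 0) bf$tp / (bf$tp + bf$fp) else 0
    r <- if (bf$tp + bf$fn > 0) bf$tp / (bf$tp + bf$fn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    expect_equal(out$curve$f1[k], f1)
  }
  expect_equal(out$best_f1, max(out$curve$f1))
})

test_that("all-TP detections peak at the lowest threshold with F1 = 1", {
  gts <- gt_df("a", "ClassOne", c(0, 20), c(0, 0), c(10, 30), c(10, 10))
  det <- det_df("a", "ClassOne", c(0.9, 0.4), c(0, 20), c(0, 0), c(10, 30),
                c(10, 10))
  out <- f1_confidence_curve(det, gts)
  expect_equal(out$best_f1, 1)
  expect_equal(out$best_confidence, 0.4)
  # adding a low-confidence FP lowers F1 only below its confidence
  det2 <- rbind(det, det_df("a", "ClassOne", 0.1, 100, 100, 110, 110))
  out2 <- f1_confidence_curve(det2, gts)
  expect_equal(out2$curve$f1[out2$curve$confidence > 0.1],
               out$curve$f1)
  expect_lt(out2$curve$f1[out2$curve$confidence == 0.1], 1)
})
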