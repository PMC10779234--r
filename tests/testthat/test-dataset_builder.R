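test_that("resize scales boxes anisotropically", {
  img <- array(100, dim = c(800, 600, 3))  # 600 wide x 800 tall
  ann <- manual_annotation(data.frame(xmin = 100, ymin = 200, xmax = 200,
                                      ymax = 400), image_size = c(600, 800))
  out <- resize_with_boxes(img, ann, c(600, 400))
  expect_equal(dim(out$image)[1:2], c(400, 600))
  expect_equal(as.numeric(out$annotation$regions[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(100, 100, 200, 200))
  expect_true(out$annotation$resized)
})

test_that("identity resize leaves the annotation unchanged", {
  img <- array(100, dim = c(400, 600, 3))
  ann <- manual_annotation(data.frame(xmin = 50, ymin = 60, xmax = 90, ymax = 100))
  out <- resize_with_boxes(img, ann, c(600, 400))
  expect_equal(out$annotation$regions[, c("xmin", "ymin", "xmax", "ymax", "area", "dp")],
               ann$regions[, c("xmin", "ymin", "xmax", "ymax", "area", "dp")])
})

test_that("uniform 2x scale multiplies box areas by 4", {
  img <- array(100, dim = c(100, 200, 3))
  ann <- manual_annotation(data.frame(xmin = 20, ymin = 10, xmax = 60, ymax = 50),
                           image_size = c(200, 100))
  out <- resize_with_boxes(img, ann, c(400, 200))
  b <- out$annotation$regions
  expect_equal((b$xmax - b$xmin) * (b$ymax - b$ymin), 40 * 40 * 4)
  expect_equal(b$area, ann$regions$area * 4)
  expect_equal(b$dp, ann$regions$dp)  # dp invariant under uniform scaling
})

test_that("split allocates by floor with remainder to train first", {
  s100 <- split_dataset(seq_len(100), seed = 5)
  expect_equal(as.numeric(s100$counts), c(70, 20, 10))
  s10 <- split_dataset(seq_len(10), seed = 5)
  expect_equal(as.numeric(s10$counts), c(7, 2, 1))
  s9 <- split_dataset(seq_len(9), seed = 5)
  expect_equal(as.numeric(s9$counts), c(7, 1, 1))
})

test_that("split partitions deterministically", {
  a <- split_dataset(letters, seed = 42)
  b <- split_dataset(letters, seed = 42)
  expect_identical(a$split, b$split)
  expect_equal(length(a$split), 26)
  expect_setequal(unique(a$split), c("train", "val", "test"))
  d <- split_dataset(letters, seed = 43)
  expect_false(identical(a$split, d$split))
  expect_error(split_dataset(1:2), "at least as many items")
  expect_error(split_dataset(1:10, c(0.5, 0.5, 0.2)), "sum to 1")
})

test_that("mosaic with a centered split keeps all four boxes", {
  imgs <- lapply(1:4, function(i) array(i * 40, dim = c(40, 60, 3)))
  anns <- lapply(1:4, function(i)
    data.frame(label = "ClassOne", xmin = 20, ymin = 10, xmax = 40, ymax = 30,
               stringsAsFactors = FALSE))
  mz <- mosaic(imgs, anns, center_jitter = 0, min_visibility = 0, seed = 1)
  expect_equal(nrow(mz$boxes), 4)
  expect_equal(dim(mz$image)[1:2], c(40, 60))  # rescaled back to input size
  # quadrant corners land at half scale: TL box (20,10,40,30) -> (10,5,20,15)
  tl <- mz$boxes[mz$boxes$xmin == min(mz$boxes$xmin) &
                   mz$boxes$ymin == min(mz$boxes$ymin), ]
  expect_equal(as.numeric(tl[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(10, 5, 20, 15))
})

test_that("boxes clipped below min visibility are dropped", {
  bx <- data.frame(label = "ClassOne", xmin = 0, ymin = 0, xmax = 10, ymax = 10,
                   stringsAsFactors = FALSE)
  # shifted fully outside -> dropped
  out <- leafgrade:::shift_clip_boxes(bx, -20, 0, 60, 40, 0.1)
  expect_equal(nrow(out), 0)
  # half visible: kept at 10% visibility, dropped at 90%
  expect_equal(nrow(leafgrade:::shift_clip_boxes(bx, -5, 0, 60, 40, 0.1)), 1)
  expect_equal(nrow(leafgrade:::shift_clip_boxes(bx, -5, 0, 60, 40, 0.9)), 0)
})

test_that("seeded mosaics keep boxes inside the canvas", {
  withr::with_seed(71, {
    imgs <- lapply(1:4, function(i)
      array(stats::runif(60 * 40 * 3, 0, 255), dim = c(40, 60, 3)))
    anns <- lapply(1:4, function(i) {
      x0 <- stats::runif(2, 0, 50); y0 <- stats::runif(2, 0, 30)
      data.frame(label = sample(severity_class_names(), 2, replace = TRUE),
                 xmin = x0, ymin = y0, xmax = x0 + stats::runif(2, 2, 60 - x0),
                 ymax = y0 + stats::runif(2, 2, 40 - y0),
                 stringsAsFactors = FALSE)
    })
  })
  for (seed in 1:30) {
    mz <- mosaic(imgs, anns, seed = seed)
    expect_lte(nrow(mz$boxes), 8)
    if (nrow(mz$boxes) > 0) {
      expect_true(all(mz$boxes$xmin >= 0 & mz$boxes$ymin >= 0))
      expect_true(all(mz$boxes$xmax <= 60 & mz$boxes$ymax <= 40))
      expect_true(all(mz$boxes$xmax > mz$boxes$xmin))
      expect_true(all(mz$boxes$ymax > mz$boxes$ymin))
    }
  }
  expect_error(mosaic(imgs[1:3], anns[1:3]), "exactly 4")
  m1 <- mosaic(imgs, anns, seed = 9)
  m2 <- mosaic(imgs, anns, seed = 9)
  expect_identical(m1$image, m2$image)
  expect_identical(m1$boxes, m2$boxes)
})

test_that("horizontal flip maps boxes by x -> W - x", {
  img <- array(0, dim = c(400, 600, 3))
  sym <- data.frame(label = "ClassOne", xmin = 150, ymin = 100, xmax = 450,
                    ymax = 300, stringsAsFactors = FALSE)
  out <- basic_augment(img, sym, "hflip")
  expect_equal(as.numeric(out$boxes[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(150, 100, 450, 300))  # symmetric box maps to itself
  corner <- data.frame(label = "ClassOne", xmin = 0, ymin = 0, xmax = 100,
                       ymax = 100, stringsAsFactors = FALSE)
  out2 <- basic_augment(img, corner, "hflip")
  expect_equal(as.numeric(out2$boxes[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(500, 0, 600, 100))
})

test_that("hflip twice is the identity", {
  withr::with_seed(3, {
    img <- array(stats::runif(40 * 60 * 3, 0, 255), dim = c(40, 60, 3))
  })
  bx <- data.frame(label = "ClassTwo", xmin = 5, ymin = 7, xmax = 22, ymax = 31,
                   stringsAsFactors = FALSE)
  out <- basic_augment(img, bx, c("hflip", "hflip"))
  expect_identical(out$image, img)
  expect_equal(out$boxes, bx)
})

test_that("rotate90 transforms boxes consistently with the raster", {
  img <- array(0, dim = c(40, 60, 3))
  img[5:10, 8:20, 1] <- 255
  bx <- data.frame(label = "ClassOne", xmin = 7, ymin = 4, xmax = 20, ymax = 10,
                   stringsAsFactors = FALSE)
  out <- basic_augment(img, bx, "rotate90")
  expect_equal(dim(out$image)[1:2], c(60, 40))
  b <- out$boxes[1, ]
  # the bright block must fall inside the rotated box
  block <- which(out$image[, , 1] > 0, arr.ind = TRUE)
  expect_true(all(block[, 2] - 0.5 >= b$xmin & block[, 2] - 0.5 <= b$xmax))
  expect_true(all(block[, 1] - 0.5 >= b$ymin & block[, 1] - 0.5 <= b$ymax))
})

test_that("photometric ops leave boxes untouched", {
  withr::with_seed(5, {
    img <- array(stats::runif(40 * 60 * 3, 0, 255), dim = c(40, 60, 3))
  })
  bx <- data.frame(label = "ClassThree", xmin = 5, ymin = 7, xmax = 22,
                   ymax = 31, stringsAsFactors = FALSE)
  for (op in c("blur", "color_jitter", "noise")) {
    out <- basic_augment(img, bx, op, seed = 2)
    expect_equal(out$boxes, bx)
    expect_false(identical(out$image, img))
  }
  expect_error(basic_augment(img, bx, "warp"), "unsupported")
})

test_that("geometric augmentations never emit degenerate boxes", {
  withr::with_seed(6, {
    img <- array(stats::runif(40 * 60 * 3, 0, 255), dim = c(40, 60, 3))
    bx <- data.frame(label = "ClassOne",
                     xmin = c(0, 25, 50), ymin = c(0, 15, 30),
                     xmax = c(10, 40, 60), ymax = c(8, 28, 40),
                     stringsAsFactors = FALSE)
  })
  for (seed in 1:15) {
    out <- basic_augment(img, bx, c("crop", "scale", "translate"), seed = seed)
    if (nrow(out$boxes) > 0) {
      expect_true(all(out$boxes$xmax > out$boxes$xmin))
      expect_true(all(out$boxes$ymax > out$boxes$ymin))
    }
  }
})

test_that("build_yolo_dataset writes the YOLO tree with a manifest", {
  src <- withr::local_tempdir(); out <- withr::local_tempdir()
  generate_dataset(10, src, ranges = small_ranges(), seed = 30,
                   canvas_size = small_canvas)
  man <- build_yolo_dataset(src, out, target_size = small_canvas, seed = 4,
                            n_mosaic = 3)
  expect_equal(as.numeric(unlist(man$counts)), c(7, 2, 1))
  for (s in c("train", "val", "test")) {
    n_img <- length(list.files(file.path(out, "images", s), pattern = "png$"))
    n_lab <- length(list.files(file.path(out, "labels", s), pattern = "txt$"))
    expect_equal(n_img, n_lab)
  }
  expect_equal(length(list.files(file.path(out, "images", "train"))), 7 + 3)
  expect_true(file.exists(file.path(out, "manifest.json")))
  # labels parse back into valid classed boxes
  gt <- read_yolo_dir(file.path(out, "labels", "train"), small_canvas)
  expect_true(all(gt$label %in% severity_class_names()))
})
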