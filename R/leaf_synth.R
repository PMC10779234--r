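#' Default color palette for synthetic leaf scenes
#'
#' Mat backgrounds (black, grey, brown), healthy blade green, reddish-brown
#' lesion tissue and the yellow halo ring that surrounds bacterial-blight
#' lesions. Values are 8-bit RGB.
#'
#' @return named list of RGB triples.
#' @export
leaf_palette <- function() {
  list(
    mats = list(black = c(15, 15, 15), grey = c(128, 128, 128), brown = c(105, 70, 45)),
    blade = c(70, 115, 55),
    lesion = c(125, 60, 35),
    halo = c(225, 200, 60)
  )
}

#' Specify one damage region for a synthetic leaf
#'
#' Three kinds of damage are modelled: \code{interior_lesion} (necrotic spot,
#' reddish-brown, optionally ringed by a yellow halo), \code{hole} (tissue
#' loss inside the blade, rendered in the background color) and
#' \code{margin_notch} (tissue loss at the blade edge; the shape straddles
#' the blade outline and only the part inside the blade counts as damage).
#'
#' @param kind one of "interior_lesion", "hole", "margin_notch".
#' @param center ellipse center (x, y) in pixels.
#' @param semi_axes ellipse semi-axes (a, b) in pixels.
#' @param rotation ellipse rotation in radians.
#' @param halo_width width of the yellow halo ring in pixels (interior
#'   lesions only; halo pixels are never counted as damage area).
#' @param color RGB override; defaults to the palette lesion color or the
#'   background color for holes/notches.
#' @param n_vertices polygon density used for the analytic outline.
#' @return a \code{lesion_spec} list.
#' @export
lesion_spec <- function(kind = c("interior_lesion", "hole", "margin_notch"),
                        center, semi_axes, rotation = 0, halo_width = 0,
                        color = NULL, n_vertices = 120L) {
  kind <- match.arg(kind)
  if (any(semi_axes <= 0)) stop("lesion semi-axes must be positive")
  structure(list(kind = kind, center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes), rotation = rotation,
                 halo_width = halo_width, color = color,
                 n_vertices = as.integer(n_vertices)),
            class = "lesion_spec")
}

# Dense polygonalization of a (rotated) ellipse.
ellipse_polygon <- function(center, semi_axes, rotation = 0, n = 120L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x0 <- semi_axes[1L] * cos(t)
  y0 <- semi_axes[2L] * sin(t)
  cbind(x = center[1L] + x0 * cos(rotation) - y0 * sin(rotation),
        y = center[2L] + x0 * sin(rotation) + y0 * cos(rotation))
}

# Blade outline: a superellipse tapered toward a pointed tip at the +x end.
# The taper is mild enough that default blades stay convex, which the
# margin-notch logic (convex hull deficiency) relies on.
blade_polygon <- function(center, semi_axes, tip = 0.3, exponent = 2.2,
                          rotation = 0, n = 720L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  u <- sign(cos(t)) * abs(cos(t))^(2 / exponent)
  v <- sign(sin(t)) * abs(sin(t))^(2 / exponent)
  x0 <- semi_axes[1L] * u
  y0 <- semi_axes[2L] * v * (1 - tip * (u + 1) / 2)
  cbind(x = center[1L] + x0 * cos(rotation) - y0 * sin(rotation),
        y = center[2L] + x0 * sin(rotation) + y0 * cos(rotation))
}

#' Specify a synthetic leaf scene
#'
#' @param canvas_size c(width, height) in pixels.
#' @param background_color RGB mat color.
#' @param blade list with \code{center}, \code{semi_axes}, and optionally
#'   \code{tip} (tip sharpness in [0, 0.6]), \code{exponent} (superellipse
#'   exponent, 2 = ellipse), \code{rotation} (radians).
#' @param blade_color RGB of healthy tissue.
#' @param blade_jitter per-pixel uniform color jitter amplitude (8-bit units).
#' @param lesions list of \code{\link{lesion_spec}} objects.
#' @param blur_sigma Gaussian blur applied after ground truth is recorded
#'   (pixels; 0 disables).
#' @param noise_sd additive Gaussian intensity noise (8-bit units; 0 disables).
#' @param seed integer; fixes the rendered image bit-for-bit.
#' @return a \code{leaf_spec} list.
#' @export
leaf_spec <- function(canvas_size = c(600, 400),
                      background_color = leaf_palette()$mats$black,
                      blade = list(center = canvas_size / 2, semi_axes = c(170, 110)),
                      blade_color = leaf_palette()$blade,
                      blade_jitter = 10,
                      lesions = list(),
                      blur_sigma = 0.6,
                      noise_sd = 4,
                      seed = 1L) {
  blade$tip <- if (is.null(blade$tip)) 0.3 else blade$tip
  blade$exponent <- if (is.null(blade$exponent)) 2.2 else blade$exponent
  blade$rotation <- if (is.null(blade$rotation)) 0 else blade$rotation
  blade$n <- if (is.null(blade$n)) 720L else as.integer(blade$n)
  structure(list(canvas_size = as.integer(canvas_size),
                 background_color = as.numeric(background_color),
                 blade = blade, blade_color = as.numeric(blade_color),
                 blade_jitter = blade_jitter, lesions = lesions,
                 blur_sigma = blur_sigma, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "leaf_spec")
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

lesion_polygon <- function(lspec) {
  ellipse_polygon(lspec$center, lspec$semi_axes, lspec$rotation, lspec$n_vertices)
}

#' Render a synthetic leaf and its exact ground truth
#'
#' Renders the scene without anti-aliasing (a pixel takes a region's color
#' iff its center falls inside the region polygon), records the analytic
#' ground truth from the shape polygons, then applies blur and noise. Ground
#' truth is therefore exact with respect to the un-degraded geometry.
#'
#' Damage percentage for each region is
#' \code{Dp = true_area / leaf_area * c * 10} with \code{c = 10} (the
#' per-image reference convention), and severity classes follow
#' \code{\link{classify_severity}} with the default bins.
#'
#' @param spec a \code{\link{leaf_spec}}.
#' @return list with \code{image} (height x width x 3 array, 0-255) and
#'   \code{truth} (list: \code{leaf_area}, \code{regions} data.frame with
#'   kind/bbox/true_area/true_dp/severity, \code{polygons},
#'   \code{total_dp}, \code{blade_polygon}).
#' @export
generate_leaf <- function(spec) {
  stopifnot(inherits(spec, "leaf_spec"))
  w <- spec$canvas_size[1L]; h <- spec$canvas_size[2L]
  blade <- blade_polygon(spec$blade$center, spec$blade$semi_axes, spec$blade$tip,
                         spec$blade$exponent, spec$blade$rotation, spec$blade$n)
  bb <- polygon_bbox(blade)
  if (bb["xmin"] < 0 || bb["ymin"] < 0 || bb["xmax"] > w || bb["ymax"] > h)
    stop("blade outline extends outside the canvas")
  leaf_area <- shoelace_area(blade)

  # --- validate lesions and compute analytic ground truth ------------------
  polys <- list(); rows <- list()
  for (i in seq_along(spec$lesions)) {
    ls <- spec$lesions[[i]]
    poly <- lesion_polygon(ls)
    inside <- points_in_polygon(blade, poly)
    if (ls$kind == "margin_notch") {
      if (all(inside) || !any(inside))
        stop(sprintf("lesion %d: margin_notch must intersect the blade outline", i))
      region <- clip_polygon_convex(poly, blade)
      if (is.null(region)) stop(sprintf("lesion %d: empty blade intersection", i))
    } else {
      if (!all(inside))
        stop(sprintf("lesion %d: %s must lie fully inside the blade", i, ls$kind))
      region <- poly
    }
    area <- shoelace_area(region)
    bbr <- polygon_bbox(region)
    dp <- damage_percent(area, leaf_area)
    rows[[i]] <- data.frame(kind = ls$kind,
                            xmin = bbr[["xmin"]], ymin = bbr[["ymin"]],
                            xmax = bbr[["xmax"]], ymax = bbr[["ymax"]],
                            true_area = area, true_dp = dp,
                            severity = classify_severity(dp),
                            stringsAsFactors = FALSE)
    polys[[i]] <- region
  }
  regions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), xmin = numeric(), ymin = numeric(),
               xmax = numeric(), ymax = numeric(), true_area = numeric(),
               true_dp = numeric(), severity = character(), stringsAsFactors = FALSE)
  truth <- list(leaf_area = leaf_area, regions = regions, polygons = polys,
                total_dp = sum(regions$true_dp), blade_polygon = blade)

  # --- render ---------------------------------------------------------------
  img <- with_seed(spec$seed, {
    img <- array(0, dim = c(h, w, 3L))
    for (k in 1:3) img[, , k] <- spec$background_color[k]
    blade_mask <- rasterize_polygon(blade, w, h)
    nb <- sum(blade_mask)
    for (k in 1:3) {
      ch <- img[, , k]
      ch[blade_mask] <- spec$blade_color[k] +
        stats::runif(nb, -spec$blade_jitter, spec$blade_jitter)
      img[, , k] <- ch
    }
    pal <- leaf_palette()
    for (i in seq_along(spec$lesions)) {
      ls <- spec$lesions[[i]]
      lmask <- rasterize_polygon(lesion_polygon(ls), w, h)
      if (ls$kind == "interior_lesion") {
        if (ls$halo_width > 0) {
          brush <- EBImage::makeBrush(2L * ceiling(ls$halo_width) + 1L, "disc")
          ring <- t(EBImage::dilate(t(lmask * 1), brush)) > 0.5
          ring <- ring & !lmask & blade_mask
          for (k in 1:3) { ch <- img[, , k]; ch[ring] <- pal$halo[k]; img[, , k] <- ch }
        }
        col <- if (is.null(ls$color)) pal$lesion else ls$color
        nl <- sum(lmask)
        for (k in 1:3) {
          ch <- img[, , k]
          ch[lmask] <- col[k] + stats::runif(nl, -4, 4)
          img[, , k] <- ch
        }
      } else {
        col <- if (is.null(ls$color)) spec$background_color else ls$color
        for (k in 1:3) { ch <- img[, , k]; ch[lmask] <- col[k]; img[, , k] <- ch }
      }
    }
    if (spec$blur_sigma > 0)
      for (k in 1:3) img[, , k] <- t(EBImage::gblur(t(img[, , k]), sigma = spec$blur_sigma))
    if (spec$noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
    img <- round(img)
    img[img < 0] <- 0; img[img > 255] <- 255
    img
  })
  list(image = img, truth = truth)
}

#' Default parameter ranges for the synthetic dataset
#'
#' The ranges emulate single-leaf photographs on black/grey/brown mats, with
#' per-defect damage fractions spanning all five severity bins (0.35--10
#' percent of blade area). Blade semi-axes scale with the canvas so the
#' blade fills a realistic fraction of the frame at any output size
#' (140--185 x 90--125 px at the default 600 x 400).
#'
#' @param canvas_size c(width, height) the ranges are sized for.
#' @return named list of ranges consumed by \code{\link{generate_dataset}}.
#' @export
synth_ranges <- function(canvas_size = c(600, 400)) {
  list(dp_range = c(0.35, 10), dp_cap = 10,
       axes_a = c(0.2333, 0.3083) * canvas_size[1L],
       axes_b = c(0.225, 0.3125) * canvas_size[2L],
       tip = c(0.15, 0.4), exponent = c(2.0, 2.5), rotation = c(-0.3, 0.3),
       halo_widths = c(0L, 1L, 2L), extra_lesion_prob = 0.4,
       extra_dp = c(0.35, 1.0))
}

# Solve lesion semi-axes so the analytic region area hits target_area;
# for margin notches the blade-clipped area is matched iteratively.
solve_lesion <- function(kind, blade, target_area, center, aspect, rotation,
                         halo_width = 0) {
  ab <- target_area / pi * if (kind == "margin_notch") 2 else 1
  a <- sqrt(ab / aspect); b <- a * aspect
  ls <- lesion_spec(kind, center, c(a, b), rotation, halo_width)
  if (kind != "margin_notch") return(ls)
  for (iter in 1:6) {
    region <- clip_polygon_convex(lesion_polygon(ls), blade)
    if (is.null(region)) return(NULL)
    got <- shoelace_area(region)
    if (abs(got / target_area - 1) < 0.02) break
    s <- sqrt(target_area / got)
    ls$semi_axes <- ls$semi_axes * s
  }
  ls
}

# Draw one random leaf_spec whose primary damage region lands in `bin`
# (1..5); bin 0 means a healthy leaf.
random_leaf_spec <- function(bin, canvas_size, ranges, bins, seed) {
  with_seed(seed, {
    pal <- leaf_palette()
    mat <- pal$mats[[sample.int(3L, 1L)]]
    a <- stats::runif(1, ranges$axes_a[1], ranges$axes_a[2])
    b <- stats::runif(1, ranges$axes_b[1], ranges$axes_b[2])
    ctr <- canvas_size / 2 + stats::runif(2, -10, 10)
    blade_args <- list(center = ctr, semi_axes = c(a, b),
                       tip = stats::runif(1, ranges$tip[1], ranges$tip[2]),
                       exponent = stats::runif(1, ranges$exponent[1], ranges$exponent[2]),
                       rotation = stats::runif(1, ranges$rotation[1], ranges$rotation[2]))
    blade <- do.call(blade_polygon, c(blade_args, list(n = 720L)))
    blade_area <- shoelace_area(blade)
    lesions <- list()
    if (bin > 0) {
      lo <- if (bin == 1) ranges$dp_range[1] else bins$boundaries[bin - 1]
      hi <- if (bin == 5) ranges$dp_cap else bins$boundaries[bin]
      lo <- max(lo, ranges$dp_range[1]); hi <- min(hi, ranges$dp_range[2])
      if (hi <= lo) stop(sprintf("severity bin %d unreachable under dp_range [%g, %g]",
                                 bin, ranges$dp_range[1], ranges$dp_range[2]))
      target_dp <- stats::runif(1, lo, hi)
      kind <- sample(c("interior_lesion", "hole", "margin_notch"), 1L)
      lesions <- c(lesions, list(place_lesion(kind, blade, blade_area,
                                              target_dp, ranges)))
      if (stats::runif(1) < ranges$extra_lesion_prob) {
        extra_dp <- stats::runif(1, ranges$extra_dp[1], ranges$extra_dp[2])
        ex <- place_lesion(sample(c("interior_lesion", "hole"), 1L), blade,
                           blade_area, extra_dp, ranges,
                           avoid = lesions[[1]])
        if (!is.null(ex)) lesions <- c(lesions, list(ex))
      }
    }
    leaf_spec(canvas_size = canvas_size, background_color = mat,
              blade = blade_args, lesions = lesions, seed = seed)
  })
}

# Place a lesion of the requested kind and target area inside/on the blade,
# retrying positions until it is valid and clear of `avoid`.
place_lesion <- function(kind, blade, blade_area, target_dp, ranges, avoid = NULL) {
  target_area <- target_dp / 100 * blade_area
  ctr0 <- polygon_centroid(blade)
  for (try in 1:60) {
    aspect <- stats::runif(1, 0.6, 1)
    rot <- stats::runif(1, 0, pi)
    if (kind == "margin_notch") {
      # a "bite": ellipse major axis along the inward normal, center pushed
      # half a semi-axis inside so the notch is deeper than its mouth is wide
      v <- blade[sample.int(nrow(blade), 1L), ]
      u <- v - ctr0; u <- u / sqrt(sum(u^2))
      aspect <- stats::runif(1, 0.45, 0.75)
      rot <- atan2(u[2L], u[1L])
      a0 <- sqrt(target_area / (0.8 * pi * aspect))
      ls <- NULL
      for (it in 1:6) {
        ctr <- v - 0.5 * a0 * u
        ls <- lesion_spec(kind, ctr, c(a0, a0 * aspect), rot, 0)
        region <- clip_polygon_convex(lesion_polygon(ls), blade)
        if (is.null(region)) { ls <- NULL; break }
        got <- shoelace_area(region)
        if (abs(got / target_area - 1) < 0.02) break
        a0 <- a0 * sqrt(target_area / got)
      }
      if (is.null(ls)) next
      poly <- lesion_polygon(ls)
      inside <- points_in_polygon(blade, poly)
      if (all(inside) || !any(inside)) next
    } else {
      f <- stats::runif(1, 0.15, 0.6)
      t <- stats::runif(1, 0, 2 * pi)
      # a point a fraction f of the way from the centroid toward the boundary
      bidx <- which.min(abs(atan2(blade[, 2] - ctr0[2], blade[, 1] - ctr0[1]) -
                              (t - pi)))
      edge <- blade[bidx, ]
      ctr <- ctr0 + f * (edge - ctr0)
      halo <- if (kind == "interior_lesion")
        sample(ranges$halo_widths, 1L) else 0
      ls <- lesion_spec(kind, ctr, c(sqrt(target_area / pi / aspect),
                                     sqrt(target_area / pi / aspect) * aspect),
                        rot, halo)
      poly <- lesion_polygon(ls)
      if (!all(points_in_polygon(blade, poly))) next
    }
    if (!is.null(avoid)) {
      pad <- 4 + ls$halo_width + avoid$halo_width
      b1 <- polygon_bbox(lesion_polygon(ls))
      b2 <- polygon_bbox(lesion_polygon(avoid))
      if (!(b1["xmax"] + pad < b2["xmin"] || b2["xmax"] + pad < b1["xmin"] ||
            b1["ymax"] + pad < b2["ymin"] || b2["ymax"] + pad < b1["ymin"])) next
    }
    return(ls)
  }
  if (is.null(avoid))
    stop(sprintf("could not place a %s with target dp %.2f", kind, target_dp))
  NULL
}

#' Generate a synthetic leaf dataset with ground truth
#'
#' Images are written as PNG plus a JSON-lines ground-truth sidecar
#' (one object per image: path, leaf area, regions, total damage). Images
#' cycle through the five severity bins so every class is represented
#' whenever \code{n >= 5}; with \code{healthy_every} > 0 every that-many-th
#' image is an undamaged leaf.
#'
#' @param n number of images (>= 1).
#' @param out_dir output directory (created if missing).
#' @param ranges parameter ranges, see \code{\link{synth_ranges}}; NULL
#'   uses the defaults for \code{canvas_size}.
#' @param seed integer master seed; per-image seeds are derived from it.
#' @param canvas_size c(width, height).
#' @param bins severity bins used for the ground-truth classes.
#' @param healthy_every emit a healthy leaf every k-th image (0 = never).
#' @return invisibly, a list with \code{items} (list of path + truth) and
#'   \code{sidecar} path.
#' @export
generate_dataset <- function(n, out_dir, ranges = NULL, seed = 1L,
                             canvas_size = c(600, 400), bins = severity_bins(),
                             healthy_every = 0L) {
  if (n < 1) stop("n must be >= 1")
  if (is.null(ranges)) ranges <- synth_ranges(canvas_size)
  lo <- c(0, bins$boundaries); hi <- c(bins$boundaries, ranges$dp_cap)
  for (b in 1:5)
    if (min(hi[b], ranges$dp_range[2]) <= max(lo[b], ranges$dp_range[1]))
      stop(sprintf("severity bin %d (%s) unreachable under dp_range [%g, %g]",
                   b, bins$labels[b], ranges$dp_range[1], ranges$dp_range[2]))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sidecar <- file.path(out_dir, "ground_truth.jsonl")
  con <- file(sidecar, open = "wt")
  on.exit(close(con), add = TRUE)
  items <- vector("list", n)
  bin_seq <- rep(1:5, length.out = n)
  for (i in seq_len(n)) {
    bin <- if (healthy_every > 0 && i %% healthy_every == 0) 0L else bin_seq[i]
    sp <- random_leaf_spec(bin, canvas_size, ranges, bins, seed = seed + i)
    gl <- generate_leaf(sp)
    path <- file.path(out_dir, sprintf("leaf_%04d.png", i))
    png::writePNG(gl$image / 255, path)
    rec <- list(path = basename(path),
                width = canvas_size[1], height = canvas_size[2],
                leaf_area = gl$truth$leaf_area,
                total_dp = gl$truth$total_dp,
                regions = gl$truth$regions[, c("kind", "xmin", "ymin", "xmax",
                                               "ymax", "true_area", "true_dp",
                                               "severity")])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    items[[i]] <- list(path = path, truth = gl$truth, spec = sp)
  }
  invisible(list(items = items, sidecar = sidecar))
}

#' Read a ground-truth sidecar written by \code{generate_dataset}
#'
#' @param path the \code{ground_truth.jsonl} file.
#' @return list of per-image truth records.
#' @export
read_ground_truth <- function(path) {
  lapply(readLines(path), function(l) jsonlite::fromJSON(l, simplifyDataFrame = TRUE))
}
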