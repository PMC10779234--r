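#' Severity class names in canonical index order
#'
#' The fixed class order used for YOLO class indices (0-based). "healthy" is
#' a valid extra name but is never emitted as a box: healthy images get an
#' empty label file, the usual detector-training convention.
#'
#' @return character vector.
#' @export
severity_class_names <- function() {
  c("ClassOne", "ClassTwo", "ClassThree", "ClassFour", "ClassFive")
}

fmt6 <- function(x) sprintf("%.6f", x)

#' Write a leaf annotation as PASCAL VOC XML
#'
#' Standard VOC fields (folder, filename, path, size, one object per damage
#' region with the severity label as the object name) plus a
#' \code{<leafgrade>} extras block carrying the quantities VOC has no slot
#' for: leaf area, reference area, total damage, and per-object area / dp /
#' damage kind. Internal boxes are 0-based half-open; on disk they follow
#' the VOC 1-based inclusive convention (\code{xmin+1, ymin+1, xmax, ymax},
#' rounded to integers). Output is deterministic: fixed field order, floats
#' at 6 decimals.
#'
#' @param annotation a \code{leaf_annotation}.
#' @param path file to write; NULL returns the xml2 document.
#' @param class_names allowed object names.
#' @return the xml2 document, invisibly when written to a file.
#' @export
write_voc_xml <- function(annotation, path = NULL,
                          class_names = severity_class_names()) {
  w <- annotation$image_size[1L]; h <- annotation$image_size[2L]
  reg <- annotation$regions
  if (nrow(reg) > 0L &&
      (any(reg$xmin < 0) || any(reg$ymin < 0) ||
       any(reg$xmax > w) || any(reg$ymax > h)))
    stop("region bounding box outside image bounds")
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", dirname(annotation$image_id))
  xml2::xml_add_child(doc, "filename", basename(annotation$image_id))
  xml2::xml_add_child(doc, "path", annotation$image_id)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(as.integer(w)))
  xml2::xml_add_child(size, "height", as.character(as.integer(h)))
  xml2::xml_add_child(size, "depth", "3")
  xml2::xml_add_child(doc, "segmented", "0")
  extras <- xml2::xml_add_child(doc, "leafgrade")
  xml2::xml_add_child(extras, "leaf_area", fmt6(annotation$leaf_area))
  xml2::xml_add_child(extras, "reference_area", fmt6(annotation$reference_area))
  xml2::xml_add_child(extras, "reference", annotation$reference)
  xml2::xml_add_child(extras, "total_dp", fmt6(annotation$total_dp))
  xml2::xml_add_child(extras, "healthy", if (annotation$healthy) "1" else "0")
  for (i in seq_len(nrow(reg))) {
    if (!(reg$severity[i] %in% class_names))
      stop(sprintf("unknown class name '%s'", reg$severity[i]))
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", reg$severity[i])
    xml2::xml_add_child(obj, "pose", "Unspecified")
    xml2::xml_add_child(obj, "truncated", "0")
    xml2::xml_add_child(obj, "difficult", "0")
    bnd <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bnd, "xmin", as.character(as.integer(round(reg$xmin[i])) + 1L))
    xml2::xml_add_child(bnd, "ymin", as.character(as.integer(round(reg$ymin[i])) + 1L))
    xml2::xml_add_child(bnd, "xmax", as.character(as.integer(round(reg$xmax[i]))))
    xml2::xml_add_child(bnd, "ymax", as.character(as.integer(round(reg$ymax[i]))))
    ex <- xml2::xml_add_child(obj, "extras")
    xml2::xml_add_child(ex, "kind", reg$kind[i])
    xml2::xml_add_child(ex, "area", fmt6(reg$area[i]))
    xml2::xml_add_child(ex, "dp", fmt6(reg$dp[i]))
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

xml_num <- function(node, name) {
  child <- xml2::xml_find_first(node, name)
  if (inherits(child, "xml_missing")) stop(sprintf("missing element <%s>", name))
  v <- suppressWarnings(as.numeric(xml2::xml_text(child)))
  if (is.na(v)) stop(sprintf("element <%s> is not numeric", name))
  v
}

#' Read a PASCAL VOC XML annotation
#'
#' Inverse of \code{\link{write_voc_xml}}. Foreign VOC files without the
#' extras block parse too; their per-region area / dp fields are NA and the
#' leaf-level areas 0.
#'
#' @param path XML file or an xml2 document.
#' @return a \code{leaf_annotation} (without polygons).
#' @export
read_voc_xml <- function(path) {
  doc <- if (inherits(path, "xml_document")) path else xml2::read_xml(path)
  size <- xml2::xml_find_first(doc, "size")
  if (inherits(size, "xml_missing")) stop("missing element <size>")
  w <- xml_num(size, "width"); h <- xml_num(size, "height")
  if (w <= 0 || h <= 0) stop("element <size> has non-positive dimensions")
  extras <- xml2::xml_find_first(doc, "leafgrade")
  has_extras <- !inherits(extras, "xml_missing")
  objs <- xml2::xml_find_all(doc, "object")
  n <- length(objs)
  reg <- data.frame(kind = character(n), xmin = numeric(n), ymin = numeric(n),
                    xmax = numeric(n), ymax = numeric(n), area = numeric(n),
                    dp = numeric(n), severity = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    o <- objs[[i]]
    bnd <- xml2::xml_find_first(o, "bndbox")
    if (inherits(bnd, "xml_missing")) stop("missing element <bndbox>")
    reg$severity[i] <- xml2::xml_text(xml2::xml_find_first(o, "name"))
    reg$xmin[i] <- xml_num(bnd, "xmin") - 1  # 1-based inclusive -> 0-based half-open
    reg$ymin[i] <- xml_num(bnd, "ymin") - 1
    reg$xmax[i] <- xml_num(bnd, "xmax")
    reg$ymax[i] <- xml_num(bnd, "ymax")
    ex <- xml2::xml_find_first(o, "extras")
    if (!inherits(ex, "xml_missing")) {
      reg$kind[i] <- xml2::xml_text(xml2::xml_find_first(ex, "kind"))
      reg$area[i] <- xml_num(ex, "area")
      reg$dp[i] <- xml_num(ex, "dp")
    } else {
      reg$kind[i] <- NA_character_; reg$area[i] <- NA_real_; reg$dp[i] <- NA_real_
    }
  }
  structure(list(
    image_id = xml2::xml_text(xml2::xml_find_first(doc, "path")),
    image_size = c(w, h),
    leaf_area = if (has_extras) xml_num(extras, "leaf_area") else 0,
    reference_area = if (has_extras) xml_num(extras, "reference_area") else 0,
    reference = if (has_extras)
      xml2::xml_text(xml2::xml_find_first(extras, "reference")) else "self",
    regions = reg,
    polygons = NULL,
    total_dp = if (has_extras) xml_num(extras, "total_dp") else sum(reg$dp),
    healthy = n == 0L), class = "leaf_annotation")
}

#' Convert an annotation to YOLO records
#'
#' Each damage region becomes one record: 0-based class index (position of
#' the severity label in \code{class_names}) and the box in normalized
#' center form \code{(xc, yc, w, h)}, all fractions of the image size.
#'
#' @param annotation a \code{leaf_annotation}.
#' @param class_names class order defining the indices.
#' @return data.frame(class_index, xc, yc, w, h); zero rows for healthy.
#' @export
to_yolo <- function(annotation, class_names = severity_class_names()) {
  reg <- annotation$regions
  W <- annotation$image_size[1L]; H <- annotation$image_size[2L]
  idx <- match(reg$severity, class_names)
  if (any(is.na(idx)))
    stop(sprintf("unknown label '%s'", reg$severity[which(is.na(idx))[1L]]))
  data.frame(class_index = idx - 1L,
             xc = (reg$xmin + reg$xmax) / 2 / W,
             yc = (reg$ymin + reg$ymax) / 2 / H,
             w = (reg$xmax - reg$xmin) / W,
             h = (reg$ymax - reg$ymin) / H)
}

#' Convert YOLO records back to labelled pixel boxes
#'
#' @param records data.frame with class_index, xc, yc, w, h (fractions).
#' @param image_size c(width, height) in pixels.
#' @param class_names class order defining the indices.
#' @return data.frame(label, xmin, ymin, xmax, ymax) in 0-based half-open
#'   pixel coordinates.
#' @export
from_yolo <- function(records, image_size, class_names = severity_class_names()) {
  if (nrow(records) > 0L) {
    vals <- as.matrix(records[, c("xc", "yc", "w", "h")])
    if (any(vals < 0) || any(vals > 1))
      stop("YOLO coordinates must be fractions in [0, 1]")
    # 6-decimal file quantization can push an edge out by ~1e-6; tolerate
    # that and clamp, reject anything larger
    q <- 2e-6
    x0 <- records$xc - records$w / 2; x1 <- records$xc + records$w / 2
    y0 <- records$yc - records$h / 2; y1 <- records$yc + records$h / 2
    if (any(x0 < -q) || any(y0 < -q) || any(x1 > 1 + q) || any(y1 > 1 + q))
      stop("implied YOLO box lies outside [0, 1]^2")
    if (any(records$class_index < 0) || any(records$class_index >= length(class_names)))
      stop("class index out of range")
  }
  W <- image_size[1L]; H <- image_size[2L]
  data.frame(label = class_names[records$class_index + 1L],
             xmin = pmax(0, (records$xc - records$w / 2)) * W,
             ymin = pmax(0, (records$yc - records$h / 2)) * H,
             xmax = pmin(1, (records$xc + records$w / 2)) * W,
             ymax = pmin(1, (records$yc + records$h / 2)) * H,
             stringsAsFactors = FALSE)
}

#' Write YOLO records to a label file
#'
#' One \code{class xc yc w h [confidence]} line per object, space separated,
#' 6-decimal floats; healthy images produce an empty file.
#'
#' @param records data.frame from \code{\link{to_yolo}}, optionally with a
#'   confidence column.
#' @param path output txt file.
#' @export
write_yolo_txt <- function(records, path) {
  lines <- character(0)
  if (nrow(records) > 0L) {
    lines <- paste(records$class_index, fmt6(records$xc), fmt6(records$yc),
                   fmt6(records$w), fmt6(records$h))
    if (!is.null(records$confidence))
      lines <- paste(lines, fmt6(records$confidence))
  }
  writeLines(lines, path)
}

#' Read a YOLO label or prediction file
#'
#' @param path txt file; 5 columns for labels, 6 (with trailing confidence)
#'   for predictions.
#' @return data.frame(class_index, xc, yc, w, h[, confidence]).
#' @export
read_yolo_txt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(class_index = integer(), xc = numeric(), yc = numeric(),
                      w = numeric(), h = numeric()))
  parts <- strsplit(trimws(lines), "\\s+")
  ncols <- unique(lengths(parts))
  if (length(ncols) != 1L || !(ncols %in% c(5L, 6L)))
    stop(sprintf("malformed YOLO file '%s': expected 5 or 6 columns", path))
  m <- do.call(rbind, lapply(parts, as.numeric))
  out <- data.frame(class_index = as.integer(m[, 1L]), xc = m[, 2L],
                    yc = m[, 3L], w = m[, 4L], h = m[, 5L])
  if (ncols == 6L) out$confidence <- m[, 6L]
  out
}
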