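#' HSV colour range for the classical segmentation backend
#'
#' Describes one class for colour-threshold segmentation: per-channel HSV
#' bounds (hue in degrees, may wrap through 0 when `h[1] > h[2]`), a minimum
#' connected-component size, and optional morphological cleaning.
#'
#' @param h hue bounds in degrees `c(lo, hi)`; `lo > hi` means the band wraps
#'   through 0 (e.g. `c(350, 10)` for reds).
#' @param s,v saturation / value bounds in `c(lo, hi)`, each in \[0, 1\].
#' @param min_component_px connected components smaller than this are dropped
#'   (speckle rejection); must be >= 1.
#' @param morphology `"none"` or `"open_close"` (opening then closing with a
#'   square brush before component labelling).
#' @param kernel_px side of the square morphology brush, default 3.
#' @return An object of class `color_range`.
#' @export
color_range <- function(h = c(0, 360), s = c(0, 1), v = c(0, 1),
                        min_component_px = 1L,
                        morphology = c("none", "open_close"),
                        kernel_px = 3L) {
  morphology <- match.arg(morphology)
  if (length(h) != 2L || length(s) != 2L || length(v) != 2L) {
    pp_abort("h, s, v must each be length-2 lo/hi bounds", "parameter")
  }
  if (s[1] > s[2] || v[1] > v[2]) {
    pp_abort("saturation and value bounds must satisfy lo <= hi", "parameter")
  }
  if (min_component_px < 1L) pp_abort("min_component_px must be >= 1", "parameter")
  structure(
    list(h = as.numeric(h), s = as.numeric(s), v = as.numeric(v),
         min_component_px = as.integer(min_component_px),
         morphology = morphology, kernel_px = as.integer(kernel_px)),
    class = "color_range"
  )
}

# HSV channels of an image as H x W matrices; hue in degrees [0, 360)
image_hsv <- function(image) {
  px <- image$pixels
  d <- dim(px)
  flat <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  hsvm <- rgb2hsv(flat, maxColorValue = 255)
  list(
    h = matrix(hsvm[1, ] * 360, d[1], d[2]),
    s = matrix(hsvm[2, ], d[1], d[2]),
    v = matrix(hsvm[3, ], d[1], d[2])
  )
}

in_color_range <- function(hsv, range) {
  h <- hsv$h
  hue_ok <- if (range$h[1] <= range$h[2]) {
    h >= range$h[1] & h <= range$h[2]
  } else {
    h >= range$h[1] | h <= range$h[2] # band wraps through 0 degrees
  }
  hue_ok &
    hsv$s >= range$s[1] & hsv$s <= range$s[2] &
    hsv$v >= range$v[1] & hsv$v <= range$v[2]
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected, so
# diagonal adjacencies between 4-labels are merged with a union-find pass and
# components renumbered in scan order (deterministic).
label_components <- function(bits) {
  bits <- as_mask(bits)
  lab <- EBImage::bwlabel(matrix(as.numeric(bits), nrow(bits)))
  lab <- matrix(as.integer(lab), nrow(bits))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  dr <- cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1]))   # down-right
  dl <- cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))   # down-left
  pairs <- rbind(dr, dl)
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- as.integer(match(roots, unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

new_detections <- function(label = character(), confidence = numeric(),
                           mask = list(), tile = integer()) {
  tibble(label = label, confidence = confidence, mask = mask,
         tile = as.integer(tile))
}

#' Classical colour-threshold segmentation
#'
#' A deterministic segmentation backend: pixels inside the HSV `range` are
#' selected, optionally cleaned by morphological opening/closing, split into
#' 8-connected components, and components of at least `min_component_px`
#' pixels become one detection each with confidence 1.0 (the classical
#' backend carries no calibrated score). Identical input always yields
#' bit-identical masks.
#'
#' @param image a `raster_image`.
#' @param label class label to assign (`"flower"`, `"reference"`, `"other"`).
#' @param range a [color_range()].
#' @return A detections tibble with columns `label`, `confidence`, `mask`
#'   (list of full-image logical matrices), `tile` (NA here).
#' @export
segment_classical <- function(image, label, range) {
  stopifnot(inherits(image, "raster_image"), inherits(range, "color_range"))
  bits <- in_color_range(image_hsv(image), range)
  if (range$morphology == "open_close" && any(bits)) {
    brush <- EBImage::makeBrush(range$kernel_px, shape = "box")
    b <- matrix(as.numeric(bits), nrow(bits))
    b <- EBImage::closing(EBImage::opening(b, brush), brush)
    bits <- b > 0.5
  }
  if (!any(bits)) return(new_detections())
  lab <- label_components(bits)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= range$min_component_px)
  if (!length(keep)) return(new_detections())
  masks <- lapply(keep, function(k) lab == k)
  new_detections(
    label = rep(label, length(keep)),
    confidence = rep(1.0, length(keep)),
    mask = masks,
    tile = rep(NA_integer_, length(keep))
  )
}

#' Segmentation backends
#'
#' A backend is any function `image -> detections` where detections is a data
#' frame with columns `label` (one of flower/reference/other), `confidence`
#' (in \[0, 1\]) and `mask` (list of logical matrices matching the image
#' dimensions, each with at least one true pixel). [classical_backend()]
#' wraps [segment_classical()] into this contract; [stub_backend()] returns a
#' fixed detection list (useful for tests and for adapting external neural
#' segmenters whose output is precomputed).
#'
#' @param label class label the backend emits.
#' @param range a [color_range()].
#' @param detections fixed detections tibble for the stub.
#' @param id backend identifier attached for provenance.
#' @return A backend function with attribute `backend_id`.
#' @export
classical_backend <- function(label, range, id = paste0("classical/", label)) {
  f <- function(image) segment_classical(image, label, range)
  attr(f, "backend_id") <- id
  f
}

#' @rdname classical_backend
#' @export
stub_backend <- function(detections, id = "stub") {
  f <- function(image) detections
  attr(f, "backend_id") <- id
  f
}

#' Run a segmentation backend with contract checking
#'
#' Calls the backend and normalises its output to a detections tibble,
#' validating the contract: required columns, labels from the class enum,
#' confidences in \[0, 1\], masks that are logical matrices with the image's
#' dimensions and at least one true pixel. A backend that raises, or returns
#' malformed output, is reported as a backend failure carrying the backend id.
#'
#' @param image a `raster_image`.
#' @param backend a backend function (see [classical_backend()]).
#' @return A detections tibble; attribute `backend_id` records provenance.
#' @export
segment_with_backend <- function(image, backend) {
  stopifnot(inherits(image, "raster_image"), is.function(backend))
  id <- attr(backend, "backend_id") %||% "anonymous"
  res <- tryCatch(
    backend(image),
    error = function(e) {
      pp_abort(sprintf("backend '%s' failed: %s", id, conditionMessage(e)),
               "backend_failure", backend_id = id)
    }
  )
  fail <- function(msg) {
    pp_abort(sprintf("backend '%s' violated the contract: %s", id, msg),
             "backend_failure", backend_id = id)
  }
  if (!is.data.frame(res) || !all(c("label", "confidence", "mask") %in% names(res))) {
    fail("result must have columns label, confidence, mask")
  }
  det <- as_tibble(res)
  if (!"tile" %in% names(det)) det$tile <- NA_integer_
  det <- det[c("label", "confidence", "mask", "tile")]
  if (nrow(det) == 0L) return(new_detections())
  if (!all(det$label %in% c("flower", "reference", "other"))) {
    fail("labels must be flower, reference or other")
  }
  if (anyNA(det$confidence) || any(det$confidence < 0 | det$confidence > 1)) {
    fail("confidences must lie in [0, 1]")
  }
  shape <- image_shape(image)
  ok <- vapply(det$mask, function(m) {
    is.matrix(m) && identical(as.integer(dim(m)), as.integer(shape)) &&
      sum(m) > 0
  }, logical(1))
  if (!all(ok)) fail("masks must match the image dimensions and be non-empty")
  det$mask <- lapply(det$mask, as_mask)
  attr(det, "backend_id") <- id
  det
}

#' Filter detections by confidence
#'
#' Keeps detections whose confidence is at or above the threshold
#' (>= semantics), preserving order. The default cutoff is 0.5.
#'
#' @param detections a detections tibble.
#' @param threshold confidence cutoff in \[0, 1\].
#' @return The filtered detections tibble.
#' @export
filter_by_confidence <- function(detections, threshold = 0.5) {
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0 || threshold > 1) {
    pp_abort("confidence threshold must be a single value in [0, 1]", "parameter")
  }
  detections[detections$confidence >= threshold, , drop = FALSE]
}

#' Count pixels of one class
#'
#' Pixel count of the union of all masks carrying `label`: overlapping
#' instance masks of the same class contribute each pixel once. An absent
#' label counts 0 (a `shape` is then required to size the empty union).
#'
#' @param detections a detections tibble.
#' @param label class label to count.
#' @param shape integer `c(height, width)`; needed when no detection carries
#'   the label.
#' @return Integer pixel count.
#' @export
class_pixel_count <- function(detections, label, shape = NULL) {
  masks <- detections$mask[detections$label == label]
  if (length(masks) == 0L) {
    if (is.null(shape)) return(0L)
    return(mask_pixel_count(union_masks(list(), shape)))
  }
  mask_pixel_count(union_masks(masks))
}

#' Union mask of one class
#'
#' @inheritParams class_pixel_count
#' @return A logical matrix (all-false when the label is absent).
#' @export
class_mask <- function(detections, label, shape) {
  masks <- detections$mask[detections$label == label]
  union_masks(masks, shape = shape)
}
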