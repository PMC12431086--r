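#' Reference-object specification
#'
#' The in-scene reference object provides the pixel-to-area scale. The
#' default follows the published deployment convention: a 7.6 cm square of
#' brown cardboard whose nominal area is taken as 58 cm^2 (the published
#' constant, kept although 7.6^2 = 57.76; configurable).
#'
#' @param area_cm2 known reference area in cm^2 (> 0), default 58.
#' @param side_cm documented side length in cm for a square reference,
#'   default 7.6; informational.
#' @param description free-text description.
#' @return An object of class `reference_spec`.
#' @export
reference_spec <- function(area_cm2 = 58, side_cm = 7.6,
                           description = "brown cardboard square") {
  if (!is.numeric(area_cm2) || length(area_cm2) != 1L || is.na(area_cm2) ||
      area_cm2 <= 0) {
    pp_abort("reference area must be a single positive number", "parameter")
  }
  structure(
    list(area_cm2 = as.numeric(area_cm2), side_cm = side_cm,
         description = description),
    class = "reference_spec"
  )
}

#' Flower / reference pixel counts
#'
#' @param f_pixels segmented flower pixel count (>= 0).
#' @param r_pixels segmented reference-object pixel count (>= 0).
#' @return An object of class `pixel_counts`.
#' @export
pixel_counts <- function(f_pixels, r_pixels) {
  if (any(c(f_pixels, r_pixels) < 0) || anyNA(c(f_pixels, r_pixels))) {
    pp_abort("pixel counts must be non-negative", "parameter")
  }
  structure(list(f_pixels = as.numeric(f_pixels), r_pixels = as.numeric(r_pixels)),
            class = "pixel_counts")
}

#' Estimate floral area from pixel counts
#'
#' The 2-D photogrammetry step: floral area equals the flower-to-reference
#' pixel ratio times the known reference area,
#' `area = f_pixels / r_pixels * area_cm2`. The estimate is scale invariant
#' (multiplying both counts by the same factor leaves it unchanged). A zero
#' reference count means the image carries no scale and is an error.
#'
#' @param counts a [pixel_counts()] object (or a list with `f_pixels`,
#'   `r_pixels`).
#' @param reference a [reference_spec()].
#' @param warnings character vector of warnings to carry along.
#' @return An object of class `area_estimate` with fields `floral_area_cm2`,
#'   `counts`, `reference`, `warnings`.
#' @examples
#' estimate_area(pixel_counts(11600, 5800))  # 116 cm^2
#' @export
estimate_area <- function(counts, reference = reference_spec(),
                          warnings = character()) {
  if (!inherits(counts, "pixel_counts")) {
    counts <- pixel_counts(counts$f_pixels, counts$r_pixels)
  }
  stopifnot(inherits(reference, "reference_spec"))
  if (counts$r_pixels == 0) {
    pp_abort("reference object not detected: no reference pixels to set the scale",
             "reference_not_detected")
  }
  structure(
    list(
      floral_area_cm2 = counts$f_pixels / counts$r_pixels * reference$area_cm2,
      counts = counts,
      reference = reference,
      warnings = warnings
    ),
    class = "area_estimate"
  )
}

#' @export
print.area_estimate <- function(x, ...) {
  cat(sprintf("Floral area: %.2f cm^2 (F = %s px, R = %s px, R_area = %g cm^2)\n",
              x$floral_area_cm2, format(x$counts$f_pixels, big.mark = ","),
              format(x$counts$r_pixels, big.mark = ","), x$reference$area_cm2))
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' @export
tidy.area_estimate <- function(x, ...) {
  tibble(
    floral_area_cm2 = x$floral_area_cm2,
    f_pixels = x$counts$f_pixels,
    r_pixels = x$counts$r_pixels,
    r_area_cm2 = x$reference$area_cm2,
    n_warnings = length(x$warnings)
  )
}

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end estimator with the published
#' defaults: a 2 x 2 tile grid, a 0.5 confidence threshold and a 58 cm^2
#' reference. Backends default to the classical colour-threshold segmenters
#' with the package's default palette.
#'
#' @param tiles integer `c(rows, cols)`, default `c(2, 2)`.
#' @param confidence_threshold detection cutoff in \[0, 1\], default 0.5.
#' @param reference a [reference_spec()].
#' @param flower_backend,reference_backend backend functions (see
#'   [classical_backend()]); `NULL` builds classical backends from
#'   `color_config`.
#' @param color_config list with `flower` and `reference` [color_range()]s,
#'   default [default_color_config()].
#' @param keep_detections keep the merged detection tibble on the result.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(tiles = c(2L, 2L), confidence_threshold = 0.5,
                            reference = reference_spec(),
                            flower_backend = NULL, reference_backend = NULL,
                            color_config = default_color_config(),
                            keep_detections = FALSE) {
  if (is.null(flower_backend)) {
    flower_backend <- classical_backend("flower", color_config$flower)
  }
  if (is.null(reference_backend)) {
    reference_backend <- classical_backend("reference", color_config$reference)
  }
  structure(
    list(tiles = as.integer(tiles), confidence_threshold = confidence_threshold,
         reference = reference, flower_backend = flower_backend,
         reference_backend = reference_backend,
         keep_detections = isTRUE(keep_detections)),
    class = "pipeline_config"
  )
}

#' Run the floral-area pipeline on one image
#'
#' Executes the full workflow: split the image into tiles (2 x 2 by
#' default), segment every tile with the flower and the reference backends,
#' lift each tile mask into full-image coordinates, pool the detections,
#' filter at the confidence threshold (0.5 by default), count flower and
#' reference pixels as class-wise mask unions across all tiles, and apply the
#' pixel-ratio formula. Intermediate per-tile counts are recorded in an audit
#' table; more than one reference component raises a recorded warning (the
#' scene is expected to contain exactly one reference object).
#'
#' @param image a `raster_image`.
#' @param config a [pipeline_config()].
#' @return An `area_estimate` with extra fields: `f_pixels`, `r_pixels`,
#'   `tiles`, `confidence_threshold`, `backend_ids`, `audit` (per-tile,
#'   per-class detection and pixel counts), `flower_mask`, `reference_mask`,
#'   and `detections` when `keep_detections` is set.
#' @export
run_pipeline <- function(image, config = pipeline_config()) {
  stopifnot(inherits(image, "raster_image"), inherits(config, "pipeline_config"))
  shape <- image_shape(image)
  layout <- make_tiles(image, config$tiles[1], config$tiles[2])

  all_det <- vector("list", nrow(layout))
  audit <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    rect <- layout[i, ]
    tile_img <- crop_image(image, rect)
    det_f <- segment_with_backend(tile_img, config$flower_backend)
    det_r <- segment_with_backend(tile_img, config$reference_backend)
    det <- bind_rows(det_f, det_r)
    if (nrow(det)) {
      det$mask <- lapply(det$mask, lift_mask, rect = rect, full_shape = shape)
      det$tile <- i
    }
    all_det[[i]] <- det
    audit[[i]] <- tibble(
      tile = i,
      n_flower = nrow(det_f), n_reference = nrow(det_r),
      flower_px = class_pixel_count(det, "flower", shape),
      reference_px = class_pixel_count(det, "reference", shape)
    )
  }
  detections <- bind_rows(all_det)
  if (nrow(detections) == 0L) detections <- new_detections()
  kept <- filter_by_confidence(detections, config$confidence_threshold)

  flower_mask <- class_mask(kept, "flower", shape)
  reference_mask <- class_mask(kept, "reference", shape)

  # tiling may cut the one reference object into per-tile detections, so the
  # "more than one reference" warning looks at components of the merged mask
  warnings <- character()
  if (any(reference_mask)) {
    n_ref <- max(label_components(reference_mask))
    if (n_ref > 1L) {
      warnings <- c(warnings, sprintf(
        "%d reference components found; counting their union (one reference object expected)",
        n_ref))
    }
  }
  counts <- pixel_counts(sum(flower_mask), sum(reference_mask))
  est <- estimate_area(counts, config$reference, warnings = warnings)

  est$f_pixels <- counts$f_pixels
  est$r_pixels <- counts$r_pixels
  est$tiles <- config$tiles
  est$confidence_threshold <- config$confidence_threshold
  est$backend_ids <- c(
    flower = attr(config$flower_backend, "backend_id") %||% "anonymous",
    reference = attr(config$reference_backend, "backend_id") %||% "anonymous"
  )
  est$audit <- bind_rows(audit)
  est$flower_mask <- flower_mask
  est$reference_mask <- reference_mask
  if (config$keep_detections) est$detections <- kept
  est
}
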