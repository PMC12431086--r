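eval_table_columns <- c("image_id", "predicted_cm2", "measured_cm2",
                        "color_category", "petal_category", "distance_cm")

#' Validate an evaluation table
#'
#' An evaluation table pairs per-image predicted and measured floral areas
#' with robustness-category labels. Required columns: `image_id`,
#' `predicted_cm2`, `measured_cm2`, `color_category`, `petal_category`,
#' `distance_cm`.
#'
#' @param table a data frame.
#' @return The table, invisibly, or an error naming missing columns /
#'   offending rows.
#' @export
validate_eval_table <- function(table) {
  missing_cols <- setdiff(eval_table_columns, names(table))
  if (length(missing_cols)) {
    pp_abort(paste0("evaluation table is missing columns: ",
                    paste(missing_cols, collapse = ", ")), "schema")
  }
  bad <- which(!is.finite(table$predicted_cm2) | !is.finite(table$measured_cm2))
  if (length(bad)) {
    pp_abort(paste0("non-numeric predicted/measured values in rows: ",
                    paste(bad, collapse = ", ")), "schema")
  }
  if (any(table$measured_cm2 < 0)) {
    pp_abort("measured_cm2 must be non-negative", "schema")
  }
  invisible(table)
}

#' Read / write evaluation tables
#'
#' CSV with header `image_id,predicted_cm2,measured_cm2,color_category,`
#' `petal_category,distance_cm`.
#'
#' @param path CSV file path.
#' @param table an evaluation table.
#' @return `read_eval_table` returns a validated tibble; `write_eval_table`
#'   returns `path` invisibly.
#' @export
read_eval_table <- function(path) {
  if (!file.exists(path)) pp_abort(paste0("table not found: ", path), "io")
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  validate_eval_table(tbl)
  tbl
}

#' @rdname read_eval_table
#' @export
write_eval_table <- function(table, path) {
  validate_eval_table(table)
  readr::write_csv(table, path)
  invisible(path)
}

#' Serialize an area estimate as JSON
#'
#' Writes `{floral_area_cm2, f_pixels, r_pixels, r_area_cm2, tiles,
#' confidence_threshold, backend_ids, warnings}`.
#'
#' @param estimate an `area_estimate` from [run_pipeline()] or
#'   [estimate_area()].
#' @param path destination; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_estimate_json <- function(estimate, path = NULL) {
  stopifnot(inherits(estimate, "area_estimate"))
  payload <- list(
    floral_area_cm2 = estimate$floral_area_cm2,
    f_pixels = estimate$counts$f_pixels,
    r_pixels = estimate$counts$r_pixels,
    r_area_cm2 = estimate$reference$area_cm2,
    tiles = estimate$tiles %||% NA,
    confidence_threshold = estimate$confidence_threshold %||% NA,
    backend_ids = as.list(estimate$backend_ids %||% list()),
    warnings = estimate$warnings
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Save a segmentation overlay image
#'
#' Visualization of pipeline step 7: the flower mask is tinted magenta and
#' the reference mask cyan over the source image, then written as PNG. Purely
#' cosmetic; has no effect on any number the pipeline reports.
#'
#' @param image the source `raster_image`.
#' @param flower_mask,reference_mask full-image logical matrices.
#' @param path destination PNG path.
#' @param alpha tint opacity in \[0, 1\], default 0.5.
#' @return `path`, invisibly.
#' @export
save_overlay <- function(image, flower_mask, reference_mask, path, alpha = 0.5) {
  stopifnot(inherits(image, "raster_image"))
  px <- image$pixels / 255
  tint <- function(px, mask, rgb) {
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[mask] <- (1 - alpha) * plane[mask] + alpha * rgb[ch]
      px[, , ch] <- plane
    }
    px
  }
  px <- tint(px, as_mask(flower_mask), c(1, 0, 1))
  px <- tint(px, as_mask(reference_mask), c(0, 1, 1))
  png::writePNG(px, path)
  invisible(path)
}

#' Write a rendered scene to disk
#'
#' Persists one synthetic scene the way field data would arrive: the scene
#' PNG, one single-channel mask PNG per ground-truth instance, and a JSON
#' sidecar with exact pixel counts, areas and category labels.
#'
#' @param scene result of [generate_scene()].
#' @param dir output directory (created if needed).
#' @param id image id used as the file stem.
#' @param labels optional named list of category labels stored in the sidecar.
#' @return Invisibly, a list with `image`, `sidecar` and `masks` paths.
#' @export
write_scene <- function(scene, dir, id, labels = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0(id, ".png"))
  save_image(scene$image, img_path)
  inst <- scene$truth$instances
  mask_paths <- character(nrow(inst))
  for (k in seq_len(nrow(inst))) {
    mask_paths[k] <- file.path(dir, sprintf("%s_mask_%02d_%s.png",
                                            id, k, inst$label[k]))
    save_mask(inst$mask[[k]], mask_paths[k])
  }
  sidecar <- file.path(dir, paste0(id, "_truth.json"))
  payload <- c(
    list(
      image = basename(img_path),
      masks = basename(mask_paths),
      mask_labels = inst$label,
      f_pixels_true = scene$truth$f_pixels_true,
      r_pixels_true = scene$truth$r_pixels_true,
      floral_area_cm2_true = scene$truth$floral_area_cm2_true,
      reference_area_cm2_rendered = scene$truth$reference_area_cm2_rendered,
      px_per_cm = scene$truth$px_per_cm
    ),
    labels
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), sidecar)
  invisible(list(image = img_path, sidecar = sidecar, masks = mask_paths))
}
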