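#' Raster images
#'
#' A raster image is an H x W x 3 integer array of 8-bit RGB values (0-255)
#' with an optional metadata list (capture distance, category labels, source
#' path). Pixels are stored row-major in image orientation: `pixels[i, j, ]`
#' is the pixel in row `i` (from the top) and column `j` (from the left).
#'
#' @param pixels numeric array with dimensions height x width x 3, values in
#'   \[0, 255\].
#' @param metadata optional named list (e.g. `capture_distance_cm`,
#'   `color_category`, `petal_category`, `source_path`).
#' @return An object of class `raster_image`.
#' @examples
#' img <- raster_image(array(128, dim = c(4, 6, 3)))
#' image_shape(img)
#' @export
raster_image <- function(pixels, metadata = list()) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    pp_abort("`pixels` must be an H x W x 3 array", "image")
  }
  d <- dim(pixels)
  if (d[1] < 2L || d[2] < 2L) {
    pp_abort("image must be at least 2 x 2 pixels", "image")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    pp_abort("channel values must lie in [0, 255]", "image")
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, metadata = metadata),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image %d x %d px>\n", d[1], d[2]))
  if (length(x$metadata)) {
    cat("metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Image dimensions
#'
#' @param image a `raster_image`.
#' @return Integer vector `c(height, width)` in pixels.
#' @export
image_shape <- function(image) {
  stopifnot(inherits(image, "raster_image"))
  dim(image$pixels)[1:2]
}

#' Read an image from disk
#'
#' Reads PNG, JPEG or TIFF into a `raster_image`. Greyscale images are
#' expanded to three identical channels; an alpha channel, if present, is
#' dropped. Note that PNG and TIFF carry no EXIF orientation tag, so stored
#' dimensions are the as-rendered dimensions.
#'
#' @param path file path.
#' @param metadata optional metadata list; `source_path` is filled in.
#' @return A `raster_image`.
#' @export
load_image <- function(path, metadata = list()) {
  if (!file.exists(path)) {
    pp_abort(paste0("image file not found: ", path), "io")
  }
  img <- tryCatch(
    EBImage::readImage(path),
    error = function(e) pp_abort(paste0("unreadable image: ", path), "io")
  )
  dat <- EBImage::imageData(img) # x (width) first, then y (height)
  if (length(dim(dat)) == 2L) {
    dat <- array(rep(dat, 3L), dim = c(dim(dat), 3L))
  } else if (dim(dat)[3] > 3L) {
    dat <- dat[, , 1:3, drop = FALSE]
  }
  px <- aperm(dat, c(2L, 1L, 3L)) * 255
  metadata$source_path <- path
  raster_image(round(px), metadata = metadata)
}

#' Write an image to disk
#'
#' Output format follows the file extension (png, jpg/jpeg, tif/tiff).
#'
#' @param image a `raster_image`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  stopifnot(inherits(image, "raster_image"))
  dat <- aperm(image$pixels / 255, c(2L, 1L, 3L))
  EBImage::writeImage(EBImage::Image(dat, colormode = "Color"), path)
  invisible(path)
}

#' Crop a raster image to a tile rectangle
#'
#' @param image a `raster_image`.
#' @param rect one-row tile rectangle (see [make_tiles()]): half-open,
#'   0-based `r0, r1, c0, c1`.
#' @return The cropped `raster_image` (metadata preserved).
#' @export
crop_image <- function(image, rect) {
  stopifnot(inherits(image, "raster_image"))
  rect <- as.list(rect[c("r0", "r1", "c0", "c1")])
  px <- image$pixels[(rect$r0 + 1L):rect$r1, (rect$c0 + 1L):rect$c1, , drop = FALSE]
  raster_image(px, metadata = image$metadata)
}
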