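#' Binary mask arithmetic
#'
#' Masks are plain logical matrices with the same height x width as the image
#' they annotate. These helpers implement the pixel-count semantics used
#' throughout the pipeline: pixels of one class are counted as the union of
#' that class's instance masks, never the sum, so overlapping instances are
#' not double counted.
#'
#' @param mask,a,b logical matrices.
#' @name mask-ops
NULL

as_mask <- function(x) {
  if (!is.matrix(x)) pp_abort("mask must be a matrix", "mask")
  if (!is.logical(x)) {
    storage.mode(x) <- "logical"
  }
  if (anyNA(x)) pp_abort("mask must not contain NA", "mask")
  x
}

#' @describeIn mask-ops number of true pixels in a mask.
#' @export
mask_pixel_count <- function(mask) {
  sum(as_mask(mask))
}

#' Union of binary masks
#'
#' Bitwise OR of a list of same-shaped masks. The empty list is valid when a
#' target `shape` is given and yields the all-false mask.
#'
#' @param masks list of logical matrices sharing dimensions.
#' @param shape integer `c(height, width)`; required when `masks` is empty.
#' @return A logical matrix.
#' @examples
#' a <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
#' b <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2)
#' mask_pixel_count(union_masks(list(a, b)))
#' @export
union_masks <- function(masks, shape = NULL) {
  if (length(masks) == 0L) {
    if (is.null(shape)) {
      pp_abort("empty mask list needs an explicit `shape`", "mask")
    }
    return(matrix(FALSE, shape[1], shape[2]))
  }
  masks <- lapply(masks, as_mask)
  d <- dim(masks[[1]])
  same <- vapply(masks, function(m) identical(dim(m), d), logical(1))
  if (!all(same)) pp_abort("masks have mixed dimensions", "mask")
  if (!is.null(shape) && !identical(as.integer(d), as.integer(shape))) {
    pp_abort("masks do not match the requested shape", "mask")
  }
  Reduce(`|`, masks)
}

#' Intersection pixel count of two masks
#'
#' @rdname mask-ops
#' @export
mask_intersection_count <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  if (!identical(dim(a), dim(b))) pp_abort("masks have mixed dimensions", "mask")
  sum(a & b)
}

#' Read a mask image
#'
#' Masks are persisted as single-channel PNG with 0 = background and
#' 255 = object. Any pixel at or above half intensity is foreground.
#'
#' @param path PNG file path.
#' @return A logical matrix.
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) pp_abort(paste0("mask file not found: ", path), "io")
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m >= 0.5
}

#' Write a mask image
#'
#' @param mask logical matrix.
#' @param path destination PNG path.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  png::writePNG(as_mask(mask) * 1, path)
  invisible(path)
}
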