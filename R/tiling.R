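#' Split an image into a grid of tiles
#'
#' Tiled (sliced) inference: the image is divided into a `rows` x `cols` grid
#' of non-overlapping rectangles whose union covers the image exactly, each
#' tile is segmented independently, and tile masks are lifted back into
#' full-image coordinates before pixels are counted. The default grid is
#' 2 x 2 (four tiles).
#'
#' Rectangles are half-open and 0-based: a tile `r0, r1, c0, c1` covers image
#' rows `r0 .. r1 - 1` and columns `c0 .. c1 - 1`. When a dimension is not
#' divisible by the grid, the first `remainder` tiles along that dimension get
#' one extra pixel (ceil-first rule), which makes the layout deterministic.
#'
#' @param image a `raster_image`, or an integer `c(height, width)`.
#' @param rows,cols grid dimensions; both default to 2.
#' @return A tibble of class `tile_layout` with columns `tile` (row-major
#'   index), `r0`, `r1`, `c0`, `c1` and attributes `rows`, `cols`, `shape`.
#' @examples
#' make_tiles(c(640, 640))       # four 320 x 320 tiles
#' make_tiles(c(641, 640))       # first tile row is 321 px tall
#' @export
make_tiles <- function(image, rows = 2L, cols = 2L) {
  shape <- if (inherits(image, "raster_image")) image_shape(image) else as.integer(image)
  if (length(shape) < 2L || anyNA(shape)) pp_abort("invalid image shape", "tiling")
  h <- shape[1]; w <- shape[2]
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) pp_abort("grid must be at least 1 x 1", "tiling")
  if (rows > h || cols > w) {
    pp_abort(sprintf("cannot split a %d x %d image into a %d x %d grid", h, w, rows, cols),
             "tiling")
  }
  splits <- function(n, k) {
    sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
    cumsum(c(0L, sizes))
  }
  rb <- splits(h, rows)
  cb <- splits(w, cols)
  grid <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  layout <- tibble(
    tile = seq_len(rows * cols),
    r0 = rb[grid$row], r1 = rb[grid$row + 1L],
    c0 = cb[grid$col], c1 = cb[grid$col + 1L]
  )
  structure(layout,
            class = c("tile_layout", class(layout)),
            rows = rows, cols = cols, shape = c(h, w))
}

#' Lift a tile mask into full-image coordinates
#'
#' Translates a mask computed on a tile into a full-image mask: true bits are
#' shifted by the tile's offset and everything outside the tile is false.
#' Pixel counts are preserved exactly.
#'
#' @param tile_mask logical matrix with the tile's dimensions.
#' @param rect one-row tile rectangle from [make_tiles()].
#' @param full_shape integer `c(height, width)` of the full image.
#' @return A logical `full_shape` matrix.
#' @export
lift_mask <- function(tile_mask, rect, full_shape) {
  tile_mask <- as_mask(tile_mask)
  rect <- as.list(rect[c("r0", "r1", "c0", "c1")])
  th <- rect$r1 - rect$r0
  tw <- rect$c1 - rect$c0
  if (!identical(dim(tile_mask), as.integer(c(th, tw)))) {
    pp_abort("tile mask does not match the tile rectangle", "lift")
  }
  if (rect$r0 < 0 || rect$c0 < 0 || rect$r1 > full_shape[1] || rect$c1 > full_shape[2]) {
    pp_abort("tile rectangle lies outside the image", "lift")
  }
  out <- matrix(FALSE, full_shape[1], full_shape[2])
  out[(rect$r0 + 1L):rect$r1, (rect$c0 + 1L):rect$c1] <- tile_mask
  out
}

#' Crop a mask to a tile rectangle
#'
#' Inverse of [lift_mask()] restricted to the tile: extracts the sub-mask
#' covered by `rect`.
#'
#' @inheritParams lift_mask
#' @param mask full-image logical matrix.
#' @return A logical matrix with the tile's dimensions.
#' @export
crop_mask <- function(mask, rect) {
  mask <- as_mask(mask)
  rect <- as.list(rect[c("r0", "r1", "c0", "c1")])
  mask[(rect$r0 + 1L):rect$r1, (rect$c0 + 1L):rect$c1, drop = FALSE]
}
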