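# Colour conventions shared by the synthetic renderer and the default
# classical-backend configuration. Hue is in degrees [0, 360); saturation and
# value in [0, 1]. Flowers are bright (v >= ~0.7) and saturated; the cardboard
# reference is a dark desaturated brown; the background is near-achromatic, so
# the three groups are separable by HSV thresholds alone.

# flower colour categories:
#   T1 red/orange/yellow mixed on one plant, T2 pinkish-purple, T3 pink,
#   T4 red, T5 purple
category_hsv <- function(category) {
  switch(category,
    T1 = list(h = c(0, 35, 55), s = 0.85, v = 0.92),
    T2 = list(h = 315,          s = 0.55, v = 0.88),
    T3 = list(h = 330,          s = 0.45, v = 0.95),
    T4 = list(h = 0,            s = 0.85, v = 0.85),
    T5 = list(h = 275,          s = 0.65, v = 0.78),
    pp_abort(paste0("unknown color category: ", category), "parameter")
  )
}

color_categories <- function() c("T1", "T2", "T3", "T4", "T5")
petal_categories <- function() c("C1", "C2", "C3")

reference_brown_hsv <- function() list(h = 25, s = 0.62, v = 0.45)
background_gray_rgb <- function() c(208L, 208L, 208L)

hsv_to_rgb255 <- function(h, s, v) {
  as.integer(col2rgb(hsv(h / 360, s, v)))
}

#' Default colour configuration for the classical backend
#'
#' Returns HSV colour ranges matched to the synthetic renderer's palette:
#' a broad bright-flower band covering all five colour categories (red through
#' yellow and pink through purple, i.e. hue wrapping 250 deg -> 70 deg) and a
#' dark-brown band for the cardboard reference square. Per-category flower
#' ranges are included for narrower segmentation when the category is known.
#'
#' @return A named list with elements `flower`, `reference` (both
#'   [color_range()] objects) and `flower_by_category` (named list of
#'   [color_range()] per colour category).
#' @export
default_color_config <- function() {
  per_cat <- list(
    T1 = color_range(h = c(340, 70), s = c(0.30, 1), v = c(0.62, 1),
                     min_component_px = 1L),
    T2 = color_range(h = c(300, 328), s = c(0.30, 1), v = c(0.62, 1),
                     min_component_px = 1L),
    T3 = color_range(h = c(318, 345), s = c(0.30, 1), v = c(0.62, 1),
                     min_component_px = 1L),
    T4 = color_range(h = c(350, 12), s = c(0.30, 1), v = c(0.62, 1),
                     min_component_px = 1L),
    T5 = color_range(h = c(260, 292), s = c(0.30, 1), v = c(0.62, 1),
                     min_component_px = 1L)
  )
  list(
    flower = color_range(h = c(250, 70), s = c(0.30, 1), v = c(0.62, 1),
                         min_component_px = 1L),
    reference = color_range(h = c(12, 38), s = c(0.35, 0.85), v = c(0.20, 0.60),
                            min_component_px = 1L),
    flower_by_category = per_cat
  )
}

#' Read a colour configuration from YAML
#'
#' The YAML file holds one block per class with fields `h`, `s`, `v`
#' (two-element lo/hi), `min_component_px`, `morphology`, `kernel_px`, e.g.
#'
#' ```yaml
#' flower:    {h: [250, 70], s: [0.3, 1], v: [0.62, 1], min_component_px: 10}
#' reference: {h: [12, 38],  s: [0.35, 0.85], v: [0.2, 0.6], min_component_px: 50}
#' ```
#'
#' @param path YAML file path.
#' @return A list of [color_range()] objects keyed by class name.
#' @export
read_color_config <- function(path) {
  if (!file.exists(path)) pp_abort(paste0("config file not found: ", path), "io")
  raw <- yaml::read_yaml(path)
  lapply(raw, function(b) {
    color_range(
      h = as.numeric(b$h %||% c(0, 360)),
      s = as.numeric(b$s %||% c(0, 1)),
      v = as.numeric(b$v %||% c(0, 1)),
      min_component_px = as.integer(b$min_component_px %||% 1L),
      morphology = b$morphology %||% "none",
      kernel_px = as.integer(b$kernel_px %||% 3L)
    )
  })
}
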