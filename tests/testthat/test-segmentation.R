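brown <- function() {
  b <- petalpix:::reference_brown_hsv()
  as.integer(grDevices::col2rgb(grDevices::hsv(b$h / 360, b$s, b$v)))
}

test_that("classical backend recovers a rendered reference square exactly", {
  cfg <- default_color_config()
  img <- rect_image(c(60, 80), 11, 40, 21, 50, brown())
  res <- segment_classical(img, "reference", cfg$reference)
  expect_equal(nrow(res), 1L)
  expect_equal(res$label, "reference")
  expect_equal(res$confidence, 1.0)
  expect_identical(res$mask[[1]], rect_mask(c(60, 80), 11, 40, 21, 50))
})

test_that("classical backend finds nothing outside its colour range", {
  cfg <- default_color_config()
  img <- flat_image(c(30, 30), c(0, 0, 0))
  expect_equal(nrow(segment_classical(img, "flower", cfg$flower)), 0L)
})

test_that("disjoint same-colour regions become separate detections", {
  cfg <- default_color_config()
  red <- c(217L, 33L, 33L)
  img <- rect_image(c(40, 40), 2, 10, 2, 10, red)
  px <- img$pixels
  for (ch in 1:3) px[25:35, 25:35, ch] <- red[ch]
  img <- raster_image(px)
  res <- segment_classical(img, "flower", cfg$flower)
  expect_equal(nrow(res), 2L)
  expect_equal(sum(purrr::map_int(res$mask, sum)), 81 + 121)

  # min_component_px filters the smaller component
  rng <- cfg$flower
  rng$min_component_px <- 100L
  res2 <- segment_classical(img, "flower", rng)
  expect_equal(nrow(res2), 1L)
  expect_equal(sum(res2$mask[[1]]), 121)
})

test_that("component labelling is 8-connected", {
  m <- matrix(FALSE, 6, 6)
  m[cbind(1:5, 1:5)] <- TRUE # a pure diagonal: one component under 8-connectivity
  lab <- petalpix:::label_components(m)
  expect_equal(max(lab), 1L)
})

test_that("segmentation is deterministic and tiling-invariant in threshold-only mode", {
  cfg <- default_color_config()
  set.seed(31)
  for (i in 1:5) {
    sp <- random_scene_spec(sample.int(1e6, 1), "T5", "C3", canvas_cm = c(24, 32),
                            px_per_cm = 6)
    sc <- generate_scene(sp)
    a <- segment_classical(sc$image, "flower", cfg$flower)
    b <- segment_classical(sc$image, "flower", cfg$flower)
    expect_identical(a$mask, b$mask)

    shape <- image_shape(sc$image)
    whole <- class_mask(a, "flower", shape)
    tl <- make_tiles(shape)
    parts <- lapply(seq_len(nrow(tl)), function(k) {
      det <- segment_classical(crop_image(sc$image, tl[k, ]), "flower", cfg$flower)
      lifted <- lapply(det$mask, lift_mask, rect = tl[k, ], full_shape = shape)
      union_masks(lifted, shape = shape)
    })
    expect_identical(union_masks(parts, shape = shape), whole)
  }
})

test_that("morphology cleans speckle noise inside the kernel scale", {
  cfg <- default_color_config()
  red <- c(217L, 33L, 33L)
  img <- rect_image(c(40, 40), 5, 25, 5, 25, red)
  px <- img$pixels
  for (ch in 1:3) px[35, 35, ch] <- red[ch] # 1-px speck
  img <- raster_image(px)
  rng <- cfg$flower
  rng$morphology <- "open_close"
  res <- segment_classical(img, "flower", rng)
  expect_equal(nrow(res), 1L) # speck opened away, block kept
  expect_gt(sum(res$mask[[1]]), 400)
})

test_that("backend contract is enforced and violations carry the backend id", {
  cfg <- default_color_config()
  img <- rect_image(c(30, 40), 5, 20, 5, 20, brown())

  routed <- segment_with_backend(img, classical_backend("reference", cfg$reference))
  direct <- segment_classical(img, "reference", cfg$reference)
  expect_identical(routed$mask, direct$mask)
  expect_equal(attr(routed, "backend_id"), "classical/reference")

  fixed <- stub_detections(c(0.8, 0.4), shape = c(30, 40))
  expect_equal(nrow(segment_with_backend(img, stub_backend(fixed))), 2L)

  bad_shape <- stub_detections(0.9, shape = c(10, 10))
  expect_error(segment_with_backend(img, stub_backend(bad_shape, id = "bad")),
               regexp = "bad", class = "petalpix_error_backend_failure")
  raiser <- stub_backend(NULL, id = "boom")
  raiser <- structure(function(image) stop("exploded"), backend_id = "boom")
  expect_error(segment_with_backend(img, raiser),
               regexp = "boom", class = "petalpix_error_backend_failure")
})

test_that("confidence filter keeps >= threshold and composes by max", {
  det <- stub_detections(c(0.9, 0.5, 0.49))
  expect_equal(nrow(filter_by_confidence(det, 0.5)), 2L)
  expect_equal(nrow(filter_by_confidence(det, 0)), 3L)
  expect_equal(nrow(filter_by_confidence(det, 1)), 0L)
  expect_error(filter_by_confidence(det, 1.2), class = "petalpix_error_parameter")

  set.seed(13)
  for (i in 1:10) {
    d <- stub_detections(stats::runif(8))
    t1 <- stats::runif(1); t2 <- stats::runif(1)
    expect_identical(
      filter_by_confidence(filter_by_confidence(d, t1), t2),
      filter_by_confidence(d, max(t1, t2))
    )
  }
})

test_that("class pixel counts use mask unions, invariant to order and duplicates", {
  shape <- c(20, 20)
  a <- rect_mask(shape, 1, 10, 1, 10)
  b <- rect_mask(shape, 7, 16, 7, 16)
  det <- tibble::tibble(label = c("flower", "flower"), confidence = c(1, 1),
                        mask = list(a, b))
  expect_equal(class_pixel_count(det, "flower"),
               sum(a) + sum(b) - mask_intersection_count(a, b))
  expect_equal(class_pixel_count(det, "reference", shape), 0)
  expect_equal(class_pixel_count(det[2:1, ], "flower"),
               class_pixel_count(det, "flower"))
  expect_equal(class_pixel_count(det[c(1, 2, 2, 1), ], "flower"),
               class_pixel_count(det, "flower"))

  disjoint <- tibble::tibble(label = "flower", confidence = 1,
                             mask = list(rect_mask(shape, 1, 10, 1, 10),
                                         rect_mask(shape, 11, 20, 11, 20)))
  expect_equal(class_pixel_count(disjoint, "flower"), 200)
})
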