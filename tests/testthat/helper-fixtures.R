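# shared fixtures: tiny masks, random masks, flat-colour images, and
# brute-force oracles used to cross-check the fast implementations

rect_mask <- function(shape, r0, r1, c0, c1) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[r0:r1, c0:c1] <- TRUE
  m
}

random_mask <- function(shape, p = 0.3) {
  matrix(stats::runif(prod(shape)) < p, shape[1], shape[2])
}

flat_image <- function(shape, rgb) {
  px <- array(0, dim = c(shape, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  raster_image(px)
}

# image with a coloured rectangle on a flat background
rect_image <- function(shape, r0, r1, c0, c1, rgb, bg = c(208, 208, 208)) {
  img <- flat_image(shape, bg)
  px <- img$pixels
  for (ch in 1:3) px[r0:r1, c0:c1, ch] <- rgb[ch]
  raster_image(px)
}

# stub detections of given confidences over trivially valid masks
stub_detections <- function(confidences, shape = c(8, 8), label = "flower") {
  tibble::tibble(
    label = rep(label, length(confidences)),
    confidence = confidences,
    mask = lapply(seq_along(confidences), function(i) rect_mask(shape, 1, 2, 1, 2))
  )
}

# brute-force AP oracle: enumerate every confidence cut, compute the PR point
# at each cut (greedy matching of the kept top-k list), build the precision
# envelope over a dense recall grid, and integrate numerically. Independent
# of the single-sweep implementation.
ap_bruteforce <- function(predictions, truths, iou_threshold = 0.5,
                          grid_n = 20000L) {
  pred <- predictions[order(-predictions$confidence), , drop = FALSE]
  n <- nrow(pred)
  pts <- lapply(seq_len(n), function(k) {
    top <- pred[seq_len(k), , drop = FALSE]
    m <- match_detections(top, truths, iou_threshold)
    tp <- nrow(m$pairs)
    c(recall = tp / length(truths), precision = tp / k)
  })
  pts <- do.call(rbind, pts)
  rgrid <- seq(0, 1, length.out = grid_n)
  penv <- vapply(rgrid, function(r) {
    cand <- pts[pts[, "recall"] >= r - 1e-12, "precision"]
    if (length(cand)) max(cand) else 0
  }, numeric(1))
  max_r <- max(pts[, "recall"])
  penv[rgrid > max_r + 1e-12] <- 0
  mean(penv) # integral over [0,1] of the envelope (0 beyond max recall)
}

# brute-force one-way ANOVA F from first principles (no shared code path)
f_bruteforce <- function(groups) {
  values <- unlist(groups)
  k <- length(groups)
  n <- length(values)
  gm <- sum(values) / n
  msb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, numeric(1))) / (k - 1)
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / (n - k)
  msb / msw
}

# small benchmark for pipeline-level tests (kept tiny for speed)
tiny_benchmark <- function(n = 6, seed = 5) {
  generate_benchmark(n, seed = seed, canvas_cm = c(30, 40))
}
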