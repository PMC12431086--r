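shape <- c(20, 20)

test_that("mask IoU matches inclusion-exclusion arithmetic", {
  a <- rect_mask(shape, 1, 10, 1, 10)
  expect_equal(mask_iou(a, a), 1)
  expect_equal(mask_iou(a, rect_mask(shape, 11, 20, 11, 20)), 0)
  # 100 and 100 px sharing 40: IoU = 40 / 160
  b <- rect_mask(shape, 5, 14, 1, 10)
  expect_equal(mask_intersection_count(a, b), 60)
  b2 <- rect_mask(shape, 7, 16, 1, 10)
  expect_equal(mask_iou(a, b2), 40 / 160)
  expect_equal(mask_iou(a, b2), mask_iou(b2, a))
  empty <- matrix(FALSE, 20, 20)
  expect_error(mask_iou(empty, empty), class = "petalpix_error_undefined_iou")
})

test_that("greedy matching is confidence-ordered, one-to-one, lowest-index on ties", {
  t1 <- rect_mask(shape, 1, 10, 1, 10)
  t2 <- rect_mask(shape, 11, 20, 11, 20)

  m <- match_detections(list(t1), list(t1), 0.5)
  expect_equal(nrow(m$pairs), 1L)
  expect_length(m$unmatched_predictions, 0L)
  expect_length(m$unmatched_truths, 0L)

  # two predictions both over truth 1: higher confidence wins, other is FP
  preds <- tibble::tibble(mask = list(t1, t1), confidence = c(0.6, 0.9))
  m <- match_detections(preds, list(t1, t2), 0.5)
  expect_equal(m$pairs$prediction, 2L)
  expect_equal(m$pairs$truth, 1L)
  expect_equal(m$unmatched_predictions, 1L)
  expect_equal(m$unmatched_truths, 2L)

  # tie on IoU goes to the lowest truth index
  m <- match_detections(list(t1), list(t1, t1), 0.5)
  expect_equal(m$pairs$truth, 1L)

  m <- match_detections(list(), list(t1, t2, t1), 0.5)
  expect_equal(length(m$unmatched_truths), 3L)
})

test_that("precision and recall follow their defining ratios", {
  t1 <- rect_mask(shape, 1, 10, 1, 10)
  t2 <- rect_mask(shape, 11, 20, 11, 20)
  off <- rect_mask(shape, 1, 2, 15, 16)
  preds <- tibble::tibble(mask = list(t1, t2, off), confidence = c(0.9, 0.8, 0.7))
  m <- match_detections(preds, list(t1, t2), 0.5)
  pr <- precision_recall(m, 3, 2)
  expect_equal(pr$precision, 2 / 3, tolerance = 1e-12)
  expect_equal(pr$recall, 1)

  perfect <- match_detections(list(t1, t2), list(t1, t2), 0.5)
  pr <- precision_recall(perfect, 2, 2)
  expect_equal(c(pr$precision, pr$recall), c(1, 1))

  none <- match_detections(list(off), list(t1), 0.5)
  pr <- precision_recall(none, 1, 1)
  expect_equal(c(pr$precision, pr$recall), c(0, 0))

  empty <- match_detections(list(), list(t1), 0.5)
  pr0 <- precision_recall(empty, 0, 1)
  expect_false(pr0$precision_defined)
  expect_equal(pr0$precision, 0)
  expect_error(precision_recall(empty, 0, 0), class = "petalpix_error_parameter")
})

test_that("AP equals the hand-computed envelope on the TP,FP,TP case", {
  t1 <- rect_mask(shape, 1, 10, 1, 10)
  t2 <- rect_mask(shape, 11, 20, 11, 20)
  off <- rect_mask(shape, 1, 2, 15, 16)
  preds <- tibble::tibble(mask = list(t1, off, t2), confidence = c(0.9, 0.8, 0.7))
  ap <- average_precision(preds, list(t1, t2), 0.5)
  expect_equal(ap$ap, 0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)

  expect_equal(average_precision(list(t1, t2), list(t1, t2), 0.5)$ap, 1)
  expect_equal(average_precision(list(), list(t1), 0.5)$ap, 0)
  expect_error(average_precision(list(t1), list(), 0.5),
               class = "petalpix_error_parameter")
})

test_that("sweep AP equals brute-force envelope integration on small cases", {
  t1 <- rect_mask(shape, 1, 10, 1, 10)
  t2 <- rect_mask(shape, 11, 20, 11, 20)
  t3 <- rect_mask(shape, 1, 8, 12, 19)
  off <- rect_mask(shape, 12, 13, 1, 2)
  near <- rect_mask(shape, 2, 11, 1, 10) # IoU with t1 = 90/110 ~ 0.82
  cases <- list(
    list(preds = tibble::tibble(mask = list(t1, off, t2),
                                confidence = c(0.9, 0.8, 0.7)),
         truths = list(t1, t2)),
    list(preds = tibble::tibble(mask = list(off, t1), confidence = c(0.9, 0.2)),
         truths = list(t1)),
    list(preds = tibble::tibble(mask = list(near, t2, off, t3, t1, off),
                                confidence = c(0.95, 0.9, 0.85, 0.5, 0.4, 0.1)),
         truths = list(t1, t2, t3)),
    list(preds = tibble::tibble(mask = list(t1, t1, t2, off),
                                confidence = c(0.7, 0.7, 0.6, 0.5)),
         truths = list(t1, t2, t3))
  )
  for (cs in cases) {
    for (thr in c(0.5, 0.75)) {
      expect_equal(average_precision(cs$preds, cs$truths, thr)$ap,
                   ap_bruteforce(cs$preds, cs$truths, thr),
                   tolerance = 2e-4)
    }
  }
})

test_that("AP is invariant to rank-preserving confidence rescaling", {
  t1 <- rect_mask(shape, 1, 10, 1, 10)
  t2 <- rect_mask(shape, 11, 20, 11, 20)
  off <- rect_mask(shape, 12, 13, 1, 2)
  preds <- tibble::tibble(mask = list(t1, off, t2), confidence = c(0.9, 0.5, 0.3))
  ap1 <- average_precision(preds, list(t1, t2), 0.5)$ap
  preds$confidence <- preds$confidence^3 / 2 # monotone rescale
  expect_equal(average_precision(preds, list(t1, t2), 0.5)$ap, ap1)
})

test_that("appending a lowest-ranked false positive never raises AP", {
  t1 <- rect_mask(shape, 1, 10, 1, 10)
  t2 <- rect_mask(shape, 11, 20, 11, 20)
  off <- rect_mask(shape, 12, 13, 1, 2)
  set.seed(5)
  for (i in 1:8) {
    k <- sample(1:3, 1)
    masks <- sample(list(t1, t2, off), k, replace = TRUE)
    conf <- sort(stats::runif(k), decreasing = TRUE)
    preds <- tibble::tibble(mask = masks, confidence = conf)
    base <- average_precision(preds, list(t1, t2), 0.5)$ap
    worse <- dplyr::bind_rows(preds, tibble::tibble(mask = list(off),
                                                    confidence = min(conf) / 2))
    expect_lte(average_precision(worse, list(t1, t2), 0.5)$ap, base + 1e-12)
  }
})

test_that("mAP averages thresholds and is non-increasing in the threshold", {
  t1 <- rect_mask(shape, 1, 10, 1, 10)
  # prediction with IoU 0.6 against its truth: overlaps 75 of 125
  pred <- rect_mask(shape, 3, 12, 1, 10) # IoU with t1 = 80/120 = 2/3
  expect_equal(mask_iou(pred, t1), 2 / 3, tolerance = 1e-12)
  s <- mean_ap(list(pred), list(t1))
  # AP 1 at thresholds <= 2/3 (0.50, 0.55, 0.60, 0.65), 0 above
  expect_equal(s$map5095, 4 / 10)
  expect_equal(s$map50, 1)

  perfect <- mean_ap(list(t1), list(t1))
  expect_equal(perfect$map5095, 1)
  expect_equal(perfect$per_threshold$ap, rep(1, 10))

  single <- mean_ap(list(pred), list(t1), thresholds = 0.5)
  expect_equal(single$map5095, average_precision(list(pred), list(t1), 0.5)$ap)

  expect_true(all(diff(s$per_threshold$ap) <= 1e-12))
})

test_that("multi-class mAP averages per-class AP with equal weight", {
  t1 <- rect_mask(shape, 1, 10, 1, 10)
  t2 <- rect_mask(shape, 11, 20, 11, 20)
  preds <- tibble::tibble(label = c("flower", "reference"),
                          mask = list(t1, t2), confidence = c(0.9, 0.9))
  truths <- tibble::tibble(label = c("flower", "reference"), mask = list(t1, t2))
  s <- mean_ap(preds, truths, thresholds = 0.5)
  expect_equal(s$map50, 1)
  # break one class: flower prediction misses entirely
  preds$mask[[1]] <- rect_mask(shape, 12, 13, 1, 2)
  s2 <- mean_ap(preds, truths, thresholds = 0.5)
  expect_equal(s2$map50, 0.5)
})
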