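#' Mask intersection over union
#'
#' IoU of two same-shaped binary masks: `|A & B| / |A | B|`. Symmetric, in
#' \[0, 1\]. Undefined (an error) when both masks are empty.
#'
#' @param a,b logical matrices with identical dimensions.
#' @return IoU in \[0, 1\].
#' @export
mask_iou <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  if (!identical(dim(a), dim(b))) pp_abort("masks have mixed dimensions", "mask")
  uni <- sum(a | b)
  if (uni == 0L) pp_abort("IoU of two empty masks is undefined", "undefined_iou")
  sum(a & b) / uni
}

# predictions as a tibble with columns mask (list) and confidence; accepts a
# plain list of masks (confidence 1, original order)
as_prediction_tbl <- function(predictions) {
  if (is.data.frame(predictions)) {
    stopifnot(all(c("mask", "confidence") %in% names(predictions)))
    as_tibble(predictions)
  } else {
    tibble(mask = predictions, confidence = rep(1, length(predictions)))
  }
}

#' Match predicted to ground-truth masks
#'
#' Greedy one-to-one matching, the standard detection-evaluation procedure:
#' predictions are visited in order of descending confidence (ties keep the
#' original order) and each claims the still-unmatched ground truth with the
#' highest IoU, provided that IoU reaches `iou_threshold`; IoU ties go to the
#' lowest truth index. Unmatched predictions are false positives, unmatched
#' truths false negatives.
#'
#' @param predictions detections tibble (columns `mask`, `confidence`) or a
#'   list of masks.
#' @param truths list of ground-truth masks.
#' @param iou_threshold minimum IoU for a valid match, default 0.5.
#' @return An object of class `match_result`: `pairs` (tibble `prediction`,
#'   `truth`, `iou`, `confidence`, in match order), `unmatched_predictions`,
#'   `unmatched_truths`, `iou_threshold`.
#' @export
match_detections <- function(predictions, truths, iou_threshold = 0.5) {
  pred <- as_prediction_tbl(predictions)
  ord <- order(-pred$confidence) # stable: ties keep original order
  matched_truth <- rep(FALSE, length(truths))
  pairs <- list()
  for (i in ord) {
    ious <- vapply(seq_along(truths), function(j) {
      if (matched_truth[j]) return(-1)
      tryCatch(mask_iou(pred$mask[[i]], truths[[j]]), petalpix_error = function(e) 0)
    }, numeric(1))
    if (length(ious) == 0L) next
    best <- max(ious)
    if (best >= iou_threshold) {
      j <- which(ious == best)[1] # lowest truth index on ties
      matched_truth[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- tibble(
        prediction = i, truth = j, iou = best, confidence = pred$confidence[i]
      )
    }
  }
  pairs <- if (length(pairs)) bind_rows(pairs) else {
    tibble(prediction = integer(), truth = integer(),
           iou = numeric(), confidence = numeric())
  }
  structure(
    list(
      pairs = pairs,
      unmatched_predictions = setdiff(seq_len(nrow(pred)), pairs$prediction),
      unmatched_truths = which(!matched_truth),
      iou_threshold = iou_threshold
    ),
    class = "match_result"
  )
}

#' Precision and recall from a match result
#'
#' Precision is the fraction of predictions that are true positives; recall
#' the fraction of ground truths found. With zero predictions precision is
#' reported as 0 with `precision_defined = FALSE` (rather than NaN) so batch
#' summaries stay finite; zero ground truths make recall an error.
#'
#' @param match a `match_result`.
#' @param n_predictions,n_truths totals the match was computed over.
#' @return A list: `precision`, `recall`, `tp`, `precision_defined`.
#' @export
precision_recall <- function(match, n_predictions, n_truths) {
  stopifnot(inherits(match, "match_result"))
  if (n_truths < 1L) pp_abort("recall needs at least one ground truth", "parameter")
  tp <- nrow(match$pairs)
  list(
    precision = if (n_predictions > 0L) tp / n_predictions else 0,
    recall = tp / n_truths,
    tp = tp,
    precision_defined = n_predictions > 0L
  )
}

#' Average precision at one IoU threshold
#'
#' Sweeps the confidence-ranked prediction list, accumulating true/false
#' positives under greedy matching, builds the precision-recall curve, applies
#' the all-point precision envelope (precision at recall r is the maximum
#' precision attained at any recall >= r, the COCO-style convention), and
#' integrates the envelope over recall.
#'
#' @inheritParams match_detections
#' @return An object of class `ap_result`: `ap`, `iou_threshold`, `curve`
#'   (tibble `recall`, `precision`, `precision_envelope` in rank order),
#'   `n_predictions`, `n_truths`.
#' @export
average_precision <- function(predictions, truths, iou_threshold = 0.5) {
  pred <- as_prediction_tbl(predictions)
  if (length(truths) < 1L) pp_abort("AP needs at least one ground truth", "parameter")
  n <- nrow(pred)
  if (n == 0L) {
    return(structure(
      list(ap = 0, iou_threshold = iou_threshold,
           curve = tibble(recall = numeric(), precision = numeric(),
                          precision_envelope = numeric()),
           n_predictions = 0L, n_truths = length(truths)),
      class = "ap_result"
    ))
  }
  m <- match_detections(pred, truths, iou_threshold)
  ord <- order(-pred$confidence)
  tp <- ord %in% m$pairs$prediction
  ctp <- cumsum(tp)
  prec <- ctp / seq_len(n)
  rec <- ctp / length(truths)
  penv <- rev(cummax(rev(prec)))
  ap <- sum(diff(c(0, rec)) * penv)
  structure(
    list(ap = ap, iou_threshold = iou_threshold,
         curve = tibble(recall = rec, precision = prec, precision_envelope = penv),
         n_predictions = n, n_truths = length(truths)),
    class = "ap_result"
  )
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("AP@%.2f = %.4f (%d predictions, %d truths)\n",
              x$iou_threshold, x$ap, x$n_predictions, x$n_truths))
  invisible(x)
}

#' Mean average precision over IoU thresholds
#'
#' Computes AP at each IoU threshold (default 0.50 to 0.95 in steps of 0.05,
#' ten values) and averages with equal weight. When both predictions and
#' truths carry labels, AP is computed per class and classes are averaged
#' with equal weight at each threshold before the threshold mean. The summary
#' also reports precision and recall of the full prediction set at IoU 0.5,
#' `map50` (AP averaged at threshold 0.5 only) and `map5095` (the 10-threshold
#' mean).
#'
#' @param predictions detections tibble (`mask`, `confidence`, optionally
#'   `label`) or list of masks.
#' @param truths list of masks, or tibble with `mask` and optionally `label`.
#' @param thresholds IoU thresholds, default `seq(0.5, 0.95, by = 0.05)`.
#' @return An object of class `map_summary`: `precision`, `recall`, `map50`,
#'   `map5095`, `per_threshold` (tibble `iou_threshold`, `ap`), `classes`.
#' @export
mean_ap <- function(predictions, truths, thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (length(thresholds) == 0L) pp_abort("need at least one IoU threshold", "parameter")
  pred <- as_prediction_tbl(predictions)
  truth_tbl <- if (is.data.frame(truths)) as_tibble(truths) else tibble(mask = truths)
  labelled <- "label" %in% names(pred) && "label" %in% names(truth_tbl)
  classes <- if (labelled) sort(unique(truth_tbl$label)) else "all"

  ap_one <- function(p, t, thr) average_precision(p, t, thr)$ap
  per_thr <- map_dbl(thresholds, function(thr) {
    if (!labelled) {
      ap_one(pred, truth_tbl$mask, thr)
    } else {
      mean(map_dbl(classes, function(cl) {
        ap_one(pred[pred$label == cl, , drop = FALSE],
               truth_tbl$mask[truth_tbl$label == cl], thr)
      }))
    }
  })

  m <- match_detections(pred, truth_tbl$mask, 0.5)
  pr <- precision_recall(m, nrow(pred), nrow(truth_tbl))
  map50 <- if (any(abs(thresholds - 0.5) < 1e-12)) {
    per_thr[which.min(abs(thresholds - 0.5))]
  } else {
    NA_real_
  }
  structure(
    list(precision = pr$precision, recall = pr$recall,
         map50 = map50, map5095 = mean(per_thr),
         per_threshold = tibble(iou_threshold = thresholds, ap = per_thr),
         classes = classes),
    class = "map_summary"
  )
}

#' @export
print.map_summary <- function(x, ...) {
  cat(sprintf("precision %.3f | recall %.3f | mAP@0.5 %s | mAP@0.5:0.95 %.3f\n",
              x$precision, x$recall,
              ifelse(is.na(x$map50), "NA", sprintf("%.3f", x$map50)),
              x$map5095))
  invisible(x)
}

#' @export
glance.map_summary <- function(x, ...) {
  tibble(precision = x$precision, recall = x$recall,
         map50 = x$map50, map5095 = x$map5095,
         n_thresholds = nrow(x$per_threshold))
}

#' @export
tidy.map_summary <- function(x, ...) x$per_threshold
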