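# Pixel-level and object-level performance measures for spike segmentation
# and counting.
#
# Pixel metrics follow the usual confusion-count definitions: precision
# TP/(TP+FP), recall TP/(TP+FN), accuracy (TP+TN)/total, F1 = 2PR/(P+R),
# Jaccard index TP/(TP+FP+FN). The two classification-error summaries are
# E1 = (FP+FN)/total (overall misclassification rate, so E1 * total is the
# number of wrongly classified pixels) and E2 = mean of the false-positive
# and false-negative rates (class-balanced type-I/II error).

#' Pixel-level confusion counts between a predicted and a true mask
#'
#' @param predicted,truth Binary matrices of equal size, 1 = spike.
#' @return A `pixel_confusion` with counts `tp`, `tn`, `fp`, `fn`.
#' @export
pixel_confusion <- function(predicted, truth) {
  check_binary_pair(predicted, truth)
  p <- predicted == 1
  t <- truth == 1
  structure(
    list(
      tp = sum(p & t), tn = sum(!p & !t),
      fp = sum(p & !t), fn = sum(!p & t)
    ),
    class = "pixel_confusion"
  )
}

check_binary_pair <- function(predicted, truth) {
  if (!all(dim(predicted) == dim(truth))) {
    abort("`predicted` and `truth` must have identical dimensions.")
  }
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1))) {
    abort("masks must be binary (values in {0, 1}).")
  }
  invisible(NULL)
}

#' @export
print.pixel_confusion <- function(x, ...) {
  cat(sprintf("<pixel_confusion> TP %d  TN %d  FP %d  FN %d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

ratio_or <- function(num, den, empty_value) {
  if (den == 0) empty_value else num / den
}

#' Segmentation metrics from pixel confusion counts
#'
#' When a denominator is empty (no predicted or no true positives at all),
#' the corresponding ratio is 1 if the other side is empty too -- perfect
#' agreement on an empty class is not penalised -- and 0 otherwise.
#'
#' @param confusion A `pixel_confusion` (or a list with `tp`, `tn`, `fp`,
#'   `fn`).
#' @return One-row tibble with `precision`, `recall`, `accuracy`, `f1`,
#'   `ji`, `e1`, `e2`.
#' @export
#' @examples
#' segmentation_metrics(list(tp = 90, tn = 900, fp = 5, fn = 5))
segmentation_metrics <- function(confusion) {
  tp <- confusion$tp; tn <- confusion$tn; fp <- confusion$fp; fn <- confusion$fn
  total <- tp + tn + fp + fn
  if (total == 0) abort("empty confusion: no pixels were compared.")
  both_empty <- (tp + fp == 0) && (tp + fn == 0)
  precision <- ratio_or(tp, tp + fp, if (both_empty) 1 else 0)
  recall <- ratio_or(tp, tp + fn, if (both_empty) 1 else 0)
  f1 <- ratio_or(2 * precision * recall, precision + recall, 0)
  ji <- ratio_or(tp, tp + fp + fn, 1) # empty union means identical empty masks
  fpr <- ratio_or(fp, fp + tn, 0)
  fnr <- ratio_or(fn, fn + tp, 0)
  tibble::tibble(
    precision = precision,
    recall = recall,
    accuracy = (tp + tn) / total,
    f1 = f1,
    ji = ji,
    e1 = (fp + fn) / total,
    e2 = (fpr + fnr) / 2
  )
}

#' F-measure from a precision/recall operating point
#'
#' @param precision,recall Rates in `[0, 1]`.
#' @return The harmonic mean `2 P R / (P + R)`.
#' @export
#' @examples
#' f_measure(0.9993, 0.9989) # 0.9991
f_measure <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Jaccard index from a precision/recall operating point
#'
#' Uses the identity `JI = 1 / (1/P + 1/R - 1)`, valid whenever TP > 0.
#'
#' @inheritParams f_measure
#' @return The implied intersection-over-union.
#' @export
#' @examples
#' jaccard_from_pr(0.9993, 0.9989) # 0.9982
jaccard_from_pr <- function(precision, recall) {
  1 / (1 / precision + 1 / recall - 1)
}

#' Object-level counting metrics
#'
#' Same formulas as the pixel metrics but with TN fixed at 0 (the background
#' is not an object), so accuracy reduces to TP/(TP+FP+FN) -- identical to
#' the Jaccard index of the object counts.
#'
#' @param confusion A list with object counts `tp`, `fp`, `fn` (and
#'   optionally `tn`, which must be 0).
#' @return One-row tibble with `precision`, `recall`, `accuracy`, `f1`.
#' @export
#' @examples
#' counting_metrics(list(tp = 13, fp = 2, fn = 1)) # accuracy 0.8125
counting_metrics <- function(confusion) {
  tp <- confusion$tp; fp <- confusion$fp; fn <- confusion$fn
  tn <- confusion$tn %||% 0
  if (tn != 0) abort("object-level TN must be 0.")
  if (tp + fp + fn == 0) abort("empty object confusion.")
  precision <- ratio_or(tp, tp + fp, 1)
  recall <- ratio_or(tp, tp + fn, 1)
  tibble::tibble(
    precision = precision,
    recall = recall,
    accuracy = tp / (tp + fp + fn),
    f1 = ratio_or(2 * precision * recall, precision + recall, 0)
  )
}

#' Number of misclassified pixels implied by an error rate
#'
#' @param e1 Overall misclassification rate in `[0, 1]`.
#' @param n_pixels Number of pixels the rate refers to (65,536 for a
#'   256 x 256 mask).
#' @return `round(e1 * n_pixels)`, the implied count of wrongly classified
#'   pixels.
#' @export
#' @examples
#' implied_error_pixels(0.0016, 256^2) # 105
implied_error_pixels <- function(e1, n_pixels) {
  if (any(e1 < 0 | e1 > 1)) abort("`e1` must lie in [0, 1].")
  round(e1 * n_pixels)
}

#' Render the disagreement overlay between a prediction and the truth
#'
#' The ground-truth mask is drawn as the backdrop (spikes dark on a white
#' background); missed spike pixels (false negatives) are painted pink and
#' spurious spike pixels (false positives) green, so the coloured-pixel
#' count equals FP + FN.
#'
#' @inheritParams pixel_confusion
#' @return RGB array `[H, W, 3]` on 0--255.
#' @export
error_overlay <- function(predicted, truth) {
  check_binary_pair(predicted, truth)
  H <- nrow(truth); W <- ncol(truth)
  img <- array(255, c(H, W, 3))
  paint <- function(img, sel, color) {
    lin <- which(sel)
    for (ch in 1:3) img[lin + (ch - 1L) * H * W] <- color[ch]
    img
  }
  img <- paint(img, truth == 1, c(40, 40, 40))
  img <- paint(img, truth == 1 & predicted == 0, c(255, 105, 180)) # missed: pink
  img <- paint(img, truth == 0 & predicted == 1, c(0, 200, 0)) # spurious: green
  img
}

#' Evaluate a set of predicted/true mask pairs
#'
#' Computes [segmentation_metrics()] per image and then averages the
#' per-image metrics arithmetically (mean of ratios, not pooled confusion),
#' matching how per-plant values are averaged over the three view images.
#'
#' @param pairs A list of `list(predicted = , truth = )` mask pairs, or a
#'   data frame / tibble with list-columns `predicted` and `truth`.
#' @return A list with `per_image` (tibble, one row per pair, with an `image`
#'   index) and `average` (one-row tibble of the column means).
#' @export
evaluate_dataset <- function(pairs) {
  if (is.data.frame(pairs)) {
    pairs <- purrr::map2(pairs$predicted, pairs$truth,
                         function(p, t) list(predicted = p, truth = t))
  }
  if (length(pairs) == 0L) abort("`pairs` must contain at least one mask pair.")
  per <- purrr::map_dfr(seq_along(pairs), function(i) {
    m <- segmentation_metrics(pixel_confusion(pairs[[i]]$predicted,
                                              pairs[[i]]$truth))
    dplyr::bind_cols(tibble::tibble(image = i), m)
  })
  avg <- dplyr::summarise(per, dplyr::across(-"image", mean))
  list(per_image = per, average = avg)
}

#' Worked spike-count validation outcomes for a 30-plant experiment
#'
#' Per-plant ground-truth and predicted spike counts with the object-level
#' TP/FP/FN bookkeeping for a 30-plant validation of the three-view counting
#' protocol; shipped as a plain-text fixture so the object-metric arithmetic
#' has a realistic worked example. Re-deriving precision/accuracy/F1 per row
#' with [counting_metrics()] reproduces the tabulated two-decimal values,
#' and their means round to 99%, 95% and 97%.
#'
#' @return Tibble with columns `image`, `ground_truth`, `predicted`, `tp`,
#'   `fp`, `fn`, `precision`, `accuracy`, `f1`.
#' @export
spike_count_validation <- function() {
  path <- system.file("extdata", "spike_count_validation.csv",
                      package = "spikeseg", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
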