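#' Evaluate detections against ground truth: P, R, F1 and AP
#'
#' Pascal-VOC style single-class evaluation. Predictions are ranked by
#' descending confidence; each is greedily matched to the unclaimed truth box
#' of highest IoU, a true positive if that IoU reaches `iou_thresh` and a
#' false positive otherwise; truths left unclaimed are false negatives.
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and `F1 = 2PR/(P+R)` are
#' reported at the full ranking, and average precision is the area under the
#' precision-recall curve accumulated over the ranking.
#'
#' @param predicted Data frame of predicted boxes with a `conf` column
#'   (scores in \[0, 1\]).
#' @param truth Data frame of ground-truth boxes.
#' @param iou_thresh Minimum IoU for a prediction to claim a truth box.
#'   Default 0.5.
#' @param interpolation `"all"` (default; all-point interpolated AP, the area
#'   under the running-maximum precision envelope) or `"11pt"` (the older
#'   11-point average).
#' @return Object of class `detection_eval`: `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`, `ap`, `pr_curve` (tibble `recall`, `precision`), and
#'   `undefined` flags for empty inputs.
#' @examples
#' truth <- bbox(c(10, 30, 50), 10, 8, 8)
#' pred <- bbox(c(10, 90, 30), 10, 8, 8, conf = c(0.9, 0.8, 0.7))
#' eval_detections(pred, truth)$ap # 5/9
#' @export
eval_detections <- function(predicted, truth, iou_thresh = 0.5,
                            interpolation = c("all", "11pt")) {
  interpolation <- match.arg(interpolation)
  predicted <- tibble::as_tibble(predicted)
  truth <- tibble::as_tibble(truth)
  np <- nrow(predicted); nt <- nrow(truth)
  if (np > 0) {
    validate_boxes(predicted)
    if (!"conf" %in% names(predicted)) predicted$conf <- 1
  }
  if (nt > 0) validate_boxes(truth)

  if (np == 0L) {
    return(new_detection_eval(tp = 0L, fp = 0L, fn = nt,
                              is_tp = logical(),
                              n_truth = nt, interpolation = interpolation))
  }
  ord <- order(predicted$conf, decreasing = TRUE)
  predicted <- predicted[ord, ]
  is_tp <- greedy_claim(predicted, truth, iou_thresh)
  new_detection_eval(tp = sum(is_tp), fp = sum(!is_tp),
                     fn = nt - sum(is_tp),
                     is_tp = is_tp, n_truth = nt,
                     interpolation = interpolation)
}

# score-ordered greedy matching: each prediction claims the unclaimed truth
# of highest IoU, TP if that IoU reaches the threshold
greedy_claim <- function(pred_sorted, truth, iou_thresh) {
  np <- nrow(pred_sorted); nt <- nrow(truth)
  is_tp <- logical(np)
  if (nt == 0L || np == 0L) return(is_tp)
  claimed <- logical(nt)
  iom <- iou_matrix(pred_sorted, truth)
  for (i in seq_len(np)) {
    ious <- iom[i, ]
    ious[claimed] <- -1
    j <- which.max(ious)
    if (ious[j] >= iou_thresh) {
      is_tp[i] <- TRUE
      claimed[j] <- TRUE
    }
  }
  is_tp
}

#' Evaluate a multi-frame detection stream
#'
#' Frame-aware variant of [eval_detections()]: predictions may only claim
#' truth boxes of their own frame, while the precision-recall curve and AP
#' are accumulated over the global confidence ranking across frames.
#'
#' @param predicted,truth Detection tibbles with a `frame` column.
#' @inheritParams eval_detections
#' @return A `detection_eval` object.
#' @export
eval_detection_stream <- function(predicted, truth, iou_thresh = 0.5,
                                  interpolation = c("all", "11pt")) {
  interpolation <- match.arg(interpolation)
  predicted <- tibble::as_tibble(predicted)
  truth <- tibble::as_tibble(truth)
  if (!"conf" %in% names(predicted)) predicted$conf <- 1
  frames <- union(unique(predicted$frame), unique(truth$frame))
  per_frame <- purrr::map(frames, function(f) {
    p <- predicted[predicted$frame == f, , drop = FALSE]
    p <- p[order(p$conf, decreasing = TRUE), , drop = FALSE]
    list(conf = p$conf,
         is_tp = greedy_claim(p, truth[truth$frame == f, , drop = FALSE],
                              iou_thresh))
  })
  conf <- unlist(purrr::map(per_frame, "conf"))
  is_tp <- unlist(purrr::map(per_frame, "is_tp"))
  ord <- order(conf, decreasing = TRUE)
  is_tp <- as.logical(is_tp[ord] %||% logical())
  nt <- nrow(truth)
  new_detection_eval(tp = sum(is_tp), fp = sum(!is_tp),
                     fn = nt - sum(is_tp), is_tp = is_tp, n_truth = nt,
                     interpolation = interpolation)
}

new_detection_eval <- function(tp, fp, fn, is_tp, n_truth, interpolation) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  if (length(is_tp) && n_truth > 0) {
    cum_tp <- cumsum(is_tp)
    pr <- tibble::tibble(recall = cum_tp / n_truth,
                         precision = cum_tp / seq_along(is_tp))
    ap <- average_precision(pr$recall, pr$precision, interpolation)
  } else {
    pr <- tibble::tibble(recall = numeric(), precision = numeric())
    ap <- 0
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                 precision = precision, recall = recall, f1 = f1, ap = ap,
                 pr_curve = pr,
                 undefined = list(precision = tp + fp == 0,
                                  recall = n_truth == 0)),
            class = "detection_eval")
}

# area under the PR curve from the ranked (recall, precision) sequence
average_precision <- function(recall, precision, interpolation = "all") {
  # precision envelope: max precision achievable at recall >= r
  env <- rev(cummax(rev(precision)))
  if (interpolation == "11pt") {
    pts <- vapply(seq(0, 1, by = 0.1), function(r) {
      ok <- recall >= r - 1e-12
      if (any(ok)) max(precision[ok]) else 0
    }, numeric(1))
    return(mean(pts))
  }
  r_prev <- c(0, head(recall, -1))
  sum((recall - r_prev) * env)
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf("<detection_eval> TP %d FP %d FN %d | P %.4f R %.4f F1 %.4f AP %.4f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1, x$ap))
  invisible(x)
}

#' @describeIn eval_detections `tidy()` returns the PR curve tibble.
#' @param x A `detection_eval` object.
#' @param ... Unused.
#' @method tidy detection_eval
#' @export
tidy.detection_eval <- function(x, ...) x$pr_curve

#' @describeIn eval_detections `glance()` returns a one-row tibble of all
#'   scalar metrics.
#' @method glance detection_eval
#' @export
glance.detection_eval <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn, precision = x$precision,
                 recall = x$recall, f1 = x$f1, ap = x$ap)
}

#' @describeIn eval_detections `autoplot()` draws the precision-recall curve.
#' @param object A `detection_eval` object.
#' @method autoplot detection_eval
#' @export
autoplot.detection_eval <- function(object, ...) {
  ggplot2::ggplot(object$pr_curve,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("PR curve (AP = %.4f)", object$ap)) +
    ggplot2::theme_minimal()
}

#' Agreement between predicted and true counts
#'
#' Coefficient of determination
#' \deqn{R^2 = 1 - \sum_i (\hat y_i - y_i)^2 / \sum_i (\bar y - y_i)^2}
#' and root mean square error
#' \deqn{RMSE = \sqrt{\sum_i (\hat y_i - y_i)^2 / n}}
#' over paired per-video (or per-image) counts. `r2` is 1 and `rmse` 0
#' exactly when predictions equal truth elementwise; `r2` is undefined (and
#' flagged) when the truth has zero variance.
#'
#' @param data Optional data frame holding the two count columns; when
#'   supplied, `pred` and `truth` are evaluated within it, so the function
#'   pipes: `scores |> eval_counts(predicted, observed)`.
#' @param pred,truth Numeric vectors of equal length (bare column names when
#'   `data` is given).
#' @return Object of class `count_eval`: one-row tibble with `r2`, `rmse`,
#'   `n`, `r2_defined`.
#' @examples
#' eval_counts(pred = c(2, 2, 2), truth = c(1, 2, 3)) # rmse sqrt(2/3), r2 0
#' @export
eval_counts <- function(data = NULL, pred, truth) {
  if (is.data.frame(data)) {
    pred <- rlang::eval_tidy(rlang::enquo(pred), data)
    truth <- rlang::eval_tidy(rlang::enquo(truth), data)
  } else if (!is.null(data)) {
    # called positionally without a data frame: eval_counts(pred, truth)
    if (missing(pred)) {
      pred <- data
    } else if (missing(truth)) {
      truth <- pred
      pred <- data
    }
  }
  if (length(pred) != length(truth)) {
    abort("pred and truth must have equal length")
  }
  n <- length(pred)
  err2 <- sum((pred - truth)^2)
  rmse <- if (n > 0) sqrt(err2 / n) else NA_real_
  ss_tot <- sum((mean(truth) - truth)^2)
  r2_defined <- n >= 2 && ss_tot > 0
  r2 <- if (r2_defined) 1 - err2 / ss_tot else NA_real_
  if (!r2_defined && n >= 2) {
    warn("truth counts have zero variance; R^2 is undefined")
  }
  structure(tibble::tibble(r2 = r2, rmse = rmse, n = n,
                           r2_defined = r2_defined),
            class = c("count_eval", class(tibble::tibble())))
}

#' @describeIn eval_counts `glance()` returns the metrics tibble itself.
#' @param x A `count_eval` object.
#' @param ... Unused.
#' @method glance count_eval
#' @export
glance.count_eval <- function(x, ...) tibble::as_tibble(unclass(x))
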