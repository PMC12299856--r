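#' Greedy confidence-ordered matching of detections to ground truth
#'
#' Detections are ranked by descending confidence (ties keep input order)
#' and each is matched, within its image, to the still-unmatched ground
#' truth of highest IoU, provided that IoU reaches the threshold. Matching
#' is one-to-one: later (less confident) duplicates of an already-claimed
#' ground truth become false positives. IoU ties resolve to the
#' lowest-index ground truth.
#'
#' @param detections Tibble with columns `x1, y1, x2, y2, confidence` and
#'   optionally `image_id` (a single shared image is assumed when absent).
#' @param gt Tibble of ground-truth boxes with `x1, y1, x2, y2` and
#'   optionally `image_id`.
#' @param iou_threshold Minimum IoU for a match, in (0, 1).
#' @return The detections in ranked order with added columns `rank`, `tp`
#'   (logical) and `matched_gt` (row index into `gt`, `NA` for false
#'   positives).
#' @examples
#' det <- tibble::tibble(x1 = 0, y1 = 0, x2 = 2, y2 = 2, confidence = 0.9)
#' match_detections(det, boxes(0, 0, 2, 2), iou_threshold = 0.5)
#' @export
match_detections <- function(detections, gt, iou_threshold = 0.5) {
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  detections <- as_detection_table(detections, need_conf = TRUE)
  gt <- as_detection_table(gt, need_conf = FALSE)
  ord <- order(-detections$confidence)   # stable: confidence ties keep input order
  det <- detections[ord, ]
  det$rank <- seq_len(nrow(det))
  det$tp <- FALSE
  det$matched_gt <- NA_integer_
  if (nrow(det) == 0 || nrow(gt) == 0) return(det)
  claimed <- rep(FALSE, nrow(gt))
  for (i in seq_len(nrow(det))) {
    cand <- which(!claimed & gt$image_id == det$image_id[i])
    if (length(cand) == 0) next
    ious <- box_iou(det[i, c("x1", "y1", "x2", "y2")],
                    gt[cand, c("x1", "y1", "x2", "y2")])
    best <- which.max(ious)              # first max -> lowest GT index on ties
    if (ious[best] >= iou_threshold) {
      det$tp[i] <- TRUE
      det$matched_gt[i] <- cand[best]
      claimed[cand[best]] <- TRUE
    }
  }
  det
}

as_detection_table <- function(x, need_conf) {
  x <- tibble::as_tibble(x)
  validate_boxes(x, allow_degenerate = TRUE, arg = "box table")
  if (need_conf) {
    if (!"confidence" %in% names(x)) {
      stop("detections need a `confidence` column", call. = FALSE)
    }
    if (nrow(x) > 0 &&
        (!all(is.finite(x$confidence)) || any(x$confidence < 0 | x$confidence > 1))) {
      stop("confidence must be finite and in [0, 1]", call. = FALSE)
    }
  }
  if (!"image_id" %in% names(x)) x$image_id <- 1L
  x
}

#' Precision–recall curve and average precision from ranked TP/FP flags
#'
#' Given the true-positive flags of a confidence-ranked detection list and
#' the number of ground-truth objects, computes cumulative precision and
#' recall and the average precision as the area under the monotone
#' (non-increasing) precision envelope over recall — all-point
#' interpolation, the convention of modern detector evaluators. AP is 0
#' when there are no ground truths or no detections.
#'
#' @param tp Logical vector of per-detection true-positive flags, in rank
#'   order (most confident first).
#' @param n_gt Number of ground-truth objects.
#' @return A list with `curve` (tibble `rank, precision, recall`) and `ap`.
#' @examples
#' pr_curve_ap(c(TRUE, FALSE, TRUE), n_gt = 2)$ap  # 5/6
#' @export
pr_curve_ap <- function(tp, n_gt) {
  stopifnot(n_gt >= 0)
  tp <- as.logical(tp)
  n <- length(tp)
  if (n == 0 || n_gt == 0) {
    return(list(curve = tibble::tibble(rank = integer(), precision = numeric(),
                                       recall = numeric()),
                ap = 0))
  }
  ctp <- cumsum(tp)
  precision <- ctp / seq_len(n)
  recall <- ctp / n_gt
  env <- rev(cummax(rev(precision)))     # monotone envelope from the right
  ap <- sum(diff(c(0, recall)) * env)
  list(curve = tibble::tibble(rank = seq_len(n), precision = precision,
                              recall = recall),
       ap = ap)
}

#' Evaluate detections against ground truth across IoU thresholds
#'
#' Runs greedy matching and AP computation at each IoU threshold and
#' aggregates the detector-evaluation summaries: `map50` (AP at threshold
#' 0.50), `map50_90` (mean AP over the threshold set, by default 0.50 to
#' 0.90 in steps of 0.05), and precision/recall at the final operating
#' point of the ranking at threshold 0.50. With a single class, mAP equals
#' AP.
#'
#' @inheritParams match_detections
#' @param thresholds IoU thresholds; default `seq(0.5, 0.9, by = 0.05)`.
#'   Use `seq(0.5, 0.95, by = 0.05)` for the COCO convention.
#' @return An object of class `"detection_eval"`: a list with
#'   `per_threshold` (tibble `threshold, ap, n_tp, n_fp`), `curves` (list
#'   of PR tibbles keyed by threshold), `matches` (match table at the first
#'   threshold), `map50`, `map50_90`, `precision`, `recall`, `n_detections`,
#'   `n_gt` and `thresholds`.
#' @examples
#' gt <- boxes(c(0, 10), c(0, 10), c(4, 14), c(4, 14))
#' det <- dplyr::mutate(gt, confidence = c(0.9, 0.8))
#' glance(evaluate_detections(det, gt))
#' @export
evaluate_detections <- function(detections, gt,
                                thresholds = seq(0.5, 0.9, by = 0.05)) {
  detections <- as_detection_table(detections, need_conf = TRUE)
  gt <- as_detection_table(gt, need_conf = FALSE)
  n_gt <- nrow(gt)
  if (n_gt == 0 && nrow(detections) > 0) {
    warning("no ground-truth boxes: every detection is a false positive",
            call. = FALSE)
  }
  zero_pred <- nrow(detections) == 0
  per <- vector("list", length(thresholds))
  curves <- vector("list", length(thresholds))
  matches <- NULL
  for (ti in seq_along(thresholds)) {
    m <- match_detections(detections, gt, thresholds[ti])
    if (ti == 1) matches <- m
    pr <- pr_curve_ap(m$tp, n_gt)
    per[[ti]] <- tibble::tibble(threshold = thresholds[ti], ap = pr$ap,
                                n_tp = sum(m$tp), n_fp = sum(!m$tp))
    curves[[ti]] <- pr$curve
  }
  per <- dplyr::bind_rows(per)
  names(curves) <- format(thresholds)
  m50 <- match_detections(detections, gt, 0.5)
  precision <- if (zero_pred) 0 else sum(m50$tp) / nrow(m50)
  recall <- if (n_gt == 0) 0 else sum(m50$tp) / n_gt
  structure(list(
    per_threshold = per, curves = curves, matches = matches,
    map50 = per$ap[which.min(abs(per$threshold - 0.5))],
    map50_90 = mean(per$ap),
    precision = precision, recall = recall,
    no_predictions = zero_pred,
    n_detections = nrow(detections), n_gt = n_gt, thresholds = thresholds
  ), class = "detection_eval")
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf("<detection_eval> %d detections vs %d ground truths\n",
              x$n_detections, x$n_gt))
  cat(sprintf("  mAP@50 = %.4f   mAP@%d-%d = %.4f\n",
              x$map50, round(100 * min(x$thresholds)),
              round(100 * max(x$thresholds)), x$map50_90))
  cat(sprintf("  precision = %.4f   recall = %.4f  (IoU 0.50, full ranking)\n",
              x$precision, x$recall))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-threshold APs of a detection evaluation
#'
#' @param x A `detection_eval` object.
#' @param ... Unused.
#' @return Tibble with one row per IoU threshold.
#' @method tidy detection_eval
#' @export
tidy.detection_eval <- function(x, ...) {
  x$per_threshold
}

#' One-row summary of a detection evaluation
#'
#' @param x A `detection_eval` object.
#' @param ... Unused.
#' @return One-row tibble with `map50, map50_90, precision, recall,
#'   n_detections, n_gt`.
#' @method glance detection_eval
#' @export
glance.detection_eval <- function(x, ...) {
  tibble::tibble(map50 = x$map50, map50_90 = x$map50_90,
                 precision = x$precision, recall = x$recall,
                 n_detections = x$n_detections, n_gt = x$n_gt)
}

#' Plot precision–recall curves of a detection evaluation
#'
#' @param object A `detection_eval` object.
#' @param ... Unused.
#' @return A ggplot of the PR curve at each IoU threshold.
#' @method autoplot detection_eval
#' @export
autoplot.detection_eval <- function(object, ...) {
  df <- purrr::imap_dfr(object$curves,
                        ~ dplyr::mutate(.x, threshold = .y))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision,
                                   colour = .data$threshold)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision", colour = "IoU threshold",
                  title = "Precision-recall by IoU threshold") +
    ggplot2::theme_minimal()
}
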