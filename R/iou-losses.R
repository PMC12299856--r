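#' Configuration for IoU-based box losses
#'
#' @param variant One of `"eapiou"`, `"ciou"`, `"diou"`, `"giou"`, `"iou"`.
#' @param lambda Penalty coefficient weighting both aspect terms of the
#'   EAPIoU score (and, for the CIoU baseline in `fixed_lambda` mode, the
#'   arctangent term). Must lie in `[0, 1]`; default 0.1, the recommended
#'   setting.
#' @param eps Denominator guard: heights and `c^2` are floored at `eps`
#'   (additive only in the CIoU `alpha` denominator); keeps scores and
#'   gradients finite near degeneracy without disturbing exact scale
#'   invariance for valid boxes.
#' @param ciou_alpha_mode How the CIoU baseline weights its arctangent term:
#'   `"original_alpha"` (default) uses the adaptive trade-off
#'   `alpha = v / ((1 - IoU) + v)` of the original CIoU formulation;
#'   `"fixed_lambda"` uses the fixed coefficient `lambda` instead. Only the
#'   `ciou` variant consults this field — the EAPIoU score always uses the
#'   plain `lambda` weight.
#' @return A list of class `"loss_config"`.
#' @examples
#' loss_config("eapiou", lambda = 0.1)
#' @export
loss_config <- function(variant = c("eapiou", "ciou", "diou", "giou", "iou"),
                        lambda = 0.1, eps = 1e-7,
                        ciou_alpha_mode = c("original_alpha", "fixed_lambda")) {
  variant <- match.arg(variant)
  ciou_alpha_mode <- match.arg(ciou_alpha_mode)
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a single number in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0) {
    stop("eps must be a single positive number", call. = FALSE)
  }
  structure(list(variant = variant, lambda = lambda, eps = eps,
                 ciou_alpha_mode = ciou_alpha_mode),
            class = "loss_config")
}

#' @export
print.loss_config <- function(x, ...) {
  cat(sprintf("<loss_config> variant = %s, lambda = %g, eps = %g, ciou_alpha_mode = %s\n",
              x$variant, x$lambda, x$eps, x$ciou_alpha_mode))
  invisible(x)
}

#' Aspect-ratio terms of IoU-based losses
#'
#' `aspect_v()` is the arctangent angular term
#' `v = (4/pi^2) (atan(w_gt/h_gt) - atan(w/h))^2`, bounded in `[0, 1]`, used
#' by CIoU. `aspect_penalty()` is the explicit squared ratio difference
#' `(w1/h1 - w2/h2)^2` that the EAPIoU score adds; unlike `v` it is
#' unbounded and keeps a large gradient when the ratios diverge, which is
#' what makes the penalty responsive for strongly elongated boxes.
#'
#' @param pred,gt Box tibbles (row-wise pairs; single rows recycle).
#' @param eps Guard added to heights before forming ratios.
#' @return Numeric vector (per pair). Both terms are symmetric in their
#'   arguments.
#' @examples
#' aspect_v(boxes(0, 0, 1, 1), boxes(0, 0, 2, 1))        # ~0.0420
#' aspect_penalty(boxes(0, 0, 4, 1), boxes(0, 0, 1, 4))  # 14.0625
#' @export
aspect_v <- function(pred, gt, eps = 1e-7) {
  pair_geometry(pred, gt, eps = eps)$v
}

#' @rdname aspect_v
#' @export
aspect_penalty <- function(pred, gt, eps = 1e-7) {
  pair_geometry(pred, gt, eps = eps)$aspect_sq
}

#' Penalized IoU scores and losses for box pairs
#'
#' Computes, row-wise over pairs of boxes, the score of the configured IoU
#' variant and the associated regression loss `1 - score`. The EAPIoU score
#' is
#' \deqn{\mathrm{EAPIoU} = \mathrm{IoU} - \rho^2/c^2 - \lambda v -
#'   \lambda (w_1/h_1 - w_2/h_2)^2,}
#' where `rho^2` is the squared center distance, `c^2` the squared diagonal
#' of the smallest enclosing box, `v` the arctangent aspect term and the
#' final term the explicit squared aspect-ratio penalty. Baselines: `iou`
#' (plain IoU), `giou` (IoU minus the enclosing-box gap), `diou` (IoU minus
#' `rho^2/c^2`), `ciou` (DIoU minus a weighted `v`).
#'
#' The returned terms are each on their raw scale; for every variant
#' `score = iou - distance_term - v_weight * v_term -
#' aspect_weight * aspect_term` (with `distance_term` holding the enclosing-box gap
#' for `giou`, and weights zero for terms a variant does not use).
#'
#' @param pred,gt Box tibbles (predicted and ground-truth; single rows
#'   recycle).
#' @param config A [loss_config()].
#' @return A tibble with columns `variant, lambda, iou, distance_term,
#'   v_term, aspect_term, v_weight, aspect_weight, score, loss`.
#' @examples
#' box_loss(boxes(-1, -1, 1, 1), boxes(-2, -2, 2, 2),
#'          loss_config("eapiou", lambda = 0.1))
#' @export
box_loss <- function(pred, gt, config = loss_config()) {
  stopifnot(inherits(config, "loss_config"))
  g <- pair_geometry(pred, gt, eps = config$eps)
  dist <- g$rho_sq / pmax(g$c_sq, config$eps)
  v_w <- rep(0, nrow(g)); a_w <- rep(0, nrow(g)); dterm <- rep(0, nrow(g))
  if (config$variant == "iou") {
    # nothing beyond IoU
  } else if (config$variant == "giou") {
    dterm <- giou_gap(pred, gt, eps = config$eps)
  } else if (config$variant == "diou") {
    dterm <- dist
  } else if (config$variant == "ciou") {
    dterm <- dist
    v_w <- if (config$ciou_alpha_mode == "original_alpha") {
      g$v / ((1 - g$iou) + g$v + config$eps)
    } else {
      rep(config$lambda, nrow(g))
    }
  } else if (config$variant == "eapiou") {
    dterm <- dist
    v_w <- rep(config$lambda, nrow(g))
    a_w <- rep(config$lambda, nrow(g))
  }
  score <- g$iou - dterm - v_w * g$v - a_w * g$aspect_sq
  tibble::tibble(
    variant = config$variant, lambda = config$lambda,
    iou = g$iou, distance_term = dterm, v_term = g$v,
    aspect_term = g$aspect_sq, v_weight = v_w, aspect_weight = a_w,
    score = score, loss = 1 - score
  )
}

# Enclosing-box gap (|C| - |union|) / |C| used by GIoU.
giou_gap <- function(pred, gt, eps = 1e-7) {
  p <- align_pair(pred, gt)
  iw <- pmax(0, pmin(p$ax2, p$bx2) - pmax(p$ax1, p$bx1))
  ih <- pmax(0, pmin(p$ay2, p$by2) - pmax(p$ay1, p$by1))
  un <- (p$ax2 - p$ax1) * (p$ay2 - p$ay1) +
    (p$bx2 - p$bx1) * (p$by2 - p$by1) - iw * ih
  cenc <- (pmax(p$ax2, p$bx2) - pmin(p$ax1, p$bx1)) *
    (pmax(p$ay2, p$by2) - pmin(p$ay1, p$by1))
  (cenc - un) / pmax(cenc, eps)
}

#' EAPIoU score of box pairs
#'
#' Convenience wrapper around [box_loss()] with `variant = "eapiou"`.
#'
#' @inheritParams box_loss
#' @param lambda,eps See [loss_config()].
#' @return See [box_loss()].
#' @examples
#' eapiou_score(boxes(0, 0, 4, 1), boxes(0, 0, 1, 4), lambda = 0.1)$score
#' @export
eapiou_score <- function(pred, gt, lambda = 0.1, eps = 1e-7) {
  box_loss(pred, gt, loss_config("eapiou", lambda = lambda, eps = eps))
}
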