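#' Loss value and analytic gradient for one predicted box
#'
#' Evaluates `loss = 1 - score` for the configured IoU variant together with
#' its exact analytic gradient with respect to the predicted box parameters,
#' for use in gradient-based box-regression simulation. Two
#' parameterizations are supported:
#'
#' * `"corner"` — `pred_params = (x1, y1, x2, y2)`;
#' * `"center_log"` — `pred_params = (cx, cy, log w, log h)`, which keeps
#'   width and height positive without constraints.
#'
#' Gradients are assembled by the chain rule over the closed-form terms. The
#' arctangent term `v` is differentiated exactly (no dropped factors), and
#' the CIoU baseline's adaptive weight `alpha = v / ((1 - IoU) + v)` is
#' differentiated through. The IoU term is piecewise smooth; at the optimum
#' (prediction identical to the target) its subgradient is taken as 0, so
#' the whole gradient vanishes there. For disjoint boxes the IoU term has
#' zero gradient and the center-distance term supplies the pull toward the
#' target.
#'
#' @param pred_params Numeric length-4 vector of predicted-box parameters.
#' @param gt Single-row box tibble (ground truth).
#' @param config A [loss_config()].
#' @param parameterization `"corner"` or `"center_log"`.
#' @return A list with elements `loss`, `gradient` (length 4), `score` and
#'   `iou`.
#' @examples
#' loss_and_grad(c(0, 0, 2, 2), boxes(1, 1, 3, 3), loss_config("eapiou"))
#' @export
loss_and_grad <- function(pred_params, gt,
                          config = loss_config(),
                          parameterization = c("corner", "center_log")) {
  parameterization <- match.arg(parameterization)
  stopifnot(is.numeric(pred_params), length(pred_params) == 4,
            all(is.finite(pred_params)), inherits(config, "loss_config"))
  validate_boxes(gt, allow_degenerate = TRUE, arg = "gt")
  if (nrow(gt) != 1) stop("gt must have exactly one row", call. = FALSE)

  if (parameterization == "center_log") {
    cx <- pred_params[1]; cy <- pred_params[2]
    w <- exp(pred_params[3]); h <- exp(pred_params[4])
    corners <- c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
  } else {
    corners <- pred_params
    if (corners[3] <= corners[1] || corners[4] <= corners[2]) {
      stop("predicted box is degenerate in corner parameterization",
           call. = FALSE)
    }
  }

  cg <- corner_score_grad(corners, c(gt$x1, gt$y1, gt$x2, gt$y2), config)

  grad_score <- cg$grad
  if (parameterization == "center_log") {
    w <- corners[3] - corners[1]; h <- corners[4] - corners[2]
    grad_score <- c(
      grad_score[1] + grad_score[3],
      grad_score[2] + grad_score[4],
      (w / 2) * (grad_score[3] - grad_score[1]),
      (h / 2) * (grad_score[4] - grad_score[2])
    )
  }
  list(loss = 1 - cg$score, gradient = -grad_score,
       score = cg$score, iou = cg$iou)
}

# Indicator with symmetric subgradient at ties: 1 for TRUE, 0 for FALSE,
# 0.5 where the two coordinates coincide (to within a 1e-9 relative band —
# parameter round trips land within a few ulp of exact ties). The min/max
# terms of the intersection and enclosing box are kinked at ties; taking
# the average of the two one-sided derivatives matches the central finite
# difference and keeps gradient descent from stalling on a coordinate that
# has already snapped onto the target.
tie_band <- function(a, b) abs(a - b) <= 1e-9 * max(1, abs(a), abs(b))
ind_gt <- function(a, b) if (tie_band(a, b)) 0.5 else as.numeric(a > b)
ind_lt <- function(a, b) if (tie_band(a, b)) 0.5 else as.numeric(a < b)

# Score and d(score)/d(x1,y1,x2,y2) for a single pair; gt held fixed.
corner_score_grad <- function(p, q, config) {
  eps <- config$eps
  x1 <- p[1]; y1 <- p[2]; x2 <- p[3]; y2 <- p[4]
  X1 <- q[1]; Y1 <- q[2]; X2 <- q[3]; Y2 <- q[4]
  w <- x2 - x1; h <- y2 - y1; W <- X2 - X1; H <- Y2 - Y1
  identical_pair <- all(mapply(tie_band, p, q))

  # --- IoU and gradient -----------------------------------------------
  iw <- min(x2, X2) - max(x1, X1)
  ih <- min(y2, Y2) - max(y1, Y1)
  inter <- max(iw, 0) * max(ih, 0)
  un <- w * h + W * H - inter
  iou <- if (un > 0) inter / un else 0
  if (identical_pair) {
    g_iou <- numeric(4)  # subgradient at the kink chosen as 0
  } else {
    d_iw <- c(-ind_gt(x1, X1), 0, ind_lt(x2, X2), 0)
    d_ih <- c(0, -ind_gt(y1, Y1), 0, ind_lt(y2, Y2))
    g_inter <- if (iw > 0 && ih > 0) ih * d_iw + iw * d_ih else numeric(4)
    g_area <- c(-h, -w, h, w)
    g_un <- g_area - g_inter
    g_iou <- if (un > 0) (g_inter * un - inter * g_un) / un^2 else numeric(4)
  }

  # --- center-distance term rho^2 / c^2 -------------------------------
  dx <- (x1 + x2) / 2 - (X1 + X2) / 2
  dy <- (y1 + y2) / 2 - (Y1 + Y2) / 2
  rho_sq <- dx * dx + dy * dy
  g_rho <- c(dx, dy, dx, dy)
  cw <- max(x2, X2) - min(x1, X1)
  ch <- max(y2, Y2) - min(y1, Y1)
  c_sq <- max(cw * cw + ch * ch, eps)
  g_cw <- c(-ind_lt(x1, X1), 0, ind_gt(x2, X2), 0)
  g_ch <- c(0, -ind_lt(y1, Y1), 0, ind_gt(y2, Y2))
  # the floor is flat: no denominator gradient below eps
  g_csq <- if (cw * cw + ch * ch >= eps) 2 * cw * g_cw + 2 * ch * g_ch
           else numeric(4)
  dist <- rho_sq / c_sq
  g_dist <- (g_rho * c_sq - rho_sq * g_csq) / c_sq^2

  # --- aspect terms ----------------------------------------------------
  he <- max(h, eps)
  r <- w / he
  rg <- W / max(H, eps)
  qv <- atan(rg) - atan(r)
  v <- (4 / pi^2) * qv * qv
  dv_dr <- -(8 / pi^2) * qv / (1 + r * r)
  dh_active <- as.numeric(h >= eps)
  g_r <- c(-1 / he, dh_active * w / he^2, 1 / he, -dh_active * w / he^2)
  g_v <- dv_dr * g_r
  asp <- (r - rg)^2
  g_asp <- 2 * (r - rg) * g_r

  variant <- config$variant
  if (variant == "iou") {
    score <- iou; g <- g_iou
  } else if (variant == "giou") {
    cenc <- max(cw * ch, eps)
    g_cenc <- if (cw * ch >= eps) ch * g_cw + cw * g_ch else numeric(4)
    gap <- (cenc - un) / cenc
    g_area <- c(-h, -w, h, w)
    g_inter2 <- if (identical_pair || iw <= 0 || ih <= 0) numeric(4) else {
      ih * c(-ind_gt(x1, X1), 0, ind_lt(x2, X2), 0) +
        iw * c(0, -ind_gt(y1, Y1), 0, ind_lt(y2, Y2))
    }
    g_un <- g_area - g_inter2
    g_gap <- -(g_un * cenc - un * g_cenc) / cenc^2
    score <- iou - gap; g <- g_iou - g_gap
  } else if (variant == "diou") {
    score <- iou - dist; g <- g_iou - g_dist
  } else if (variant == "ciou") {
    if (config$ciou_alpha_mode == "original_alpha") {
      den <- (1 - iou) + v + eps
      alpha <- v / den
      g_alpha <- (g_v * (1 - iou + eps) + v * g_iou) / den^2
      score <- iou - dist - alpha * v
      g <- g_iou - g_dist - (g_alpha * v + alpha * g_v)
    } else {
      score <- iou - dist - config$lambda * v
      g <- g_iou - g_dist - config$lambda * g_v
    }
  } else {  # eapiou
    lam <- config$lambda
    score <- iou - dist - lam * v - lam * asp
    g <- g_iou - g_dist - lam * g_v - lam * g_asp
  }

  check_finite_grad(list(iou = g_iou, distance = g_dist, v = g_v,
                         aspect = g_asp, total = g))
  list(score = score, grad = g, iou = iou)
}

check_finite_grad <- function(parts) {
  for (nm in names(parts)) {
    if (!all(is.finite(parts[[nm]]))) {
      stop(sprintf("non-finite gradient in the %s term", nm), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Batch losses for matrices of box corners
#'
#' Vectorized entry point used by the regression simulator and the
#' evaluation code: takes `n x 4` matrices of predicted and ground-truth
#' corners and returns the per-pair scores and losses of the configured
#' variant.
#'
#' @param pred,gt Numeric `n x 4` matrices of `(x1, y1, x2, y2)` corners
#'   (rows recycle if one input has a single row).
#' @param config A [loss_config()].
#' @return See [box_loss()].
#' @export
box_loss_matrix <- function(pred, gt, config = loss_config()) {
  pred <- matrix(as.numeric(pred), ncol = 4)
  gt <- matrix(as.numeric(gt), ncol = 4)
  box_loss(
    tibble::tibble(x1 = pred[, 1], y1 = pred[, 2], x2 = pred[, 3], y2 = pred[, 4]),
    tibble::tibble(x1 = gt[, 1], y1 = gt[, 2], x2 = gt[, 3], y2 = gt[, 4]),
    config
  )
}
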