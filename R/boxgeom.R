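#' Construct a tibble of axis-aligned boxes
#'
#' Boxes are axis-aligned rectangles in corner format `(x1, y1, x2, y2)` with
#' continuous real coordinates; `x` grows to the right and `y` grows downward
#' (image convention). All geometry in this package is vectorized over the
#' rows of such tibbles.
#'
#' @param x1,y1,x2,y2 Numeric vectors of corner coordinates (recycled to a
#'   common length). `x2 >= x1` and `y2 >= y1` are required unless
#'   `allow_degenerate = TRUE` permits zero width/height (never negative).
#' @param allow_degenerate Allow zero-width or zero-height boxes.
#' @return A tibble with columns `x1, y1, x2, y2`.
#' @examples
#' boxes(0, 0, c(1, 2), c(1, 3))
#' @export
boxes <- function(x1, y1, x2, y2, allow_degenerate = FALSE) {
  b <- tibble::tibble(x1 = as.numeric(x1), y1 = as.numeric(y1),
                      x2 = as.numeric(x2), y2 = as.numeric(y2))
  validate_boxes(b, allow_degenerate = allow_degenerate)
  b
}

validate_boxes <- function(b, allow_degenerate = FALSE, arg = "boxes") {
  need <- c("x1", "y1", "x2", "y2")
  miss <- setdiff(need, names(b))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing column(s): %s", arg, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  vals <- as.matrix(b[need])
  if (!all(is.finite(vals))) {
    stop(sprintf("%s contains non-finite coordinates", arg), call. = FALSE)
  }
  w <- b$x2 - b$x1
  h <- b$y2 - b$y1
  if (any(w < 0) || any(h < 0)) {
    stop(sprintf("%s has x2 < x1 or y2 < y1", arg), call. = FALSE)
  }
  if (!allow_degenerate && (any(w == 0) || any(h == 0))) {
    stop(sprintf("%s contains degenerate (zero width/height) boxes", arg),
         call. = FALSE)
  }
  invisible(b)
}

# Align two box tables to a common number of rows (recycling singletons),
# returning a list of plain numeric vectors for fast arithmetic.
align_pair <- function(a, b) {
  validate_boxes(a, allow_degenerate = TRUE, arg = "first box set")
  validate_boxes(b, allow_degenerate = TRUE, arg = "second box set")
  na <- nrow(a); nb <- nrow(b)
  if (na != nb) {
    if (na == 1) a <- a[rep(1L, nb), ] else if (nb == 1) b <- b[rep(1L, na), ]
    else stop("box sets have incompatible row counts (", na, " vs ", nb, ")",
              call. = FALSE)
  }
  list(ax1 = a$x1, ay1 = a$y1, ax2 = a$x2, ay2 = a$y2,
       bx1 = b$x1, by1 = b$y1, bx2 = b$x2, by2 = b$y2)
}

#' Box areas, widths, heights and centers
#'
#' @param b A box tibble (see [boxes()]).
#' @return `box_area()` returns a numeric vector of areas (0 for degenerate
#'   boxes). `box_center()` returns a tibble with columns `cx, cy`.
#' @examples
#' box_area(boxes(0, 0, 2, 3))     # 6
#' box_center(boxes(0, 0, 4, 1))   # (2, 0.5)
#' @export
box_area <- function(b) {
  validate_boxes(b, allow_degenerate = TRUE)
  (b$x2 - b$x1) * (b$y2 - b$y1)
}

#' @rdname box_area
#' @export
box_center <- function(b) {
  validate_boxes(b, allow_degenerate = TRUE)
  tibble::tibble(cx = (b$x1 + b$x2) / 2, cy = (b$y1 + b$y2) / 2)
}

#' Intersection over union of box pairs
#'
#' Computes IoU row-wise between two box tibbles (either may have a single
#' row, which is recycled). A pair in which both boxes are degenerate (zero
#' area) has IoU 0 and raises a warning.
#'
#' @param a,b Box tibbles.
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @examples
#' box_iou(boxes(0, 0, 2, 2), boxes(1, 1, 3, 3))  # 1/7
#' @export
box_iou <- function(a, b) {
  p <- align_pair(a, b)
  iw <- pmax(0, pmin(p$ax2, p$bx2) - pmax(p$ax1, p$bx1))
  ih <- pmax(0, pmin(p$ay2, p$by2) - pmax(p$ay1, p$by1))
  inter <- iw * ih
  area_a <- (p$ax2 - p$ax1) * (p$ay2 - p$ay1)
  area_b <- (p$bx2 - p$bx1) * (p$by2 - p$by1)
  un <- area_a + area_b - inter
  both_degen <- area_a == 0 & area_b == 0
  if (any(both_degen)) {
    warning("IoU of a pair of degenerate (zero-area) boxes is defined as 0",
            call. = FALSE)
  }
  ifelse(un > 0, inter / un, 0)
}

#' Squared center distance and squared enclosing-box diagonal
#'
#' `box_center_distance_sq()` is the squared Euclidean distance between box
#' centers. `box_enclosing_diagonal_sq()` is `cw^2 + ch^2` of the smallest
#' axis-aligned box covering both; it errors when both boxes collapse to one
#' identical point (a degenerate pair, for which no penalty is defined).
#'
#' @inheritParams box_iou
#' @return Numeric vector.
#' @examples
#' box_center_distance_sq(boxes(0, 0, 2, 2), boxes(1, 1, 3, 3))    # 2
#' box_enclosing_diagonal_sq(boxes(0, 0, 2, 2), boxes(1, 1, 3, 3)) # 18
#' @export
box_center_distance_sq <- function(a, b) {
  p <- align_pair(a, b)
  dx <- (p$ax1 + p$ax2) / 2 - (p$bx1 + p$bx2) / 2
  dy <- (p$ay1 + p$ay2) / 2 - (p$by1 + p$by2) / 2
  dx * dx + dy * dy
}

#' @rdname box_center_distance_sq
#' @export
box_enclosing_diagonal_sq <- function(a, b) {
  p <- align_pair(a, b)
  cw <- pmax(p$ax2, p$bx2) - pmin(p$ax1, p$bx1)
  ch <- pmax(p$ay2, p$by2) - pmin(p$ay1, p$by1)
  c_sq <- cw * cw + ch * ch
  if (any(c_sq == 0)) {
    stop("degenerate pair: both boxes collapse to one identical point",
         call. = FALSE)
  }
  c_sq
}

#' All pairwise geometric quantities used by IoU-based losses
#'
#' For each pair of boxes, computes the IoU, the squared center distance
#' `rho_sq`, the squared enclosing-box diagonal `c_sq`, the width/height
#' ratios `r1` (first set) and `r2` (second set), the arctangent aspect term
#' `v = (4/pi^2) (atan(r2) - atan(r1))^2` and the squared ratio difference
#' `aspect_sq = (r1 - r2)^2`. Ratio denominators floor the heights at `eps`
#' so degenerate boxes yield finite values; non-degenerate boxes are
#' unaffected, which preserves exact scale invariance.
#'
#' Every field is symmetric under swapping the two sets except `r1`/`r2`,
#' which swap with them.
#'
#' @inheritParams box_iou
#' @param eps Floor applied to heights in ratio denominators.
#' @return A tibble with columns
#'   `iou, rho_sq, c_sq, r1, r2, v, aspect_sq`.
#' @examples
#' pair_geometry(boxes(0, 0, 2, 2), boxes(1, 1, 3, 3))
#' @export
pair_geometry <- function(a, b, eps = 1e-7) {
  p <- align_pair(a, b)
  r1 <- (p$ax2 - p$ax1) / pmax(p$ay2 - p$ay1, eps)
  r2 <- (p$bx2 - p$bx1) / pmax(p$by2 - p$by1, eps)
  d_atan <- atan(r2) - atan(r1)
  tibble::tibble(
    iou = box_iou(a, b),
    rho_sq = box_center_distance_sq(a, b),
    c_sq = box_enclosing_diagonal_sq(a, b),
    r1 = r1,
    r2 = r2,
    v = (4 / pi^2) * d_atan * d_atan,
    aspect_sq = (r1 - r2)^2
  )
}

#' Rasterized IoU oracle
#'
#' Estimates the IoU of two boxes by counting pixel-center membership on a
#' `grid x grid` lattice laid over their smallest enclosing box. Because
#' membership of an axis-aligned box factorizes over the two axes, the 2-D
#' count is taken as a product of 1-D counts; the result is identical to
#' classifying every lattice point individually. Converges to [box_iou()] as
#' `grid` grows; intended as an independent check, not for production use.
#'
#' @param a,b Single-row box tibbles.
#' @param grid Number of samples per axis (>= 10).
#' @return A single IoU estimate in `[0, 1]`.
#' @examples
#' rasterized_iou(boxes(0, 0, 2, 2), boxes(1, 1, 3, 3), grid = 200)
#' @export
rasterized_iou <- function(a, b, grid = 1000) {
  stopifnot(nrow(a) == 1, nrow(b) == 1, grid >= 10)
  validate_boxes(a, allow_degenerate = TRUE)
  validate_boxes(b, allow_degenerate = TRUE)
  ex1 <- min(a$x1, b$x1); ex2 <- max(a$x2, b$x2)
  ey1 <- min(a$y1, b$y1); ey2 <- max(a$y2, b$y2)
  if (ex2 <= ex1 || ey2 <= ey1) return(0)
  xs <- ex1 + (seq_len(grid) - 0.5) * (ex2 - ex1) / grid
  ys <- ey1 + (seq_len(grid) - 0.5) * (ey2 - ey1) / grid
  in_ax <- xs >= a$x1 & xs <= a$x2; in_ay <- ys >= a$y1 & ys <= a$y2
  in_bx <- xs >= b$x1 & xs <= b$x2; in_by <- ys >= b$y1 & ys <= b$y2
  n_a <- sum(in_ax) * sum(in_ay)
  n_b <- sum(in_bx) * sum(in_by)
  n_ab <- sum(in_ax & in_bx) * sum(in_ay & in_by)
  n_union <- n_a + n_b - n_ab
  if (n_union == 0) return(0)
  n_ab / n_union
}
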