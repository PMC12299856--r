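#' Sample box pairs with controlled overlap and aspect-ratio mismatch
#'
#' Generates `n` (box, box) pairs whose measured IoU lies in `iou_range`
#' and whose width/height-ratio quotient `r1/r2` lies in
#' `ratio_mismatch_range`, by constructing a jittered partner for a random
#' base box and rejection-sampling until both measurements (taken with the
#' package's own geometry) fall inside the requested ranges. Deterministic
#' per seed; the generator re-measures and self-validates every pair it
#' returns.
#'
#' @param n Number of pairs.
#' @param iou_range Length-2 inclusive IoU range within `[0, 1]`. The exact
#'   range `c(1, 1)` yields identical boxes.
#' @param ratio_mismatch_range Length-2 inclusive range for the ratio
#'   quotient `r1/r2`.
#' @param seed Optional integer seed.
#' @param max_tries Rejection-sampling budget per pair.
#' @return A tibble with columns `pair_id`, first-box corners
#'   `x1, y1, x2, y2`, second-box corners `gt_x1, gt_y1, gt_x2, gt_y2`, and
#'   the measured `iou` and `ratio_quotient`.
#' @examples
#' sample_box_pairs(3, iou_range = c(0.2, 0.8), seed = 1)
#' @export
sample_box_pairs <- function(n, iou_range = c(0, 1),
                             ratio_mismatch_range = c(1 / 4, 4),
                             seed = NULL, max_tries = 2000) {
  stopifnot(n >= 1, length(iou_range) == 2, iou_range[1] <= iou_range[2],
            iou_range[1] >= 0, iou_range[2] <= 1,
            length(ratio_mismatch_range) == 2,
            ratio_mismatch_range[1] > 0,
            ratio_mismatch_range[1] <= ratio_mismatch_range[2])
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    got <- FALSE
    for (try in seq_len(max_tries)) {
      base <- random_box()
      if (iou_range[1] >= 1) {
        partner <- base
      } else {
        partner <- jitter_partner(base, ratio_mismatch_range, iou_range)
      }
      a <- tibble::tibble(x1 = base[1], y1 = base[2], x2 = base[3], y2 = base[4])
      b <- tibble::tibble(x1 = partner[1], y1 = partner[2],
                          x2 = partner[3], y2 = partner[4])
      g <- pair_geometry(a, b)
      q <- g$r1 / g$r2
      if (g$iou >= iou_range[1] && g$iou <= iou_range[2] &&
          q >= ratio_mismatch_range[1] && q <= ratio_mismatch_range[2]) {
        out[[i]] <- tibble::tibble(pair_id = i,
                                   x1 = base[1], y1 = base[2],
                                   x2 = base[3], y2 = base[4],
                                   gt_x1 = partner[1], gt_y1 = partner[2],
                                   gt_x2 = partner[3], gt_y2 = partner[4],
                                   iou = g$iou, ratio_quotient = q)
        got <- TRUE
        break
      }
    }
    if (!got) {
      stop(sprintf(paste0("sample_box_pairs: could not satisfy iou_range [%g, %g] ",
                          "and ratio range [%g, %g] after %d tries ",
                          "(achieved %d / %d pairs)"),
                   iou_range[1], iou_range[2], ratio_mismatch_range[1],
                   ratio_mismatch_range[2], max_tries, i - 1L, n),
           call. = FALSE)
    }
  }
  dplyr::bind_rows(out)
}

random_box <- function() {
  ratio <- exp(stats::runif(1, log(1 / 3), log(3)))
  size <- exp(stats::runif(1, log(0.5), log(2)))
  w <- size * sqrt(ratio); h <- size / sqrt(ratio)
  cx <- stats::runif(1, 2, 8); cy <- stats::runif(1, 2, 8)
  c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

jitter_partner <- function(base, ratio_mismatch_range, iou_range) {
  w <- base[3] - base[1]; h <- base[4] - base[2]
  cx <- (base[1] + base[3]) / 2; cy <- (base[2] + base[4]) / 2
  # base ratio divided by quotient, so r1/r2 lands near the sampled value
  q <- exp(stats::runif(1, log(ratio_mismatch_range[1]),
                        log(ratio_mismatch_range[2])))
  sc <- exp(stats::runif(1, log(0.7), log(1.4)))
  # heavier center jitter when low IoU is acceptable
  reach <- if (iou_range[1] == 0) 1.5 else 0.9
  ang <- stats::runif(1, 0, 2 * pi)
  rad <- stats::runif(1, 0, reach) * sqrt(w^2 + h^2) / 2
  w2 <- w * sc / sqrt(q); h2 <- h * sc * sqrt(q)
  cx2 <- cx + rad * cos(ang); cy2 <- cy + rad * sin(ang)
  c(cx2 - w2 / 2, cy2 - h2 / 2, cx2 + w2 / 2, cy2 + h2 / 2)
}

#' Generate a random dense feature map
#'
#' @param B,C,H,W Array dimensions (batch, channels, height, width).
#' @param distribution `"normal"` (standard), `"uniform"` (on `[0, 1]`) or
#'   `"constant"`.
#' @param value Fill value for `distribution = "constant"`.
#' @param seed Optional integer seed.
#' @return A `B x C x H x W` array.
#' @examples
#' dim(gen_feature_map(2, 3, 4, 4, seed = 1))
#' @export
gen_feature_map <- function(B, C, H, W,
                            distribution = c("normal", "uniform", "constant"),
                            value = 0, seed = NULL) {
  distribution <- match.arg(distribution)
  stopifnot(B >= 1, C >= 1, H >= 1, W >= 1)
  if (!is.null(seed)) set.seed(seed)
  ntot <- B * C * H * W
  vals <- switch(distribution,
                 normal = stats::rnorm(ntot),
                 uniform = stats::runif(ntot),
                 constant = rep(as.numeric(value), ntot))
  array(vals, dim = c(B, C, H, W))
}

#' Generate a CT-slice-like scene of bright elliptical nodules
#'
#' Emulates the statistical structure of a single-class nodule-detection
#' dataset: a noisy background with a handful of small bright blobs, each
#' annotated with a tight axis-aligned box. Nodules are anti-aliased filled
#' ellipses whose edges are softened by a Gaussian blur; this is a
#' statistical stand-in for exercising losses, metrics and attention, not a
#' physical CT simulator.
#'
#' @param n_nodules Number of nodules to place (0 gives pure noise).
#' @param image_size Length-1 or -2 integer, image height/width in pixels
#'   (default 320).
#' @param radius_range Nodule radius range in pixels (default `c(4, 16)`,
#'   minimum 2).
#' @param ellipticity_range Range of the axis ratio `a/b` of the ellipse
#'   (default `c(0.75, 1.33)`); `c(1, 1)` gives circles.
#' @param contrast Required excess of mean nodule-core intensity over the
#'   local background (default 0.5, on the `[0, 1]` intensity scale).
#' @param noise_sd Standard deviation of the Gaussian background noise
#'   (default 0.05) around the background level 0.2.
#' @param blur_sigma Gaussian edge-blur in pixels (default 1).
#' @param seed Optional integer seed; identical parameters and seed
#'   regenerate the identical image.
#' @param max_attempts Placement attempts per nodule before erroring.
#' @return A list of class `"nodule_scene"`: `image` (`H x W` matrix in
#'   `[0, 1]`), `gt_boxes` (tibble of tight boxes `x1, y1, x2, y2`, in
#'   pixel coordinates, all inside the image), and `params`.
#' @examples
#' sc <- gen_nodule_scene(n_nodules = 2, image_size = 96, seed = 3)
#' sc$gt_boxes
#' @export
gen_nodule_scene <- function(n_nodules = 5, image_size = 320,
                             radius_range = c(4, 16),
                             ellipticity_range = c(0.75, 1.33),
                             contrast = 0.5, noise_sd = 0.05,
                             blur_sigma = 1, seed = NULL,
                             max_attempts = 200) {
  stopifnot(n_nodules >= 0, radius_range[1] >= 2,
            radius_range[1] <= radius_range[2],
            ellipticity_range[1] > 0,
            ellipticity_range[1] <= ellipticity_range[2],
            contrast > 0, noise_sd >= 0)
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  H <- image_size[1]; W <- image_size[2]
  if (!is.null(seed)) set.seed(seed)
  background_level <- 0.2
  img <- matrix(stats::rnorm(H * W, background_level, noise_sd), H, W)

  placed <- list()
  layer <- matrix(0, H, W)
  for (i in seq_len(n_nodules)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      r <- stats::runif(1, radius_range[1], radius_range[2])
      e <- exp(stats::runif(1, log(ellipticity_range[1]),
                            log(ellipticity_range[2])))
      a <- r * sqrt(e); b <- r / sqrt(e)
      cx <- stats::runif(1, a + 1, W - a - 1)
      cy <- stats::runif(1, b + 1, H - b - 1)
      box <- tibble::tibble(x1 = cx - a, y1 = cy - b, x2 = cx + a, y2 = cy + b)
      overlaps <- length(placed) > 0 &&
        any(box_iou(box, dplyr::bind_rows(lapply(placed, `[[`, "box"))) > 0)
      if (!overlaps) {
        placed[[i]] <- list(cx = cx, cy = cy, a = a, b = b, box = box)
        layer <- layer + render_ellipse(H, W, cx, cy, a, b)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf("could not place nodule %d without overlap after %d attempts",
                   i, max_attempts), call. = FALSE)
    }
  }
  if (blur_sigma > 0 && length(placed) > 0) {
    layer <- gaussian_blur(layer, blur_sigma)
  }
  # self-calibrated amplitude: measure each nodule's core-vs-ring contrast
  # on the unit-amplitude layer and scale so the worst one still clears the
  # nominal contrast with headroom for the background noise
  if (length(placed) > 0) {
    unit_gap <- vapply(placed, function(nod) {
      d <- nodule_distance_map(H, W, nod)
      mean(layer[d <= 0.6]) - mean(layer[d >= 1.5 & d <= 2.5])
    }, numeric(1))
    amp <- (contrast + 0.05) / min(unit_gap)
    img <- img + amp * layer
  }
  img[] <- pmin(1, pmax(0, img))

  gt_boxes <- if (length(placed) > 0) {
    dplyr::bind_rows(lapply(placed, `[[`, "box"))
  } else {
    tibble::tibble(x1 = numeric(), y1 = numeric(),
                   x2 = numeric(), y2 = numeric())
  }
  scene <- structure(list(
    image = img, gt_boxes = gt_boxes,
    params = list(n_nodules = n_nodules, image_size = c(H, W),
                  radius_range = radius_range,
                  ellipticity_range = ellipticity_range,
                  contrast = contrast, noise_sd = noise_sd,
                  blur_sigma = blur_sigma, seed = seed,
                  background_level = background_level),
    nodules = placed
  ), class = "nodule_scene")
  validate_scene(scene)
  scene
}

# Anti-aliased filled ellipse on the pixel grid (pixel centers at 0.5 steps);
# alpha falls from 1 to 0 over ~1 px around the boundary.
render_ellipse <- function(H, W, cx, cy, a, b) {
  xs <- seq_len(W) - 0.5
  ys <- seq_len(H) - 0.5
  dx2 <- ((xs - cx) / a)^2
  dy2 <- ((ys - cy) / b)^2
  d <- sqrt(outer(dy2, dx2, "+"))          # H x W normalized radial distance
  px_scale <- min(a, b)                    # ~signed distance in pixels
  matrix(pmin(1, pmax(0, (1 - d) * px_scale + 0.5)), H, W)
}

# Separable Gaussian blur with reflected edges.
gaussian_blur <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  blur_1d <- function(x) {
    n <- length(x)
    idx <- outer(seq_len(n), -half:half, "+")
    idx[idx < 1] <- 1 - idx[idx < 1] + 1   # reflect
    idx[idx > n] <- 2 * n - idx[idx > n]
    matrix(x[idx], n)[, seq_along(kern)] %*% kern
  }
  m <- apply(m, 2, blur_1d)
  t(apply(t(m), 2, blur_1d))
}

nodule_distance_map <- function(H, W, nod) {
  xs <- seq_len(W) - 0.5
  ys <- seq_len(H) - 0.5
  sqrt(outer(((ys - nod$cy) / nod$b)^2, ((xs - nod$cx) / nod$a)^2, "+"))
}

validate_scene <- function(scene) {
  img <- scene$image
  H <- nrow(img); W <- ncol(img)
  gt <- scene$gt_boxes
  if (nrow(gt) > 0) {
    stopifnot(all(gt$x1 >= 0), all(gt$y1 >= 0),
              all(gt$x2 <= W), all(gt$y2 <= H),
              all(gt$x2 > gt$x1), all(gt$y2 > gt$y1))
    for (nod in scene$nodules) {
      d <- nodule_distance_map(H, W, nod)
      core <- mean(img[d <= 0.6])
      ring <- mean(img[d >= 1.5 & d <= 2.5])
      if (!is.finite(ring)) next
      if (core - ring < scene$params$contrast) {
        stop("rendered nodule does not reach the configured contrast",
             call. = FALSE)
      }
    }
  }
  invisible(scene)
}

#' @export
print.nodule_scene <- function(x, ...) {
  cat(sprintf("<nodule_scene> %d x %d image, %d nodule(s), seed %s\n",
              nrow(x$image), ncol(x$image), nrow(x$gt_boxes),
              ifelse(is.null(x$params$seed), "none", x$params$seed)))
  invisible(x)
}

#' Plot a nodule scene with its ground-truth boxes
#'
#' @param object A `nodule_scene`.
#' @param ... Unused.
#' @return A ggplot raster of the image with the boxes overlaid.
#' @method autoplot nodule_scene
#' @export
autoplot.nodule_scene <- function(object, ...) {
  img <- object$image
  df <- tidyr::expand_grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
  df$value <- as.vector(t(img))[(df$y - 1) * ncol(img) + df$x]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::geom_rect(data = object$gt_boxes,
                       ggplot2::aes(xmin = .data$x1, xmax = .data$x2,
                                    ymin = .data$y1, ymax = .data$y2),
                       inherit.aes = FALSE, colour = "red", fill = NA) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Intensity") +
    ggplot2::theme_minimal()
}

#' Corrupt ground-truth boxes into simulated detections
#'
#' Drives the evaluation code with realistic imperfect predictions: each
#' ground truth survives with probability `1 - fn_rate` and is jittered in
#' center and size by Gaussian noise of standard deviation `jitter_sd`
#' pixels; its confidence decays exponentially with the jitter magnitude
#' relative to the box size. False positives are added at a Poisson rate of
#' `fp_rate` per ground truth, as random boxes with the same size
#' distribution and low confidence.
#'
#' @param gt_boxes Tibble of ground-truth boxes (`x1, y1, x2, y2`,
#'   optional `image_id`).
#' @param jitter_sd Center/size jitter in pixels (0 gives perfect copies
#'   at confidence 1).
#' @param fp_rate Expected false positives per ground truth, in `[0, 1]`.
#' @param fn_rate Miss probability per ground truth, in `[0, 1]`.
#' @param image_size Length-2 `(W, H)` bounds for false-positive placement
#'   and clipping (default 320 square).
#' @param seed Optional integer seed.
#' @return A detection tibble: `image_id, x1, y1, x2, y2, confidence,
#'   class_id` (single class 0, "nodule").
#' @examples
#' gt <- boxes(c(10, 60), c(10, 60), c(30, 90), c(30, 90))
#' corrupt_gt_to_predictions(gt, jitter_sd = 1, fp_rate = 0, fn_rate = 0,
#'                           seed = 1)
#' @export
corrupt_gt_to_predictions <- function(gt_boxes, jitter_sd = 2,
                                      fp_rate = 0.1, fn_rate = 0.1,
                                      image_size = c(320, 320),
                                      seed = NULL) {
  stopifnot(fp_rate >= 0, fp_rate <= 1, fn_rate >= 0, fn_rate <= 1,
            jitter_sd >= 0)
  gt_boxes <- as_detection_table(gt_boxes, need_conf = FALSE)
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(gt_boxes)
  keep <- stats::runif(n) >= fn_rate
  rows <- list()
  for (i in which(keep)) {
    g <- gt_boxes[i, ]
    w <- g$x2 - g$x1; h <- g$y2 - g$y1
    dxy <- stats::rnorm(2, 0, jitter_sd)
    dwh <- stats::rnorm(2, 0, jitter_sd)
    w2 <- max(w + dwh[1], 1); h2 <- max(h + dwh[2], 1)
    cx <- (g$x1 + g$x2) / 2 + dxy[1]
    cy <- (g$y1 + g$y2) / 2 + dxy[2]
    mag <- sqrt(sum(dxy^2) + sum(dwh^2))
    conf <- exp(-mag / max((w + h) / 2, 1))
    rows[[length(rows) + 1]] <- tibble::tibble(
      image_id = g$image_id,
      x1 = max(cx - w2 / 2, 0), y1 = max(cy - h2 / 2, 0),
      x2 = min(cx + w2 / 2, image_size[1]), y2 = min(cy + h2 / 2, image_size[2]),
      confidence = min(conf, 1), class_id = 0L
    )
  }
  n_fp <- if (n > 0) stats::rpois(1, fp_rate * n) else 0L
  sizes <- pmax(c(gt_boxes$x2 - gt_boxes$x1, gt_boxes$y2 - gt_boxes$y1), 2)
  for (j in seq_len(n_fp)) {
    w <- sample(sizes, 1) * stats::runif(1, 0.8, 1.25)
    h <- sample(sizes, 1) * stats::runif(1, 0.8, 1.25)
    cx <- stats::runif(1, w / 2, image_size[1] - w / 2)
    cy <- stats::runif(1, h / 2, image_size[2] - h / 2)
    rows[[length(rows) + 1]] <- tibble::tibble(
      image_id = gt_boxes$image_id[1],
      x1 = cx - w / 2, y1 = cy - h / 2, x2 = cx + w / 2, y2 = cy + h / 2,
      confidence = stats::runif(1, 0.05, 0.5), class_id = 0L
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(image_id = integer(), x1 = numeric(), y1 = numeric(),
                          x2 = numeric(), y2 = numeric(),
                          confidence = numeric(), class_id = integer()))
  }
  dplyr::bind_rows(rows)
}
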