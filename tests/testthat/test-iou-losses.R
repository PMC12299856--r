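ex_pairs <- function(n, seed) {
  pairs <- sample_box_pairs(n, seed = seed)
  list(pred = dplyr::select(pairs, x1, y1, x2, y2),
       gt = dplyr::rename(dplyr::select(pairs, dplyr::starts_with("gt_")),
                          x1 = gt_x1, y1 = gt_y1, x2 = gt_x2, y2 = gt_y2))
}

test_that("arctangent aspect term matches closed-form values and saturates", {
  sq <- boxes(0, 0, 1, 1)
  expect_equal(aspect_v(sq, sq), 0)
  # frozen by an independent arctan evaluation
  expect_equal(aspect_v(boxes(0, 0, 1, 1), boxes(0, 0, 2, 1)),
               0.041956461494291, tolerance = 1e-9)
  # crossed extreme ratios: arctan difference saturates at pi/2 so v -> 1
  v_lim <- aspect_v(boxes(0, 0, 1e6, 1), boxes(0, 0, 1, 1e6))
  expect_gt(v_lim, 1 - 1e-5)
  expect_lte(v_lim, 1)
})

test_that("squared aspect penalty is exact, symmetric and convex", {
  expect_equal(aspect_penalty(boxes(0, 0, 3, 2), boxes(5, 5, 8, 7)), 0)
  expect_equal(aspect_penalty(boxes(0, 0, 4, 1), boxes(0, 0, 1, 4)), 14.0625)
  expect_identical(aspect_penalty(boxes(0, 0, 4, 1), boxes(0, 0, 1, 4)),
                   aspect_penalty(boxes(0, 0, 1, 4), boxes(0, 0, 4, 1)))
  # convexity in r1 for fixed r2: non-negative second differences on a grid
  r_grid <- seq(0.1, 8, by = 0.1)
  gt <- boxes(0, 0, 2, 1)
  pen <- aspect_penalty(boxes(0, 0, r_grid, 1), gt)
  second_diff <- diff(pen, differences = 2)
  expect_true(all(second_diff >= -1e-9))
})

test_that("EAPIoU worked pairs match the independent term-by-term oracle", {
  # identity: all penalties vanish
  idb <- boxes(2, 3, 5, 9)
  r <- eapiou_score(idb, idb, lambda = 0.37)
  expect_equal(r$score, 1)
  expect_equal(r$loss, 0)
  # concentric, same ratio: only IoU differs from 1
  r2 <- eapiou_score(boxes(-1, -1, 1, 1), boxes(-2, -2, 2, 2), lambda = 0.1)
  expect_equal(r2$score, 0.25, tolerance = 1e-9)
  # crossed 4:1 vs 1:4 at lambda 0.1 (frozen from the term-by-term script)
  r3 <- eapiou_score(boxes(0, 0, 4, 1), boxes(0, 0, 1, 4), lambda = 0.1)
  expect_equal(r3$score, -1.451363744480019, tolerance = 1e-9)
  expect_equal(r3$score,
               oracle_eapiou(c(0, 0, 4, 1), c(0, 0, 1, 4), lambda = 0.1),
               tolerance = 1e-12)
})

test_that("baseline variants reproduce their defining formulas", {
  a <- boxes(0, 0, 2, 2); b <- boxes(1, 1, 3, 3)
  for (v in c("iou", "giou", "diou", "ciou", "eapiou")) {
    expect_equal(box_loss(a, a, loss_config(v))$score, 1,
                 tolerance = 1e-9, label = v)
  }
  disj <- box_loss(boxes(0, 0, 1, 1), boxes(5, 5, 6, 6), loss_config("giou"))
  expect_equal(disj$iou, 0)
  expect_lt(disj$score, 0)
  expect_equal(box_loss(a, b, loss_config("diou"))$score,
               0.031746031746032, tolerance = 1e-9)
  expect_error(loss_config("wiou"), "arg")
})

test_that("loss terms reconstruct the score and never exceed plain IoU", {
  p <- ex_pairs(100, seed = 31)
  for (v in c("iou", "giou", "diou", "ciou", "eapiou")) {
    for (lam in c(0, 0.1, 1)) {
      r <- box_loss(p$pred, p$gt, loss_config(v, lambda = lam))
      recon <- r$iou - r$distance_term - r$v_weight * r$v_term -
        r$aspect_weight * r$aspect_term
      expect_equal(r$score, recon, tolerance = 1e-12)
      expect_true(all(r$score <= r$iou + 1e-12))
      expect_equal(r$loss, 1 - r$score, tolerance = 1e-12)
    }
  }
})

test_that("lambda outside [0, 1] is rejected", {
  expect_error(loss_config("eapiou", lambda = -0.1), "lambda")
  expect_error(loss_config("eapiou", lambda = 1.5), "lambda")
  expect_error(loss_config("eapiou", lambda = NA_real_), "lambda")
  expect_silent(loss_config("eapiou", lambda = 0))
  expect_silent(loss_config("eapiou", lambda = 1))
})

test_that("EAPIoU score is swap-symmetric and translation/scale invariant", {
  p <- ex_pairs(50, seed = 99)
  fwd <- eapiou_score(p$pred, p$gt)
  bwd <- eapiou_score(p$gt, p$pred)
  expect_identical(fwd$score, bwd$score)
  shift <- function(b, dx, dy) {
    dplyr::mutate(b, x1 = x1 + dx, x2 = x2 + dx, y1 = y1 + dy, y2 = y2 + dy)
  }
  scl <- function(b, s) dplyr::mutate(b, dplyr::across(dplyr::everything(), ~ .x * s))
  tr <- eapiou_score(shift(p$pred, 11, -3), shift(p$gt, 11, -3))
  expect_equal(tr$score, fwd$score, tolerance = 1e-9)
  sc <- eapiou_score(scl(p$pred, 5.5), scl(p$gt, 5.5))
  expect_equal(sc$score, fwd$score, tolerance = 1e-9)
})

test_that("lambda = 0 collapses EAPIoU to DIoU", {
  p <- ex_pairs(50, seed = 12)
  e0 <- box_loss(p$pred, p$gt, loss_config("eapiou", lambda = 0))
  d <- box_loss(p$pred, p$gt, loss_config("diou"))
  expect_equal(e0$score, d$score, tolerance = 1e-12)
})

test_that("score decreases strictly as the aspect-ratio gap grows", {
  # terms other than the explicit penalty held fixed by analytic substitution
  g <- pair_geometry(boxes(0, 0, 2, 2), boxes(1, 1, 3, 3))
  lam <- 0.1
  base <- g$iou - g$rho_sq / g$c_sq - lam * g$v
  gaps <- seq(0, 5, by = 0.25)
  scores <- base - lam * gaps^2
  expect_true(all(diff(scores[-1]) < 0))
  # and through the real interface: widen pred at constant center/height
  widths <- c(2, 3, 4, 6)
  s <- vapply(widths, function(w) {
    eapiou_score(boxes(-w / 2, -1, w / 2, 1), boxes(-1, -1, 1, 1))$aspect_term
  }, numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("any corner perturbation strictly decreases the score from 1", {
  b <- boxes(1, 2, 4, 6)
  for (j in 1:4) {
    for (delta in c(-0.05, 0.05)) {
      pert <- as.numeric(b[1, ])
      pert[j] <- pert[j] + delta
      s <- eapiou_score(boxes(pert[1], pert[2], pert[3], pert[4]), b)$score
      expect_lt(s, 1)
    }
  }
})

test_that("explicit penalty keeps gradient while v saturates at extreme ratios", {
  # gt square (ratio 1); derivative wrt pred ratio r evaluated numerically
  dv_dr <- function(r, h = 1e-6) {
    (aspect_v(boxes(0, 0, r + h, 1), boxes(0, 0, 1, 1)) -
       aspect_v(boxes(0, 0, r - h, 1), boxes(0, 0, 1, 1))) / (2 * h)
  }
  dpen_dr <- function(r, h = 1e-6) {
    (aspect_penalty(boxes(0, 0, r + h, 1), boxes(0, 0, 1, 1)) -
       aspect_penalty(boxes(0, 0, r - h, 1), boxes(0, 0, 1, 1))) / (2 * h)
  }
  expect_equal(dpen_dr(10), 18, tolerance = 1e-4)
  expect_gt(abs(dpen_dr(10)) / abs(dv_dr(10)), 100)
  # saturation: dv/dr shrinks with r while the squared penalty's grows
  expect_lt(abs(dv_dr(100)), abs(dv_dr(10)))
  expect_gt(abs(dpen_dr(100)), abs(dpen_dr(10)))
})

test_that("ciou alpha modes differ and fixed_lambda matches a fixed weight", {
  a <- boxes(0, 0, 3, 1); b <- boxes(0.5, 0.2, 2.5, 2.2)
  orig <- box_loss(a, b, loss_config("ciou", ciou_alpha_mode = "original_alpha"))
  lam <- box_loss(a, b, loss_config("ciou", lambda = 0.1,
                                    ciou_alpha_mode = "fixed_lambda"))
  expect_false(isTRUE(all.equal(orig$score, lam$score)))
  expect_equal(lam$v_weight, 0.1)
  g <- pair_geometry(a, b)
  expect_equal(orig$v_weight, g$v / ((1 - g$iou) + g$v + 1e-7), tolerance = 1e-12)
})
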