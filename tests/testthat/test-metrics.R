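test_that("greedy matching handles the canonical small cases", {
  gt <- box1(0, 0, 10, 10)
  one <- tibble::tibble(x1 = 0, y1 = 0, x2 = 10, y2 = 10, confidence = 0.9)
  m <- match_detections(one, gt, 0.5)
  expect_true(m$tp)
  # two identical detections on one GT: one-to-one matching
  two <- dplyr::bind_rows(one, dplyr::mutate(one, confidence = 0.8))
  m2 <- match_detections(two, gt, 0.5)
  expect_equal(m2$tp, c(TRUE, FALSE))
  expect_equal(m2$matched_gt, c(1L, NA_integer_))
})

test_that("3 detections vs 2 GTs with IoUs 0.8/0.3/0.6 flag as TP,FP,TP", {
  gt <- box1(c(0, 100), c(0, 0), c(10, 110), c(10, 10))
  # det1 on gt1 with IoU 0.8; det2 on gt1 with IoU ~0.3; det3 on gt2 IoU ~0.6
  make_det <- function(g, target_iou) {
    # shift right by d so that IoU = (10-d)/(10+d) -> d solves it
    d <- 10 * (1 - target_iou) / (1 + target_iou)
    tibble::tibble(x1 = g$x1 + d, y1 = g$y1, x2 = g$x2 + d, y2 = g$y2)
  }
  dets <- dplyr::bind_rows(
    dplyr::mutate(make_det(gt[1, ], 0.8), confidence = 0.95),
    dplyr::mutate(make_det(gt[1, ], 0.3), confidence = 0.90),
    dplyr::mutate(make_det(gt[2, ], 0.6), confidence = 0.85)
  )
  m <- match_detections(dets, gt, 0.5)
  expect_equal(m$tp, c(TRUE, FALSE, TRUE))
  expect_equal(m$matched_gt, c(1L, NA_integer_, 2L))
})

test_that("PR curve and all-point AP reproduce hand-enumerated values", {
  r1 <- pr_curve_ap(TRUE, 1)
  expect_equal(r1$curve$precision, 1)
  expect_equal(r1$curve$recall, 1)
  expect_equal(r1$ap, 1)
  expect_equal(pr_curve_ap(c(FALSE, FALSE), 1)$ap, 0)
  # envelope area: 0.5 * 1 + 0.5 * (2/3)
  expect_equal(pr_curve_ap(c(TRUE, FALSE, TRUE), 2)$ap, 0.5 + 0.5 * 2 / 3)
  expect_equal(pr_curve_ap(logical(0), 3)$ap, 0)
  expect_equal(pr_curve_ap(c(TRUE, TRUE), 0)$ap, 0)
})

test_that("perfect and empty detections give the boundary metrics", {
  sc <- gen_nodule_scene(n_nodules = 4, image_size = 160, seed = 21)
  perfect <- corrupt_gt_to_predictions(sc$gt_boxes, jitter_sd = 0, fp_rate = 0,
                                       fn_rate = 0, image_size = 160, seed = 1)
  ev <- evaluate_detections(perfect, sc$gt_boxes)
  expect_equal(ev$map50, 1)
  expect_equal(ev$map50_90, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  none <- perfect[0, ]
  ev0 <- evaluate_detections(none, sc$gt_boxes)
  expect_equal(ev0$map50, 0)
  expect_equal(ev0$map50_90, 0)
  expect_equal(ev0$precision, 0)
  expect_equal(ev0$recall, 0)
  expect_warning(evaluate_detections(perfect, sc$gt_boxes[0, ]),
                 "false positive")
})

test_that("evaluation agrees with an independent naive evaluator", {
  sc <- gen_nodule_scene(n_nodules = 8, image_size = 256, seed = 33)
  dets <- corrupt_gt_to_predictions(sc$gt_boxes, jitter_sd = 2, fp_rate = 0.3,
                                    fn_rate = 0.1, image_size = 256, seed = 34)
  thresholds <- seq(0.5, 0.9, by = 0.05)
  ev <- evaluate_detections(dets, sc$gt_boxes, thresholds)
  naive <- vapply(thresholds, function(th) naive_ap(dets, sc$gt_boxes, th),
                  numeric(1))
  expect_equal(ev$per_threshold$ap, naive, tolerance = 1e-12)
  expect_equal(ev$map50_90, mean(naive), tolerance = 1e-12)
})

test_that("AP is non-increasing in the IoU threshold on jittered suites", {
  for (seed in c(41, 42, 43)) {
    sc <- gen_nodule_scene(n_nodules = 6, image_size = 224, seed = seed)
    dets <- corrupt_gt_to_predictions(sc$gt_boxes, jitter_sd = 1.5,
                                      fp_rate = 0.2, fn_rate = 0.1,
                                      image_size = 224, seed = seed + 100)
    ev <- evaluate_detections(dets, sc$gt_boxes)
    expect_true(all(diff(ev$per_threshold$ap) <= 1e-12))
    expect_lte(ev$map50_90, ev$map50 + 1e-12)
  }
})

test_that("false positives at the ends of the ranking behave as expected", {
  gt <- box1(c(0, 50), c(0, 0), c(10, 60), c(10, 10))
  base <- tibble::tibble(x1 = c(0, 50), y1 = 0, x2 = c(10, 60), y2 = 10,
                         confidence = c(0.9, 0.8))
  ap_base <- evaluate_detections(base, gt)$map50
  fp <- tibble::tibble(x1 = 200, y1 = 200, x2 = 210, y2 = 210,
                       confidence = 0.99)
  ap_front <- evaluate_detections(dplyr::bind_rows(fp, base), gt)$map50
  expect_lte(ap_front, ap_base)
  fp_tail <- dplyr::mutate(fp, confidence = 0.01)
  ap_tail <- evaluate_detections(dplyr::bind_rows(base, fp_tail), gt)$map50
  expect_equal(ap_tail, ap_base)
})

test_that("metrics are invariant to uniform rescaling of all boxes", {
  sc <- gen_nodule_scene(n_nodules = 5, image_size = 128, seed = 55)
  dets <- corrupt_gt_to_predictions(sc$gt_boxes, jitter_sd = 2, fp_rate = 0.2,
                                    fn_rate = 0, image_size = 128, seed = 56)
  scale_tbl <- function(x, s) {
    dplyr::mutate(x, x1 = x1 * s, y1 = y1 * s, x2 = x2 * s, y2 = y2 * s)
  }
  ev1 <- evaluate_detections(dets, sc$gt_boxes)
  ev2 <- evaluate_detections(scale_tbl(dets, 7), scale_tbl(sc$gt_boxes, 7))
  expect_equal(ev1$per_threshold$ap, ev2$per_threshold$ap, tolerance = 1e-9)
})

test_that("tidy, glance and autoplot expose the evaluation results", {
  sc <- gen_nodule_scene(n_nodules = 3, image_size = 128, seed = 61)
  dets <- corrupt_gt_to_predictions(sc$gt_boxes, jitter_sd = 1, fp_rate = 0,
                                    fn_rate = 0, image_size = 128, seed = 62)
  ev <- evaluate_detections(dets, sc$gt_boxes)
  td <- tidy(ev)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 9)
  gl <- glance(ev)
  expect_equal(nrow(gl), 1)
  expect_named(gl, c("map50", "map50_90", "precision", "recall",
                     "n_detections", "n_gt"))
  expect_s3_class(autoplot(ev), "ggplot")
})
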