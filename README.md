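# eapiou

Desk-scale tools for studying bounding-box regression and attention in
small-object (pulmonary-nodule) detection. The package implements, as
tested and inspectable R code:

- the **EAPIoU** score and loss — IoU penalized by normalized center
  distance, the CIoU arctangent aspect term *v*, and an **explicit squared
  aspect-ratio penalty** — together with the IoU/GIoU/DIoU/CIoU baselines
  and exact analytic gradients;
- a reference forward pass of a **spatial squeeze-and-excitation (SSE)**
  attention module (channel SE, then max/mean-pooled spatial attention
  through a *k*×*k* convolution and sigmoid);
- **detection evaluation**: greedy confidence-ordered matching,
  precision/recall curves, all-point AP, mAP@50 and mAP@50–90;
- a seeded **box-regression simulator** (gradient descent with
  backtracking in `(cx, cy, log w, log h)`) for comparing loss variants and
  penalty weights;
- seeded **synthetic data**: box pairs with controlled overlap/aspect
  mismatch, CT-slice-like nodule scenes with tight box labels, random
  feature maps, and corrupted predictions.

Everything is tibble-in/tibble-out and pipe-friendly, with `autoplot()`,
`tidy()` and `glance()` methods for the result objects.

## The core score

For predicted and ground-truth boxes $b, b^{gt}$ with widths $w_i$ and
heights $h_i$:

$$\mathrm{EAPIoU} = \mathrm{IoU} - \frac{\rho^2(b, b^{gt})}{c^2}
 - \lambda\,v - \lambda\Big(\tfrac{w_1}{h_1}-\tfrac{w_2}{h_2}\Big)^2,
 \qquad
 v = \tfrac{4}{\pi^2}\Big(\arctan\tfrac{w_2}{h_2}-\arctan\tfrac{w_1}{h_1}\Big)^2,$$

with $\rho^2$ the squared center distance, $c^2$ the squared enclosing-box
diagonal and $\lambda \in [0,1]$ (default 0.1). The loss is
$1 - \mathrm{EAPIoU}$. The explicit squared-ratio term is the point: *v*
saturates for strongly elongated boxes while the squared difference keeps a
growing gradient, so shape mismatch is corrected faster.

## Worked example

Score a badly shape-mismatched pair (a 4:1 box against a 1:4 target),
term by term:

```r
library(eapiou)
eapiou_score(boxes(0, 0, 4, 1), boxes(0, 0, 1, 4), lambda = 0.1) |>
  dplyr::select(iou, distance_term, v_term, aspect_term, score, loss)
#> # A tibble: 1 × 6
#>     iou distance_term v_term aspect_term score  loss
#>   <dbl>         <dbl>  <dbl>       <dbl> <dbl> <dbl>
#> 1 0.143         0.141  0.473        14.1 -1.45  2.45
```

The boxes overlap a little (IoU 1/7) and their centers are close, but the
aspect penalty `(4 − 1/4)² ≈ 14.1` dominates: at λ = 0.1 the score drops to
−1.45. The bounded arctangent term (`v_term` = 0.47) barely registers the
same mismatch — that contrast is the motivation for the explicit penalty.

Generate a synthetic nodule scene, corrupt its ground truth into imperfect
"detections", and evaluate:

```r
sc   <- gen_nodule_scene(n_nodules = 5, image_size = 256, seed = 42)
dets <- corrupt_gt_to_predictions(sc$gt_boxes, jitter_sd = 1.5,
                                  fp_rate = 0.2, fn_rate = 0.1,
                                  image_size = 256, seed = 43)
evaluate_detections(dets, sc$gt_boxes)
#> <detection_eval> 5 detections vs 5 ground truths
#>   mAP@50 = 0.8000   mAP@50-90 = 0.5704
#>   precision = 0.8000   recall = 0.8000  (IoU 0.50, full ranking)
```

One of the five nodules was dropped (the miss rate), so recall tops out at
0.8; the jittered boxes match at IoU 0.5 but fall away at stricter
thresholds, which is why mAP@50–90 (0.57) sits below mAP@50.

Compare loss variants by simulated box regression under strong aspect
mismatch (initial ratios off by up to 4×):

```r
cfg <- sim_config(variants = c("eapiou", "diou"), lambdas = 0.1,
                  n_targets = 20, n_inits_per_target = 2,
                  stratum = "aspect_mismatch", seed = 7)
run_box_regression(cfg) |> glance()
#> # A tibble: 2 × 6
#>   variant lambda n_runs mean_final_iou convergence_rate median_steps_to_tol
#>   <chr>    <dbl>  <int>          <dbl>            <dbl>               <dbl>
#> 1 diou       0.1     40          0.983             0.95                40.5
#> 2 eapiou     0.1     40          0.980             0.95                31.5
```

Both variants reach the target eventually, but the explicit aspect penalty
gets there in fewer steps (median 31.5 vs 40.5) — the desk-scale analogue
of "more responsive gradients" under shape mismatch.

A thin command-line wrapper over the same functions ships at
`inst/scripts/eapiou-cli.R` (`eval`, `gen-data`, `sim-compare`,
`lambda-sweep`, `attention-demo`).

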