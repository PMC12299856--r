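---
title: "Aspect-ratio-penalized IoU regression and spatial squeeze-and-excitation attention: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eapiou)
```

## The problem

Detecting pulmonary nodules on CT slices is a small-object detection task:
the targets are a few pixels to a few dozen pixels across, often elongated,
and easily confused with background texture. Two ingredients of a detector
matter disproportionately in this regime: how the bounding-box regression
loss treats *shape* (aspect-ratio) mismatch, and whether the feature
extractor can emphasize the right *spatial* locations as well as the right
channels. This package implements both ingredients as an inspectable,
desk-scale library — no GPU, no training — so their mathematical claims can
be exercised, verified and compared directly.

## The EAPIoU score and loss

For a predicted box $b$ and ground-truth box $b^{gt}$ in corner format, with
widths/heights $w_i = x_2 - x_1$, $h_i = y_2 - y_1$, the score is

$$\mathrm{EAPIoU} \;=\; \mathrm{IoU} \;-\; \frac{\rho^2(b, b^{gt})}{c^2}
\;-\; \lambda\, v \;-\; \lambda \left(\frac{w_1}{h_1} - \frac{w_2}{h_2}\right)^2,$$

where $\rho^2$ is the squared distance between box centers, $c^2$ the squared
diagonal of the smallest enclosing box, and

$$v = \frac{4}{\pi^2}\left(\arctan\frac{w_2}{h_2} - \arctan\frac{w_1}{h_1}\right)^2$$

is the bounded arctangent aspect term familiar from CIoU. The final,
explicit squared-ratio term is the point of the construction: $v$ saturates
(it cannot exceed 1, and its derivative with respect to the ratio decays
like $1/(1+r^2)$), so a 10:1 box regressing toward a square target receives
almost no shape gradient from $v$ alone. The squared ratio difference is
convex and symmetric in the ratios and grows without bound, so its gradient
*increases* with the mismatch:

```{r saturation}
# derivative of each aspect term wrt the predicted ratio, square target
h <- 1e-6
dv   <- (aspect_v(boxes(0, 0, 10 + h, 1), boxes(0, 0, 1, 1)) -
         aspect_v(boxes(0, 0, 10 - h, 1), boxes(0, 0, 1, 1))) / (2 * h)
dpen <- (aspect_penalty(boxes(0, 0, 10 + h, 1), boxes(0, 0, 1, 1)) -
         aspect_penalty(boxes(0, 0, 10 - h, 1), boxes(0, 0, 1, 1))) / (2 * h)
c(dv = dv, dpen = dpen, ratio = dpen / dv)
```

The training-style loss is $L = 1 - \mathrm{EAPIoU}$, the standard
IoU-loss convention: the score is bounded above by 1 (attained only at
$b = b^{gt}$), so the loss is zero exactly at the optimum. Whether one
minimizes $1 - \mathrm{EAPIoU}$ or $-\mathrm{EAPIoU}$ is immaterial for
gradients; the bounded form is used because it makes trajectories
interpretable.

### The penalty weight $\lambda$

$\lambda \in [0,1]$ (enforced at construction) weights *both* aspect terms.
$\lambda = 0$ reduces the score exactly — bitwise, in this implementation —
to DIoU. The recommended default is $\lambda = 0.1$: large enough that the
shape penalty contributes meaningfully, small enough that a grossly
mismatched initialization (where the squared ratio difference can reach
$10^1$–$10^2$) does not drown the overlap terms. The `regression_sim`
module exposes the grid $\{0.001, 0.01, 0.1, 0.5, 1\}$ so the trade-off can
be mapped with convergence statistics.

### Baselines

GIoU, DIoU and CIoU are provided for comparison. The CIoU baseline defaults
to its original adaptive weight $\alpha = v / ((1-\mathrm{IoU}) + v)$
(`ciou_alpha_mode = "original_alpha"`), so comparisons are against the
formulation as published; a fixed-$\lambda$ mode is available for symmetry
with EAPIoU. Note that EAPIoU itself weights $v$ by plain $\lambda$, never
by $\alpha$.

## Numerical design

**Degeneracy guards.** Heights in ratio denominators and $c^2$ are
*floored* at $\varepsilon = 10^{-7}$ rather than incremented by it. A floor
leaves every non-degenerate box bit-exact — so joint translation and
positive rescaling of a pair change the score only through floating-point
rounding — while still making the score and gradient finite if a degenerate
box ever appears. An additive guard would bias small boxes and visibly
break scale invariance (at the $10^{-6}$ level for unit-sized boxes).

**Gradients.** `loss_and_grad()` returns the exact chain-rule gradient in
either the corner parameterization $(x_1, y_1, x_2, y_2)$ or the center-log
parameterization $(c_x, c_y, \log w, \log h)$. Three choices are worth
recording:

* the $v$ term is differentiated exactly — no dropped
  $1/(w^2 + h^2)$-style factors — and verified against central finite
  differences;
* the CIoU $\alpha$ is differentiated *through*, because the finite
  difference of the actual score function sees $\alpha$ move;
* the $\min/\max$ kinks of the intersection and enclosing box use the
  symmetric subgradient (the mean of the two one-sided derivatives) inside
  a narrow relative tie band ($10^{-9}$). At the optimum this yields a zero
  IoU subgradient; during optimization it prevents a coordinate that has
  already snapped onto its target value from supplying a spurious
  one-sided pull.

## The SSE attention forward pass

Given a feature map $X \in \mathbb{R}^{B \times C \times H \times W}$, the
module applies two gates in sequence:

1. **Channel squeeze-and-excitation.** Global average pooling gives a
   channel descriptor $z_c$; a two-layer bottleneck
   $y = \sigma(W_2\,\mathrm{ReLU}(W_1 z + b_1) + b_2)$ with reduction ratio
   $r$ produces gates $y_c \in (0,1)$; $X'_{c,i,j} = y_c X_{c,i,j}$.
2. **Spatial attention on $X'$.** Channel-axis max and mean pooling give
   two $H \times W$ descriptors; a $k \times k$ convolution
   (cross-correlation, stride 1, zero padding $(k-1)/2$, single bias) of
   the stacked pair followed by a sigmoid gives the map $S \in (0,1)^{H
   \times W}$; the output is $O_{c,i,j} = X'_{c,i,j} S_{i,j}$.

The order is deliberately sequential — the spatial descriptors are computed
on the channel-recalibrated map, not on the raw input. The source
formulation is ambiguous on this point (its discussion speaks of parallel
branches fused additively, while its defining equations compose the two
multiplicatively with the SE output feeding the spatial branch); the
equations are treated as normative here, and this implementation follows
them. Consequences that the tests pin down: both gates lie strictly in
$(0,1)$, so the module is a strict contraction ($|O| \le |X|$ elementwise),
and all-zero weights give the closed form $O = X/4$.

Defaults: $r = 16$ (the standard SE bottleneck; the width floors at one
channel), $k = 7$ with $\{3, 5, 9, 11\}$ supported. Weights are seeded
uniform $[-1/\sqrt{\mathrm{fan_in}}, +1/\sqrt{\mathrm{fan_in}}]$ with zero
biases; no training happens in this package — the weights exist so the
forward computation is concrete, reproducible and checkable against a
straight-loop oracle. Per batch element, descriptors are computed over
channels only; pooling across the batch was considered and rejected, since
it would couple unrelated images.

## Detection metrics

Matching is greedy in confidence order (ties keep input order): each
detection claims the still-unclaimed ground truth of highest IoU in its
image, provided the IoU reaches the threshold; IoU ties resolve to the
lowest ground-truth index. AP is the area under the monotone precision
envelope over recall (all-point interpolation, the modern YOLO-family
convention, not the 11-point variant). `map50` is AP at threshold 0.50;
`map50_90` averages thresholds $\{0.50, 0.55, \dots, 0.90\}$ — endpoint
inclusive, step 0.05, a reading of the "50–90" range; the COCO set
$\{0.50, \dots, 0.95\}$ is one argument away. Precision and recall are
reported at the final operating point of the ranking (threshold 0.50);
with zero predictions, precision is reported as 0 with a flag rather than
NaN. Evaluation is single-class ("nodule"); the structure generalizes to
per-class AP means but only one class is exercised.

## The regression simulator

The $\lambda$ study in the source setting measures detector mAP after GPU
training; at desk scale this package substitutes a pure box-regression
experiment, clearly labeled as an *analogue*: random targets (ratios
log-uniform in $[1/4, 4]$, sizes around 1), random initial boxes (center
jitter up to half the target diagonal, scale $\times[0.5, 2]$, ratio
mismatch per stratum), and gradient descent on the chosen loss.

Design choices:

* **Parameterization** $(c_x, c_y, \log w, \log h)$ keeps widths/heights
  positive with no constraint handling.
* **Backtracking line search** (step starts at `lr`, halves until the loss
  does not increase) makes "accepted steps never increase the loss" an
  assertable contract rather than a hope. Defaults `lr = 0.05`,
  `max_steps = 1000`, stop at $1 - \mathrm{IoU} \le 0.01$; these are this
  package's own choices, as no comparable optimizer setting exists to
  inherit.
* **Strata** (`benign`, `aspect_mismatch`, `disjoint`) are explicit presets
  so that any convergence claim names the population it was measured on.

Known limitation: plain steepest descent can stall at a *kink trap* — when
one coordinate pair has converged exactly, the IoU surface has a V-shaped
corner there, and the one-sided slope can block the line search even though
other coordinates could still improve. In the benign stratum this affects
roughly 1–3% of runs (the convergence contract is $\ge 95\%$ reaching IoU
0.9 within 1000 steps). A coordinate-descent fallback would remove it at
the cost of complicating the monotonicity contract; the simple algorithm is
kept and the failure mode documented.

## Synthetic data

The generators emulate the *statistical shape* of a single-class nodule
dataset, not its physics:

* `sample_box_pairs()` — box pairs with measured IoU and ratio quotient
  inside requested ranges (rejection sampling; every returned pair is
  re-measured with the package's own geometry).
* `gen_nodule_scene()` — default $320 \times 320$ images in $[0,1]$:
  Gaussian background (level 0.2, sd 0.05), 4–16 px anti-aliased elliptical
  nodules with Gaussian-blurred edges, tight analytic boxes,
  non-overlapping placement. The rendered amplitude is self-calibrated:
  the unit-amplitude layer is measured per nodule (core $d \le 0.6$ vs a
  local ring $1.5 \le d \le 2.5$) and scaled so the worst nodule clears the
  nominal contrast with headroom for noise — a hard validity check runs at
  construction.
* `corrupt_gt_to_predictions()` — survivors of a miss rate are jittered in
  center and size; confidence decays exponentially with jitter magnitude
  relative to box size; false positives arrive at a Poisson rate with the
  nodule size distribution.

Everything is byte-reproducible under a seed. What passing tests on these
scenes do **not** show: robustness to real CT artifacts (slice thickness,
reconstruction kernels, vessels and pleura mimicking nodules), detector
training dynamics, or anything about the named public datasets — those are
out of scope by design.

## Problem sizes

The test suite and the acceptance script run at deliberately small sizes:
1000 random pairs against a 1000×1000 rasterized IoU oracle, 200 pairs for
finite-difference gradient checks, 50 small tensors (≤ 2×8×6×6) against the
loop-level SSE oracle, 10-image synthetic detection benchmarks, and
regression sweeps of 25–100 runs capped at 600–1000 steps. These sizes were
chosen so every claim is checked by an independent oracle in seconds while
remaining statistically meaningful at the stated tolerances.
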