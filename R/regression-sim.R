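#' Configuration for the box-regression convergence experiment
#'
#' The simulator regresses randomly initialized boxes onto random targets by
#' gradient descent on a chosen IoU-based loss, as a desk-scale analogue of
#' training-time bounding-box regression: it is how this package studies
#' the responsiveness of the explicit aspect-ratio penalty and the effect
#' of the penalty weight `lambda` without training a detector.
#'
#' @param variants Loss variants to compare (see [loss_config()]).
#' @param lambdas Grid of penalty coefficients; default
#'   `c(0.001, 0.01, 0.1, 0.5, 1)`, the grid used in the lambda ablation.
#' @param n_targets,n_inits_per_target Number of random targets and of
#'   random initial boxes per target.
#' @param stratum Difficulty preset controlling how initial boxes relate to
#'   their targets: `"benign"` (initial IoU >= 0.2, aspect-ratio mismatch
#'   within a factor 2), `"aspect_mismatch"` (overlapping but with ratio
#'   multiplied by up to `aspect_mismatch_factor`), or `"disjoint"`
#'   (initial IoU = 0).
#' @param aspect_mismatch_factor Maximum multiplicative aspect-ratio
#'   mismatch of the `aspect_mismatch` stratum (default 4).
#' @param lr Base step size of the backtracking gradient descent (default
#'   0.05, in the `(cx, cy, log w, log h)` parameter space).
#' @param max_steps Step budget per run (default 1000).
#' @param tol Convergence tolerance: a run stops once `1 - IoU <= tol`
#'   (default 0.01, i.e. IoU >= 0.99).
#' @param seed Integer seed; the whole experiment is deterministic given
#'   the config.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(variants = c("eapiou", "diou", "ciou", "giou"),
                       lambdas = c(0.001, 0.01, 0.1, 0.5, 1),
                       n_targets = 20, n_inits_per_target = 2,
                       stratum = c("benign", "aspect_mismatch", "disjoint"),
                       aspect_mismatch_factor = 4,
                       lr = 0.05, max_steps = 1000, tol = 0.01, seed = 1) {
  stratum <- match.arg(stratum)
  variants <- match.arg(variants, c("eapiou", "ciou", "diou", "giou", "iou"),
                        several.ok = TRUE)
  stopifnot(lr > 0, max_steps >= 1, length(lambdas) >= 1,
            all(lambdas >= 0 & lambdas <= 1), n_targets >= 1,
            n_inits_per_target >= 1, aspect_mismatch_factor >= 1, tol > 0)
  structure(list(variants = variants, lambdas = lambdas,
                 n_targets = n_targets,
                 n_inits_per_target = n_inits_per_target,
                 stratum = stratum,
                 aspect_mismatch_factor = aspect_mismatch_factor,
                 lr = lr, max_steps = max_steps, tol = tol,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %s | lambda in {%s} | %d targets x %d inits (%s stratum) | lr %g, <=%d steps, tol %g, seed %d\n",
              paste(x$variants, collapse = "/"),
              paste(x$lambdas, collapse = ", "),
              x$n_targets, x$n_inits_per_target, x$stratum,
              x$lr, x$max_steps, x$tol, x$seed))
  invisible(x)
}

#' Sample (target, initial box) pairs for the regression experiment
#'
#' Targets have centers in a unit-scale canvas, sizes around 1 and
#' width/height ratios log-uniform in `[1/4, 4]`. Initial boxes are derived
#' by jittering the target's center (by up to half its diagonal), scale
#' (factor in `[0.5, 2]`) and aspect ratio, then rejection-resampled until
#' the stratum's overlap constraint holds.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with one row per (target, init) pair: `target_id`,
#'   `init_id`, target corners `tx1..ty2`, init corners `ix1..iy2`, and the
#'   measured `init_iou`.
#' @export
make_inits <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  rows <- vector("list", cfg$n_targets * cfg$n_inits_per_target)
  idx <- 0L
  for (t in seq_len(cfg$n_targets)) {
    ratio <- exp(stats::runif(1, log(1 / 4), log(4)))
    size <- exp(stats::runif(1, log(0.5), log(2)))
    tw <- size * sqrt(ratio); th <- size / sqrt(ratio)
    tcx <- stats::runif(1, 3, 7); tcy <- stats::runif(1, 3, 7)
    target <- c(tcx - tw / 2, tcy - th / 2, tcx + tw / 2, tcy + th / 2)
    diag_half <- sqrt(tw^2 + th^2) / 2
    for (k in seq_len(cfg$n_inits_per_target)) {
      init <- sample_init(target, tw, th, diag_half, cfg)
      idx <- idx + 1L
      rows[[idx]] <- tibble::tibble(
        target_id = t, init_id = k,
        tx1 = target[1], ty1 = target[2], tx2 = target[3], ty2 = target[4],
        ix1 = init[1], iy1 = init[2], ix2 = init[3], iy2 = init[4],
        init_iou = box_iou(
          tibble::tibble(x1 = init[1], y1 = init[2], x2 = init[3], y2 = init[4]),
          tibble::tibble(x1 = target[1], y1 = target[2], x2 = target[3], y2 = target[4])
        )
      )
    }
  }
  dplyr::bind_rows(rows)
}

sample_init <- function(target, tw, th, diag_half, cfg, max_tries = 500) {
  ratio_mult_range <- switch(cfg$stratum,
    benign = c(1 / 2, 2),
    aspect_mismatch = c(1 / cfg$aspect_mismatch_factor, cfg$aspect_mismatch_factor),
    disjoint = c(1 / 2, 2))
  tgt <- tibble::tibble(x1 = target[1], y1 = target[2],
                        x2 = target[3], y2 = target[4])
  for (try in seq_len(max_tries)) {
    rm <- exp(stats::runif(1, log(ratio_mult_range[1]), log(ratio_mult_range[2])))
    sc <- exp(stats::runif(1, log(0.5), log(2)))
    if (cfg$stratum == "disjoint") {
      # push the center well outside the target
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 2, 4) * diag_half
    } else {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0, 1) * diag_half
    }
    cx <- (target[1] + target[3]) / 2 + rad * cos(ang)
    cy <- (target[2] + target[4]) / 2 + rad * sin(ang)
    w <- tw * sc * sqrt(rm); h <- th * sc / sqrt(rm)
    init <- c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
    iou <- box_iou(tibble::tibble(x1 = init[1], y1 = init[2],
                                  x2 = init[3], y2 = init[4]), tgt)
    ok <- switch(cfg$stratum,
      benign = iou >= 0.2,
      aspect_mismatch = iou > 0,
      disjoint = iou == 0)
    if (ok) return(init)
  }
  stop("could not sample an initial box satisfying the stratum constraint",
       call. = FALSE)
}

#' Gradient-descent regression of one box onto a target
#'
#' Descends the chosen loss in the `(cx, cy, log w, log h)` parameterization
#' with a backtracking line search: each step starts from the base step
#' size and halves it until the loss does not increase, so accepted steps
#' are non-increasing in loss by construction. Stops when `1 - IoU <= tol`,
#' when no decreasing step can be found, or at the step budget.
#'
#' @param init,target Single-row box tibbles (or length-4 corner vectors).
#' @param variant Loss variant (see [loss_config()]).
#' @param lambda Penalty coefficient.
#' @param lr Base step size.
#' @param max_steps Step budget.
#' @param tol Stop when `1 - IoU <= tol`.
#' @param eps Denominator guard.
#' @return A list of class `"box_trajectory"`: `trace` (tibble
#'   `step, loss, iou`), `final_box`, `final_iou`, `converged`,
#'   `steps_to_tol` (`NA` if never reached), `variant`, `lambda`.
#' @export
optimize_box <- function(init, target, variant = "eapiou", lambda = 0.1,
                         lr = 0.05, max_steps = 1000, tol = 0.01,
                         eps = 1e-7) {
  init <- as_corner_vec(init); target <- as_corner_vec(target)
  cfg <- loss_config(variant, lambda = lambda, eps = eps)
  gt <- tibble::tibble(x1 = target[1], y1 = target[2],
                       x2 = target[3], y2 = target[4])
  par <- corners_to_center_log(init)
  cur <- loss_and_grad(par, gt, cfg, "center_log")
  trace_loss <- numeric(max_steps + 1)
  trace_iou <- numeric(max_steps + 1)
  trace_loss[1] <- cur$loss; trace_iou[1] <- cur$iou
  n_rec <- 1L
  steps_to_tol <- if (1 - cur$iou <= tol) 0L else NA_integer_
  if (is.na(steps_to_tol)) {
    for (s in seq_len(max_steps)) {
      step <- lr
      accepted <- FALSE
      for (halving in 1:30) {
        cand <- par - step * cur$gradient
        cl <- loss_and_grad(cand, gt, cfg, "center_log")
        if (cl$loss <= cur$loss) { accepted <- TRUE; break }
        step <- step / 2
      }
      if (!accepted) break
      par <- cand; cur <- cl
      n_rec <- n_rec + 1L
      trace_loss[n_rec] <- cur$loss; trace_iou[n_rec] <- cur$iou
      if (1 - cur$iou <= tol) { steps_to_tol <- s; break }
    }
  }
  final_box <- center_log_to_corners(par)
  structure(list(
    trace = tibble::tibble(step = seq_len(n_rec) - 1L,
                           loss = trace_loss[seq_len(n_rec)],
                           iou = trace_iou[seq_len(n_rec)]),
    final_box = tibble::tibble(x1 = final_box[1], y1 = final_box[2],
                               x2 = final_box[3], y2 = final_box[4]),
    final_iou = cur$iou, final_loss = cur$loss,
    converged = !is.na(steps_to_tol), steps_to_tol = steps_to_tol,
    variant = variant, lambda = lambda
  ), class = "box_trajectory")
}

as_corner_vec <- function(b) {
  if (is.numeric(b) && length(b) == 4) return(as.numeric(b))
  validate_boxes(b, arg = "box")
  if (nrow(b) != 1) stop("expected a single box", call. = FALSE)
  c(b$x1, b$y1, b$x2, b$y2)
}

corners_to_center_log <- function(p) {
  c((p[1] + p[3]) / 2, (p[2] + p[4]) / 2, log(p[3] - p[1]), log(p[4] - p[2]))
}

center_log_to_corners <- function(par) {
  w <- exp(par[3]); h <- exp(par[4])
  c(par[1] - w / 2, par[2] - h / 2, par[1] + w / 2, par[2] + h / 2)
}

#' Run the full loss-comparison regression experiment
#'
#' Sweeps the full factorial of configured variants, lambda values and
#' (target, init) pairs, running [optimize_box()] for each cell, and
#' aggregates convergence statistics per (variant, lambda). Deterministic
#' given the config (including its seed).
#'
#' @param cfg A [sim_config()].
#' @param keep_traces Keep the per-step trajectories (tibble `variant,
#'   lambda, target_id, init_id, step, loss, iou`); default `TRUE`.
#' @return An object of class `"regression_sim"`: a list with `runs` (one
#'   row per run: identifiers, `init_iou`, `final_iou`, `max_iou`,
#'   `final_loss`, `converged`, `steps_to_tol`, `n_steps`), `aggregates` (per
#'   variant/lambda: `mean_final_iou`, `convergence_rate`,
#'   `median_steps_to_tol`), optional `traces`, and `config`.
#' @examples
#' cfg <- sim_config(variants = "eapiou", lambdas = 0.1, n_targets = 2,
#'                   n_inits_per_target = 1, max_steps = 200, seed = 7)
#' sim <- run_box_regression(cfg)
#' glance(sim)
#' @export
run_box_regression <- function(cfg, keep_traces = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  inits <- make_inits(cfg)
  grid <- tidyr::expand_grid(variant = cfg$variants, lambda = cfg$lambdas,
                             pair = seq_len(nrow(inits)))
  run_rows <- vector("list", nrow(grid))
  trace_rows <- if (keep_traces) vector("list", nrow(grid)) else NULL
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- inits[g$pair, ]
    traj <- optimize_box(c(p$ix1, p$iy1, p$ix2, p$iy2),
                         c(p$tx1, p$ty1, p$tx2, p$ty2),
                         variant = g$variant, lambda = g$lambda,
                         lr = cfg$lr, max_steps = cfg$max_steps,
                         tol = cfg$tol)
    run_rows[[i]] <- tibble::tibble(
      variant = g$variant, lambda = g$lambda,
      target_id = p$target_id, init_id = p$init_id,
      init_iou = p$init_iou, final_iou = traj$final_iou,
      max_iou = max(traj$trace$iou),
      final_loss = traj$final_loss, converged = traj$converged,
      steps_to_tol = traj$steps_to_tol, n_steps = nrow(traj$trace) - 1L
    )
    if (keep_traces) {
      trace_rows[[i]] <- dplyr::mutate(traj$trace, variant = g$variant,
                                       lambda = g$lambda,
                                       target_id = p$target_id,
                                       init_id = p$init_id,
                                       .before = 1)
    }
  }
  runs <- dplyr::bind_rows(run_rows)
  aggregates <- runs |>
    dplyr::group_by(.data$variant, .data$lambda) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      mean_final_iou = mean(.data$final_iou),
      convergence_rate = mean(.data$converged),
      median_steps_to_tol = stats::median(.data$steps_to_tol, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean_final_iou))
  structure(list(runs = runs,
                 traces = if (keep_traces) dplyr::bind_rows(trace_rows),
                 aggregates = aggregates, config = cfg),
            class = "regression_sim")
}

#' @export
print.regression_sim <- function(x, ...) {
  cat("<regression_sim> simulated box regression (not a detector benchmark)\n")
  print(x$config)
  print(x$aggregates, n = 10)
  invisible(x)
}

#' Per-run results of a regression simulation
#'
#' @param x A `regression_sim` object.
#' @param ... Unused.
#' @return The `runs` tibble (one row per optimized box).
#' @method tidy regression_sim
#' @export
tidy.regression_sim <- function(x, ...) x$runs

#' Per (variant, lambda) aggregates of a regression simulation
#'
#' @param x A `regression_sim` object.
#' @param ... Unused.
#' @return The `aggregates` tibble, best mean final IoU first.
#' @method glance regression_sim
#' @export
glance.regression_sim <- function(x, ...) x$aggregates

#' Plot convergence of a regression simulation
#'
#' @param object A `regression_sim` object run with `keep_traces = TRUE`.
#' @param ... Unused.
#' @return A ggplot of mean IoU versus step, one line per variant/lambda.
#' @method autoplot regression_sim
#' @export
autoplot.regression_sim <- function(object, ...) {
  if (is.null(object$traces)) {
    stop("run_box_regression() was called with keep_traces = FALSE",
         call. = FALSE)
  }
  df <- object$traces |>
    dplyr::group_by(.data$variant, .data$lambda, .data$step) |>
    dplyr::summarise(mean_iou = mean(.data$iou), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$mean_iou,
                                   colour = .data$variant,
                                   linetype = factor(.data$lambda))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Gradient step", y = "Mean IoU with target",
                  colour = "Loss variant", linetype = "lambda",
                  title = "Simulated box-regression convergence") +
    ggplot2::theme_minimal()
}

#' Write simulation results to CSV
#'
#' Writes the per-run table and the aggregates as plain CSV files whose
#' bytes are reproducible for identical configs.
#'
#' @param sim A `regression_sim` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim_csv <- function(sim, dir) {
  stopifnot(inherits(sim, "regression_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(runs = file.path(dir, "sim_runs.csv"),
             aggregates = file.path(dir, "sim_aggregates.csv"))
  readr::write_csv(sim$runs, paths[["runs"]])
  readr::write_csv(sim$aggregates, paths[["aggregates"]])
  invisible(paths)
}
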