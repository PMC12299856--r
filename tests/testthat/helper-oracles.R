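# Independent oracles used across the suite. Each is written as plain,
# loop-level arithmetic so it shares no code path with the implementation
# it checks.

box1 <- function(x1, y1, x2, y2) {
  tibble::tibble(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
}

# scalar IoU from first principles
iou_scalar <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  inter <- max(iw, 0) * max(ih, 0)
  un <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (un <= 0) 0 else inter / un
}

# term-by-term EAPIoU score, plain arithmetic (Algorithm-style walk)
oracle_eapiou <- function(p, g, lambda = 0.1, eps = 1e-7) {
  w1 <- p[3] - p[1]; h1 <- p[4] - p[2]
  w2 <- g[3] - g[1]; h2 <- g[4] - g[2]
  rho <- ((p[1] + p[3]) / 2 - (g[1] + g[3]) / 2)^2 +
    ((p[2] + p[4]) / 2 - (g[2] + g[4]) / 2)^2
  cw <- max(p[3], g[3]) - min(p[1], g[1])
  ch <- max(p[4], g[4]) - min(p[2], g[2])
  v <- (4 / pi^2) * (atan(w2 / max(h2, eps)) - atan(w1 / max(h1, eps)))^2
  asp <- (w1 / max(h1, eps) - w2 / max(h2, eps))^2
  iou_scalar(p, g) - rho / max(cw^2 + ch^2, eps) - lambda * v - lambda * asp
}

# central finite differences of the loss in either parameterization
fd_grad <- function(par, gt, cfg, param, h_scale = 1e-6) {
  vapply(1:4, function(j) {
    h <- h_scale * max(1, abs(par[j]))
    pp <- par; pp[j] <- par[j] + h
    pm <- par; pm[j] <- par[j] - h
    (loss_and_grad(pp, gt, cfg, param)$loss -
       loss_and_grad(pm, gt, cfg, param)$loss) / (2 * h)
  }, numeric(1))
}

# straight-loop SSE forward pass
oracle_sse_forward <- function(X, w) {
  d <- dim(X); B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  O <- array(0, d)
  S_all <- array(0, c(B, H, W))
  y_all <- matrix(0, B, C)
  k <- w$k; pd <- (k - 1) / 2
  for (b in seq_len(B)) {
    z <- numeric(C)
    for (cc in seq_len(C)) {
      s <- 0
      for (i in seq_len(H)) for (j in seq_len(W)) s <- s + X[b, cc, i, j]
      z[cc] <- s / (H * W)
    }
    nb <- length(w$b1)
    a <- numeric(nb)
    for (u in seq_len(nb)) {
      s <- w$b1[u]
      for (cc in seq_len(C)) s <- s + w$W1[u, cc] * z[cc]
      a[u] <- max(s, 0)
    }
    y <- numeric(C)
    for (cc in seq_len(C)) {
      s <- w$b2[cc]
      for (u in seq_len(nb)) s <- s + w$W2[cc, u] * a[u]
      y[cc] <- 1 / (1 + exp(-s))
    }
    Xp <- array(0, c(C, H, W))
    for (cc in seq_len(C)) for (i in seq_len(H)) for (j in seq_len(W)) {
      Xp[cc, i, j] <- y[cc] * X[b, cc, i, j]
    }
    mo <- matrix(0, H, W); ao <- matrix(0, H, W)
    for (i in seq_len(H)) for (j in seq_len(W)) {
      mx <- -Inf; s <- 0
      for (cc in seq_len(C)) {
        mx <- max(mx, Xp[cc, i, j]); s <- s + Xp[cc, i, j]
      }
      mo[i, j] <- mx; ao[i, j] <- s / C
    }
    for (i in seq_len(H)) for (j in seq_len(W)) {
      acc <- w$spatial_bias
      for (u in seq_len(k)) for (v in seq_len(k)) {
        ii <- i + u - 1 - pd; jj <- j + v - 1 - pd
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
          acc <- acc + w$spatial_kernel[1, 1, u, v] * mo[ii, jj] +
            w$spatial_kernel[1, 2, u, v] * ao[ii, jj]
        }
      }
      s_ij <- 1 / (1 + exp(-acc))
      S_all[b, i, j] <- s_ij
      for (cc in seq_len(C)) O[b, cc, i, j] <- Xp[cc, i, j] * s_ij
    }
    y_all[b, ] <- y
  }
  list(O = O, S = S_all, y = y_all)
}

# naive threshold-by-threshold evaluator: greedy matching and all-point AP
# re-derived with explicit loops
naive_ap <- function(dets, gts, threshold) {
  n_gt <- nrow(gts)
  if (nrow(dets) == 0 || n_gt == 0) return(0)
  ord <- order(dets$confidence, decreasing = TRUE)
  used <- rep(FALSE, n_gt)
  flags <- logical(length(ord))
  det_img <- if ("image_id" %in% names(dets)) dets$image_id else rep(1, nrow(dets))
  gt_img <- if ("image_id" %in% names(gts)) gts$image_id else rep(1, n_gt)
  for (kk in seq_along(ord)) {
    i <- ord[kk]
    best <- -1; bj <- 0
    for (j in seq_len(n_gt)) {
      if (used[j] || det_img[i] != gt_img[j]) next
      ov <- iou_scalar(c(dets$x1[i], dets$y1[i], dets$x2[i], dets$y2[i]),
                       c(gts$x1[j], gts$y1[j], gts$x2[j], gts$y2[j]))
      if (ov > best) { best <- ov; bj <- j }
    }
    if (bj > 0 && best >= threshold) { flags[kk] <- TRUE; used[bj] <- TRUE }
  }
  tp <- cumsum(flags)
  prec <- tp / seq_along(flags)
  rec <- tp / n_gt
  env <- numeric(length(prec)); mx <- 0
  for (kk in rev(seq_along(prec))) { mx <- max(mx, prec[kk]); env[kk] <- mx }
  ap <- 0; prev <- 0
  for (kk in seq_along(rec)) { ap <- ap + (rec[kk] - prev) * env[kk]; prev <- rec[kk] }
  ap
}
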