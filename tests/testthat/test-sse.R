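test_that("global average pooling squeezes channels correctly", {
  X <- gen_feature_map(2, 3, 4, 4, distribution = "constant", value = 3)
  expect_equal(global_avg_pool(X), matrix(3, 2, 3))
  X2 <- array(0, dim = c(1, 1, 2, 2))
  X2[1, 1, , ] <- matrix(c(0, 1, 2, 3), 2, 2)
  expect_equal(as.numeric(global_avg_pool(X2)), 1.5)
  # channel permutation permutes z identically
  X3 <- gen_feature_map(1, 4, 3, 3, seed = 2)
  perm <- c(3, 1, 4, 2)
  expect_equal(global_avg_pool(X3[, perm, , , drop = FALSE]),
               global_avg_pool(X3)[, perm, drop = FALSE])
})

test_that("channel excitation follows the bottleneck sigmoid form", {
  w <- sse_weights(6, r = 2, k = 3, seed = 1)
  z <- matrix(rnorm(12), 2, 6)
  w0 <- w; w0$W1[] <- 0; w0$W2[] <- 0
  expect_equal(channel_excitation(z, w0), matrix(0.5, 2, 6))
  wb <- w0; wb$b2 <- rep(50, 6)
  expect_true(all(channel_excitation(z, wb) > 1 - 1e-12))
  # element-by-element loop oracle
  y <- channel_excitation(z, w)
  for (b in 1:2) {
    a <- pmax(w$W1 %*% z[b, ] + w$b1, 0)
    expect_equal(y[b, ], as.numeric(1 / (1 + exp(-(w$W2 %*% a + w$b2)))),
                 tolerance = 1e-12)
  }
  expect_error(channel_excitation(matrix(0, 1, 5), w), "channels")
})

test_that("channel recalibration is exact elementwise gating", {
  X <- gen_feature_map(2, 3, 4, 5, seed = 3)
  expect_identical(channel_recalibrate(X, matrix(1, 2, 3)), X)
  expect_equal(channel_recalibrate(X, matrix(0.5, 2, 3)), X / 2)
  y <- matrix(runif(6), 2, 3)
  got <- channel_recalibrate(X, y)
  for (b in 1:2) for (cc in 1:3) for (i in 1:4) for (j in 1:5) {
    expect_identical(got[b, cc, i, j], y[b, cc] * X[b, cc, i, j])
  }
})

test_that("spatial attention map reduces channels and convolves correctly", {
  # single channel: both descriptors equal the (squeezed) map
  X <- gen_feature_map(1, 1, 4, 4, seed = 4)
  w <- sse_weights(1, r = 1, k = 3, seed = 5)
  sp <- spatial_attention_map(X, w$spatial_kernel, w$spatial_bias)
  expect_equal(sp$max_out[1, , ], array(X[1, 1, , ], dim = c(4, 4)))
  expect_equal(sp$avg_out[1, , ], array(X[1, 1, , ], dim = c(4, 4)))
  # zero kernel and bias give the indifferent map
  k0 <- array(0, dim = c(1, 2, 3, 3))
  expect_equal(spatial_attention_map(X, k0, 0)$S, array(0.5, c(1, 4, 4)))
  # even kernel size rejected
  expect_error(spatial_attention_map(X, array(0, c(1, 2, 4, 4)), 0), "odd")
})

test_that("full forward pass matches the straight-loop oracle on seeded tensors", {
  set.seed(20)
  dims <- tibble::tibble(B = sample(1:2, 50, TRUE), C = sample(1:8, 50, TRUE),
                         H = sample(2:6, 50, TRUE), W = sample(2:6, 50, TRUE))
  for (i in seq_len(50)) {
    X <- gen_feature_map(dims$B[i], dims$C[i], dims$H[i], dims$W[i],
                         seed = 1000 + i)
    w <- sse_weights(dims$C[i], r = sample(c(1, 2, 4, 16), 1),
                     k = sample(c(3, 5, 7), 1), seed = 2000 + i)
    got <- sse_forward(X, w)
    ora <- oracle_sse_forward(X, w)
    expect_equal(got$O, ora$O, tolerance = 1e-12)
    expect_equal(got$S, ora$S, tolerance = 1e-12)
    expect_equal(got$y, ora$y, tolerance = 1e-12)
    # contraction and open-interval gates
    expect_true(all(abs(got$O) <= abs(X)))
    expect_true(all(got$y > 0 & got$y < 1))
    expect_true(all(got$S > 0 & got$S < 1))
  }
})

test_that("all-zero weights give the closed-form double half-gate", {
  X <- gen_feature_map(2, 4, 5, 5, seed = 9)
  w <- sse_weights(4, r = 2, k = 7, seed = 10)
  w$W1[] <- 0; w$b1[] <- 0; w$W2[] <- 0; w$b2[] <- 0
  w$spatial_kernel[] <- 0; w$spatial_bias <- 0
  out <- sse_forward(X, w)
  expect_equal(out$O, 0.25 * X, tolerance = 1e-14)
  X0 <- gen_feature_map(1, 3, 4, 4, distribution = "constant", value = 0)
  out0 <- sse_forward(X0, sse_weights(3, r = 1, k = 3, seed = 2))
  expect_equal(out0$O, X0)
})

test_that("output shape is preserved for every supported kernel size", {
  X <- gen_feature_map(1, 3, 6, 8, seed = 6)
  for (k in c(3, 5, 7, 9, 11)) {
    out <- sse_forward(X, sse_weights(3, r = 1, k = k, seed = k))
    expect_identical(dim(out$O), dim(X))
    expect_identical(dim(out$S), c(1L, 6L, 8L))
  }
  expect_error(sse_weights(3, k = 4), "odd")
})

test_that("spatial branch is translation-equivariant away from borders", {
  H <- 12; W <- 12; k <- 5
  X <- gen_feature_map(1, 3, H, W, seed = 42)
  w <- sse_weights(3, r = 1, k = k, seed = 43)
  # shift the recalibrated input down by one pixel (zero-fill at the top)
  Xs <- X
  Xs[1, , 2:H, ] <- X[1, , 1:(H - 1), ]
  Xs[1, , 1, ] <- 0
  # bypass the channel branch so the shift reaches the spatial branch intact
  S1 <- spatial_attention_map(X, w$spatial_kernel, w$spatial_bias)$S
  S2 <- spatial_attention_map(Xs, w$spatial_kernel, w$spatial_bias)$S
  m <- (k - 1) / 2 + 1   # border band plus the shift margin
  inner_r <- (m + 1):(H - m)
  inner_c <- (m + 1):(W - m)
  expect_equal(S2[1, inner_r + 1, inner_c], S1[1, inner_r, inner_c],
               tolerance = 1e-12)
})

test_that("channel permutation permutes X' and leaves S unchanged", {
  C <- 6
  X <- gen_feature_map(1, C, 5, 5, seed = 77)
  w <- sse_weights(C, r = 2, k = 3, seed = 78)
  perm <- c(4, 2, 6, 1, 3, 5)
  wp <- w
  wp$W1 <- w$W1[, perm]
  wp$W2 <- w$W2[perm, ]
  wp$b2 <- w$b2[perm]
  out <- sse_forward(X, w)
  outp <- sse_forward(X[, perm, , , drop = FALSE], wp)
  expect_equal(outp$Xp, out$Xp[, perm, , , drop = FALSE], tolerance = 1e-12)
  expect_equal(outp$S, out$S, tolerance = 1e-12)
})
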