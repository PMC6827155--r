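test_that("select_layers returns exactly C2..C5 and names missing levels", {
  pyr <- random_pyramid(seed = 1)
  extra <- c(list(C1 = feature_map(array(0, c(16, 16, 4)), 2)), pyr)
  sel <- select_layers(extra)
  expect_identical(names(sel), paste0("C", 2:5))
  expect_error(select_layers(pyr[c("C3", "C4", "C5")]), "C2")
})

test_that("demo backbone produces correctly strided, deterministic pyramids", {
  img <- matrix(runif(256 * 256, 0, 255), 256, 256)
  pyr <- demo_backbone(img, seed = 2)
  strides <- vapply(pyr, `[[`, integer(1), "stride")
  expect_identical(unname(strides), c(4L, 8L, 16L, 32L))
  expect_identical(dim(pyr$C2$data)[1:2], c(64L, 64L))
  expect_identical(dim(pyr$C5$data)[1:2], c(8L, 8L))
  pyr2 <- demo_backbone(img, seed = 2)
  expect_identical(pyr, pyr2)
})

test_that("1x1 projection matches the per-cell matrix-multiply oracle", {
  set.seed(3)
  map <- feature_map(array(rnorm(4 * 5 * 6), c(4, 5, 6)), 3)
  W <- matrix(rnorm(8 * 6), 8, 6)
  out <- project_channels(map, 8, W)
  expect_identical(dim(out$data), c(4L, 5L, 8L))
  for (y in 1:4) for (x in 1:5)
    expect_equal(out$data[y, x, ], as.numeric(W %*% map$data[y, x, ]))
  # identity projection is exact
  id <- project_channels(map, 6, diag(6))
  expect_equal(id$data, map$data)
})

test_that("bilinear upsampling is exact on constants, 1x1 maps, and the closed form", {
  const <- feature_map(array(3.5, c(4, 4, 2)), 3)
  up <- upsample_to(const, c(8, 8))
  expect_true(all(abs(up$data - 3.5) < 1e-12))

  one <- feature_map(array(2, c(1, 1, 1)), 5)
  four <- upsample_to(one, c(2, 2), level = 4)
  expect_true(all(four$data == 2))

  set.seed(4)
  src <- feature_map(array(rnorm(4 * 4 * 3), c(4, 4, 3)), 3)
  up2 <- upsample_to(src, c(8, 8))
  # closed-form check at arbitrary cells (half-pixel-centre convention)
  for (cell in list(c(1, 1), c(5, 3), c(8, 8), c(4, 7))) {
    y <- cell[1]; x <- cell[2]
    sy <- min(max((y - 0.5) * 0.5 - 0.5, 0), 3)
    sx <- min(max((x - 0.5) * 0.5 - 0.5, 0), 3)
    y0 <- floor(sy); x0 <- floor(sx)
    y1 <- min(y0 + 1, 3); x1 <- min(x0 + 1, 3)
    wy <- sy - y0; wx <- sx - x0
    ref <- (1 - wy) * (1 - wx) * src$data[y0 + 1, x0 + 1, ] +
           (1 - wy) * wx * src$data[y0 + 1, x1 + 1, ] +
           wy * (1 - wx) * src$data[y1 + 1, x0 + 1, ] +
           wy * wx * src$data[y1 + 1, x1 + 1, ]
    expect_equal(up2$data[y, x, ], ref)
  }
  expect_error(upsample_to(src, c(2, 2)), "upsampler")
})

test_that("layer fusion is the stated weighted sum with identity cases exact", {
  set.seed(5)
  f <- feature_map(array(rnorm(6 * 6 * 8), c(6, 6, 8)), 2)
  g <- feature_map(array(rnorm(6 * 6 * 8), c(6, 6, 8)), 2)
  expect_identical(layer_fuse(f, g, layer_fusion_params(1, 0))$data, f$data)
  zero <- feature_map(array(0, dim(f$data)), 2)
  expect_identical(layer_fuse(zero, g, layer_fusion_params(1, 1))$data, g$data)
  mix <- layer_fuse(f, g, layer_fusion_params(0.3, 0.7))
  expect_equal(mix$data, 0.3 * f$data + 0.7 * g$data)
  # homogeneity
  a <- 2.5
  scaled <- layer_fuse(feature_map(a * f$data, 2), feature_map(a * g$data, 2),
                       layer_fusion_params(0.3, 0.7))
  expect_equal(scaled$data, a * mix$data)
  expect_error(layer_fuse(f, feature_map(array(0, c(3, 3, 8)), 2)),
               "identical shapes")
})

test_that("global average pooling equals per-channel means", {
  arr <- array(0, c(2, 2, 2))
  arr[, , 1] <- 7
  arr[, , 2] <- matrix(c(1, 3, 2, 4), 2, 2)  # (1,2;3,4) column-major
  z <- global_avg_pool(feature_map(arr, 2))
  expect_equal(z, c(7, 2.5))
  set.seed(6)
  rnd <- array(rnorm(3 * 5 * 4), c(3, 5, 4))
  expect_equal(global_avg_pool(rnd),
               vapply(1:4, function(k) mean(rnd[, , k]), numeric(1)))
})

test_that("channel attention weights form a softmax distribution with the stated limits", {
  set.seed(7)
  map <- feature_map(array(rnorm(4 * 4 * 16), c(4, 4, 16)), 2)
  zero <- channel_attn_params(16, zero = TRUE)
  w0 <- channel_attention_weights(map, zero)
  expect_equal(w0, rep(1 / 16, 16))
  out0 <- channel_fuse(map, zero)
  expect_equal(out0$data, map$data / 16)

  # saturation: one dominant logit keeps (almost) only its channel
  sat <- channel_attn_params(16, zero = TRUE)
  sat$W1[1, ] <- 1e3; sat$W2[3, 1] <- 1e3
  z <- global_avg_pool(map)
  if (sum(z) < 0) sat$W1[1, ] <- -1e3  # ensure positive pre-activation
  ws <- channel_attention_weights(map, sat)
  expect_gt(ws[3], 1 - 1e-6)

  # random parameters: match the explicit pool->FC->ReLU->FC->softmax oracle
  for (s in 1:5) {
    p <- channel_attn_params(16, seed = s)
    wts <- channel_attention_weights(map, p)
    expect_equal(sum(wts), 1, tolerance = 1e-12)
    u <- pmax(p$W1 %*% z, 0)
    v <- as.numeric(p$W2 %*% u)
    ref <- exp(v - max(v)) / sum(exp(v - max(v)))
    expect_equal(wts, ref)
    out <- channel_fuse(map, p)
    for (k in c(1, 9, 16))
      expect_equal(out$data[, , k], map$data[, , k] * wts[k])
  }
  expect_error(channel_attn_params(12), "divisible by 8")
})

test_that("build_fused_map matches the straight-line oracle and shape arithmetic", {
  pyr <- random_pyramid(h2 = 8, w2 = 8, seed = 8)
  params <- init_fusion_params(pyr, out_c = 16, seed = 3)
  out <- build_fused_map(pyr, params)
  expect_identical(dim(out$data), c(8L, 8L, 16L))
  expect_identical(out$stride, 4L)
  ref <- oracle_fused_map(pyr, params)
  expect_equal(out$data, ref, tolerance = 1e-12)
  # bit-stable across runs
  expect_identical(out$data, build_fused_map(pyr, params)$data)

  # pass-through case: alpha = (1, 0), identity projections, no attention
  pyr_eq <- random_pyramid(h2 = 8, w2 = 8, channels = c(16, 16, 16, 16),
                           seed = 9)
  p2 <- init_fusion_params(pyr_eq, out_c = 16, seed = 1,
                           with_attention = FALSE)
  for (l in 2:5) p2$projections[[paste0("C", l)]] <- diag(16)
  for (l in 2:4) p2$fusion[[paste0("C", l)]] <- layer_fusion_params(1, 0)
  expect_equal(build_fused_map(pyr_eq, p2)$data, pyr_eq$C2$data)

  # full-image demo: 256 px input fuses to a 64 x 64 map at stride 4
  img <- matrix(runif(256 * 256, 0, 255), 256, 256)
  pyrd <- demo_backbone(img, seed = 1)
  outd <- build_fused_map(pyrd, init_fusion_params(pyrd, out_c = 32, seed = 1))
  expect_identical(dim(outd$data), c(64L, 64L, 32L))
})

test_that("analytic junction gradients match central finite differences", {
  set.seed(10)
  f <- feature_map(array(rnorm(4 * 4 * 8), c(4, 4, 8)), 2)
  g <- feature_map(array(rnorm(4 * 4 * 8), c(4, 4, 8)), 2)
  fp <- layer_fusion_params(0.8, 1.2)
  ap <- channel_attn_params(8, seed = 2)
  gr <- junction_gradients(f, g, fp, ap)

  loss_at <- function(a1, a2, W1, W2) {
    jf <- layer_fuse(f, g, layer_fusion_params(a1, a2))
    sum(channel_fuse(jf, structure(list(W1 = W1, W2 = W2),
                                   class = "channel_attn_params"))$data)
  }
  eps <- 1e-5
  fd_a1 <- (loss_at(fp$alpha1 + eps, fp$alpha2, ap$W1, ap$W2) -
            loss_at(fp$alpha1 - eps, fp$alpha2, ap$W1, ap$W2)) / (2 * eps)
  fd_a2 <- (loss_at(fp$alpha1, fp$alpha2 + eps, ap$W1, ap$W2) -
            loss_at(fp$alpha1, fp$alpha2 - eps, ap$W1, ap$W2)) / (2 * eps)
  expect_lt(abs(fd_a1 - gr$alpha1) / max(abs(fd_a1), 1e-8), 1e-4)
  expect_lt(abs(fd_a2 - gr$alpha2) / max(abs(fd_a2), 1e-8), 1e-4)

  # spot-check bottleneck matrix entries
  set.seed(11)
  for (probe in 1:6) {
    i <- sample(nrow(ap$W1), 1); j <- sample(ncol(ap$W1), 1)
    W1p <- ap$W1; W1p[i, j] <- W1p[i, j] + eps
    W1m <- ap$W1; W1m[i, j] <- W1m[i, j] - eps
    fd <- (loss_at(fp$alpha1, fp$alpha2, W1p, ap$W2) -
           loss_at(fp$alpha1, fp$alpha2, W1m, ap$W2)) / (2 * eps)
    expect_lt(abs(fd - gr$W1[i, j]) / max(abs(fd), 1e-6), 1e-4)

    i2 <- sample(nrow(ap$W2), 1); j2 <- sample(ncol(ap$W2), 1)
    W2p <- ap$W2; W2p[i2, j2] <- W2p[i2, j2] + eps
    W2m <- ap$W2; W2m[i2, j2] <- W2m[i2, j2] - eps
    fd2 <- (loss_at(fp$alpha1, fp$alpha2, ap$W1, W2p) -
            loss_at(fp$alpha1, fp$alpha2, ap$W1, W2m)) / (2 * eps)
    expect_lt(abs(fd2 - gr$W2[i2, j2]) / max(abs(fd2), 1e-6), 1e-4)
  }
})
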