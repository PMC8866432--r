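test_that("attention gate follows the additive-gate arithmetic exactly", {
  set.seed(1)
  H <- 6; W <- 5; cl <- 4; ch <- 3
  xl <- array(rnorm(H * W * cl), c(H, W, cl))
  xh <- array(rnorm(H * W * ch), c(H, W, ch))
  Wg <- ag_weights(cl, ch)
  g <- attention_gate(xl, xh, Wg)
  XL <- matrix(xl, ncol = cl); XH <- matrix(xh, ncol = ch)
  A <- sweep(XL %*% Wg$Wl + XH %*% Wg$Wh, 2, Wg$ba, `+`)
  phi <- 1 / (1 + exp(-(pmax(A, 0) %*% Wg$wpsi + Wg$bpsi)))
  expect_equal(as.numeric(g$phi), as.numeric(phi), tolerance = 1e-12)
  expect_equal(matrix(g$x_l_hat, ncol = cl), XL * as.vector(phi),
               tolerance = 1e-12)
  expect_true(all(g$phi > 0 & g$phi < 1))
  expect_true(all(abs(g$x_l_hat) <= abs(xl) + 1e-12))
  expect_error(attention_gate(xl, array(0, c(3, 3, 2)), Wg), "shape")
})

test_that("gate saturates to identity or suppression in the weight limits", {
  set.seed(2)
  xl <- array(rnorm(32), c(4, 4, 2))
  xh <- array(rnorm(16), c(4, 4, 1))
  Wg <- ag_weights(2, 1)
  Wg$bpsi <- 40
  up <- attention_gate(xl, xh, Wg)
  expect_equal(up$x_l_hat, xl, tolerance = 1e-8)
  Wg$bpsi <- -40
  dn <- attention_gate(xl, xh, Wg)
  expect_lt(max(abs(dn$x_l_hat)), 1e-8)
})

test_that("texture attention block reduces to the plain gate when texture is dead", {
  set.seed(3)
  xl <- array(rnorm(96), c(6, 4, 4))
  xh <- array(rnorm(48), c(6, 4, 2))
  tx <- array(0, c(6, 4, 3))
  Wt <- ag_weights(4, 5)
  tb <- texture_attention_block(xl, xh, tx, Wt, upsample = FALSE)
  Wp <- Wt
  Wp$Wh <- Wt$Wh[1:2, , drop = FALSE]
  plain <- attention_gate(xl, xh, Wp)
  expect_equal(tb$x_l_hat, plain$x_l_hat, tolerance = 1e-12)
  expect_equal(dim(tb$x_h_new)[3], 5)
  expect_equal(dim(tb$output), c(6L, 4L, 9L))
  up <- texture_attention_block(xl, xh, tx, Wt, upsample = TRUE)
  expect_equal(dim(up$output), c(12L, 8L, 9L))
  expect_error(texture_attention_block(xl, xh, array(0, c(3, 3, 1)), Wt),
               "shape")
})

test_that("networks emit per-pixel probabilities and enforce the shape contract", {
  net <- build_attention_unet(c(4, 8, 16, 16, 16), seed = 4)
  x <- array(rnorm(96 * 96), c(96, 96, 1))
  p <- segnet_forward(net, x)
  expect_equal(dim(p), c(96L, 96L, 3L))
  expect_equal(range(apply(p, c(1, 2), sum)), c(1, 1), tolerance = 1e-9)
  expect_error(segnet_forward(net, array(0, c(100, 96, 1))), "shape error")
  tau <- build_tau_net(c(4, 8, 16, 16, 16), seed = 5)
  tx <- list(sift = array(rnorm(24 * 24 * 128), c(24, 24, 128)),
             lbp = array(rnorm(96 * 96), c(96, 96, 1)))
  p2 <- segnet_forward(tau, x, tx)
  expect_equal(dim(p2), c(96L, 96L, 3L))
  expect_error(segnet_forward(tau, x), "texture")
})

test_that("parameter count matches a layer-by-layer hand count", {
  w <- c(4, 8, 16, 16, 16)
  net <- build_attention_unet(w, in_ch = 1, n_classes = 3, seed = 6)
  cb <- function(cin, cout) (9 * cin * cout + cout) + (9 * cout * cout + cout) +
    4 * cout  # two convs + two norm layers (gain, bias)
  enc <- cb(1, w[1]) + cb(w[1], w[2]) + cb(w[2], w[3]) + cb(w[3], w[4]) +
    cb(w[4], w[5])
  dec <- 0
  for (l in 4:1) {
    fint <- max(1, w[l] %/% 2)
    up <- 4 * w[l + 1] * w[l] + w[l]
    ag <- w[l] * fint + w[l] * fint + fint + fint + 1
    dec <- dec + up + ag + cb(2 * w[l], w[l])
  }
  head <- w[1] * 3 + 3
  expect_equal(param_count(net), enc + dec + head)
})

test_that("TAU-Net with zeroed texture path reproduces the Attention U-Net", {
  w <- c(4, 8, 16, 16, 16)
  aun <- build_attention_unet(w, seed = 7)
  tau <- transfer_aunet_to_tau(aun, build_tau_net(w, seed = 8))
  tx0 <- list(sift = array(0, c(16, 16, 128)), lbp = array(0, c(64, 64, 1)))
  set.seed(9)
  for (i in 1:3) {
    x <- array(rnorm(64 * 64), c(64, 64, 1))
    expect_lt(max(abs(segnet_forward(aun, x) -
                      segnet_forward(tau, x, tx0))), 1e-6)
  }
})

test_that("hybrid fuser: identity at average init, normalization, conv oracle", {
  f <- build_hybrid_fuser("average")
  set.seed(10)
  pa <- rand_probs(6, 6, 3, seed = 10)
  pa <- array(pa, c(6, 6, 1, 3))
  out <- fuse(pa, pa, f)
  expect_lt(max(abs(out - pa)), 1e-6)
  # random kernel: per-voxel sum 1 and equality with a direct convolution
  fr <- build_hybrid_fuser("random", seed = 11)
  pb <- array(rand_probs(6, 6, 3, seed = 12), c(6, 6, 1, 3))
  o2 <- fuse(pa, pb, fr)
  expect_equal(range(apply(o2, 1:3, sum)), c(1, 1), tolerance = 1e-9)
  # direct 3D convolution oracle at one interior voxel
  stacked <- array(c(pa, pb), c(6, 6, 1, 6))
  wk <- fr$params$w
  acc <- fr$params$b
  for (ci in 1:6) for (kz in 1:3) for (ky in 1:3) for (kx in 1:3) {
    xi <- 3 + kx - 2; yi <- 3 + ky - 2; zi <- 1 + kz - 2
    v <- if (zi >= 1 && zi <= 1) stacked[xi, yi, zi, ci] else 0
    acc <- acc + v * wk[kx, ky, kz, ci, ]
  }
  r <- pmax(acc, 0) + 1e-8
  expect_equal(as.numeric(o2[3, 3, 1, ]), r / sum(r), tolerance = 1e-9)
  expect_error(fuse(pa, array(0, c(5, 6, 1, 3)), fr), "shape")
})

test_that("networks train: loss halves within 100 steps on one slice", {
  ph <- generate_phantom(tiny_phantom_config(seed = 21))
  v <- preprocess(ph$image)
  z <- which.max(apply(ph$labels$labels == 2, 3, sum))
  x <- array(v$voxels[1:64, 1:64, z], c(64, 64, 1))
  U <- one_hot(ph$labels$labels[1:64, 1:64, z], 3)
  net <- build_attention_unet(c(4, 8, 16, 16, 16), seed = 22)
  net <- train_segnet(net, list(list(x = x, U = U, tx = NULL)),
                      steps = 100, batch_size = 1, lr = 1e-2, seed = 23)
  first <- mean(net$loss_history[1:5])
  last <- mean(tail(net$loss_history, 5))
  expect_lt(last, 0.5 * first)
})
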