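test_that("WPCE weights follow the background-to-class ratio", {
  lab <- matrix(c(rep(1, 4), rep(0, 12)), 4, 4)
  U <- one_hot(lab, 2)
  # perfect prediction gives (near) zero loss
  V <- pmin(pmax(U, 1e-7), 1 - 1e-7)
  expect_lt(wpce(U, V), 1e-5)
  # forced uniform weights reduce to plain cross entropy
  set.seed(1)
  Vr <- rand_probs(4, 4, 2, seed = 1)
  plain <- -mean(rowSums(matrix(U, ncol = 2) * log(matrix(Vr, ncol = 2))))
  expect_equal(wpce(U, Vr, weights = c(1, 1)), plain)
  # n_B = 12, n_c = 4 => the class term is scaled by 3
  w3 <- wpce(U, Vr)
  only_cls <- -sum(matrix(U, ncol = 2)[, 2] * log(matrix(Vr, ncol = 2)[, 2])) / 16
  only_bg <- -sum(matrix(U, ncol = 2)[, 1] * log(matrix(Vr, ncol = 2)[, 1])) / 16
  expect_equal(w3, only_bg + 3 * only_cls)
  # absent class gets weight zero with a warning
  lab0 <- matrix(0, 4, 4)
  expect_warning(w <- wpce(one_hot(lab0, 2), Vr), "absent")
  expect_true(is.finite(w))
})

test_that("GDL matches hand evaluation and is bounded", {
  Ub <- matrix(0, 4, 4); Ub[1:2, 1:2] <- 1
  Vb <- matrix(0, 4, 4); Vb[2:3, 1:2] <- 1
  # |U| = 4, |V| = 4, overlap 2, W = 1/16, eps = 0
  expect_equal(gdl(Ub, Vb, eps = 0), 1 - 2 * (2 / 16) / (8 / 16))
  # perfect overlap -> ~0; disjoint -> ~1
  expect_lt(gdl(Ub, Ub, eps = 1e-5), 1e-6)
  Vd <- matrix(0, 4, 4); Vd[3:4, 3:4] <- 1
  expect_gt(gdl(Ub, Vd, eps = 1e-5), 1 - 1e-3)
  expect_lte(gdl(Ub, Vd), 1)
  expect_gte(gdl(Ub, Ub), 0)
})

test_that("GDL never increases as overlap grows (nested predictions)", {
  set.seed(2)
  U <- matrix(0, 12, 12); U[4:9, 4:9] <- 1
  prev <- Inf
  for (k in 0:6) {
    V <- matrix(0, 12, 12)
    if (k > 0) V[4:(3 + k), 4:9] <- 1
    val <- gdl(U, V)
    expect_lte(val, prev + 1e-12)
    prev <- val
  }
})

test_that("boundary extraction marks the inner band", {
  # centered 2x2 square in 4x4: all four foreground pixels are boundary
  U <- matrix(0, 4, 4); U[2:3, 2:3] <- 1
  expect_equal(extract_boundary(U, 3), U)
  # a filled mask has no boundary (no complement to dilate inward)
  expect_true(all(extract_boundary(matrix(1, 6, 6), 3) == 0))
  expect_error(extract_boundary(matrix(0.5, 3, 3), 3), "domain error")
  # interior erodes away: 4x4 block keeps only its ring
  U2 <- matrix(0, 8, 8); U2[3:6, 3:6] <- 1
  b <- extract_boundary(U2, 3)
  expect_equal(sum(b), 12)
  expect_equal(b[4:5, 4:5], matrix(0, 2, 2))
})

test_that("boundary-F1 loss: identity, 1-pixel shift forgiveness, far miss", {
  U <- matrix(0, 16, 16); U[5:8, 5:8] <- 1
  expect_equal(boundary_f1_loss(U, U, 3, 3), 0)
  V1 <- matrix(0, 16, 16); V1[6:9, 5:8] <- 1
  expect_equal(boundary_f1_loss(U, V1, 3, 3), 0)
  V5 <- matrix(0, 16, 16); V5[10:13, 5:8] <- 1
  expect_equal(boundary_f1_loss(U, V5, 3, 3), 1)
  expect_warning(r <- boundary_f1_loss(matrix(0, 8, 8), V1[1:8, 1:8]),
                 "empty")
  expect_true(is.na(r))
})

test_that("total loss composes the three terms with 0.33 weights", {
  set.seed(3)
  lab <- rand_label_slice(12, 12, 3, seed = 3)
  U <- one_hot(lab, 3)
  V <- rand_probs(12, 12, 3, seed = 4)
  w <- suppressWarnings(wpce(U, V))
  g <- gdl(U, V)
  b <- suppressWarnings(boundary_f1_loss(U, V))
  expect_equal(suppressWarnings(total_loss(U, V)),
               0.33 * w + 0.33 * g + 0.33 * b)
  # components (1,1,1) would sum to 0.99 by the printed weights
  expect_equal(sum(c(0.33, 0.33, 0.33) * c(1, 1, 1)), 0.99)
  # V = U: total vanishes up to the smoothing terms
  Vu <- pmin(pmax(U, 1e-7), 1 - 1e-7)
  expect_lt(total_loss(U, Vu), 1e-5)
})

test_that("loss gradients agree with central differences", {
  lab <- rand_label_slice(16, 16, 3, seed = 5)
  U <- one_hot(lab, 3)
  set.seed(6)
  V <- array(runif(16 * 16 * 3, 0.05, 0.95), c(16, 16, 3))
  h <- 1e-6
  for (fn in list(
    list(f = function(V) wpce(U, V), g = function(V) wpce(U, V, with_grad = TRUE)$grad),
    list(f = function(V) gdl(U, V), g = function(V) gdl(U, V, with_grad = TRUE)$grad),
    list(f = function(V) boundary_f1_loss(U, V),
         g = function(V) boundary_f1_loss(U, V, with_grad = TRUE)$grad))) {
    grad <- fn$g(V)
    for (t in 1:25) {
      i <- sample(length(V), 1)
      Vp <- V; Vp[i] <- Vp[i] + h
      Vm <- V; Vm[i] <- Vm[i] - h
      num <- (fn$f(Vp) - fn$f(Vm)) / (2 * h)
      expect_lt(abs(num - grad[i]) / max(1, abs(num)), 1e-3)
    }
  }
})
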