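test_that("confusion counts match an exhaustive loop on random masks", {
  set.seed(1)
  for (i in 1:20) {
    U <- array(runif(512) < 0.3, c(8, 8, 8))
    V <- array(runif(512) < 0.3, c(8, 8, 8))
    cc <- confusion_counts(U, V)
    tp <- fp <- fn <- tn <- 0L
    for (j in seq_along(U)) {
      if (U[j] && V[j]) tp <- tp + 1L
      else if (!U[j] && V[j]) fp <- fp + 1L
      else if (U[j] && !V[j]) fn <- fn + 1L
      else tn <- tn + 1L
    }
    expect_identical(unlist(cc), c(tp = tp, fp = fp, fn = fn, tn = tn))
    # F1 of (precision, recall) equals Dice
    P <- precision(U, V); R <- recall(U, V)
    if (P + R > 0)
      expect_equal(dice(U, V), 2 * P * R / (P + R))
    expect_equal(dice(U, V), dice(V, U))
  }
})

test_that("dice/recall/precision handle identities and degenerate masks", {
  U <- c(1, 1, 1, 0); V <- c(1, 1, 0, 0)
  expect_equal(dice(U, V), 2 * 2 / (3 + 2))
  M <- array(c(1, 0, 0, 0), c(2, 2, 1))
  expect_equal(dice(M, M), 1)
  expect_equal(recall(M, M), 1)
  expect_equal(precision(M, M), 1)
  D <- array(c(0, 1, 0, 0), c(2, 2, 1))
  expect_equal(dice(M, D), 0)
  Z <- array(0, c(2, 2, 1))
  expect_equal(dice(Z, Z), 1)   # both empty
  expect_equal(dice(Z, D), 0)   # empty GT, non-empty prediction
  expect_equal(recall(Z, D), 1)
  expect_equal(precision(D, Z), 1)
})

test_that("hd95 equals closed-form distances and the all-pairs oracle", {
  u <- array(0, c(9, 9, 9)); u[2, 2, 2] <- 1
  v <- array(0, c(9, 9, 9)); v[7, 2, 2] <- 1
  expect_equal(hd95(u, v, c(2, 1, 1)), 10)
  expect_equal(hd95(u, u, c(1, 1, 1)), 0)
  expect_warning(na <- hd95(u, array(0, c(9, 9, 9))), "empty")
  expect_true(is.na(na))

  surface_oracle <- function(m) {
    idx <- which(m != 0, arr.ind = TRUE)
    keep <- logical(nrow(idx))
    d <- dim(m)
    for (r in seq_len(nrow(idx))) {
      p <- idx[r, ]
      for (ax in 1:3) for (s in c(-1, 1)) {
        q <- p; q[ax] <- q[ax] + s
        if (any(q < 1) || any(q > d) || m[q[1], q[2], q[3]] == 0) {
          keep[r] <- TRUE
        }
      }
    }
    idx[keep, , drop = FALSE]
  }
  set.seed(2)
  for (i in 1:30) {
    U <- array(runif(216) < 0.25, c(6, 6, 6))
    V <- array(runif(216) < 0.25, c(6, 6, 6))
    if (sum(U) == 0 || sum(V) == 0) next
    sp <- c(1.5, 1, 2)
    got <- hd95(U, V, sp)
    su <- sweep(surface_oracle(U) - 1, 2, sp, `*`)
    sv <- sweep(surface_oracle(V) - 1, 2, sp, `*`)
    dUV <- apply(su, 1, function(p) min(sqrt(colSums((t(sv) - p)^2))))
    dVU <- apply(sv, 1, function(p) min(sqrt(colSums((t(su) - p)^2))))
    want <- quantile(c(dUV, dVU), 0.95, names = FALSE)
    expect_lt(abs(got - want), 1e-9)
    # the 95th percentile never exceeds the exact Hausdorff distance
    expect_lte(got, max(c(dUV, dVU)) + 1e-12)
  }
})

test_that("aggregation pools voxels globally and averages per case", {
  s1 <- data.frame(dice = 0.8, tp = 2, size_u = 3, size_v = 2)
  s2 <- data.frame(dice = 0, tp = 0, size_u = 1, size_v = 1)
  agg <- aggregate_scores(rbind(s1, s2))
  expect_equal(agg$dice_global, 4 / 7)
  expect_equal(agg$dice_per_case_mean, 0.4)
  agg_rev <- aggregate_scores(rbind(s2, s1))
  expect_equal(agg_rev$dice_global, agg$dice_global)
  expect_equal(agg_rev$dice_per_case_mean, agg$dice_per_case_mean)
  single <- aggregate_scores(s1)
  expect_equal(single$dice_global, 2 * 2 / 5)
  expect_equal(single$dice_per_case_mean, 0.8)
})
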