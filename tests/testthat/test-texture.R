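test_that("2D LBP codes match a naive per-pixel oracle", {
  set.seed(7)
  img <- matrix(rnorm(256), 16, 16)
  codes <- lbp2d(img, 1, 8)
  pad <- function(m, p) {
    H <- nrow(m); W <- ncol(m)
    m[pmin(pmax(seq_len(H + 2 * p) - p, 1), H),
      pmin(pmax(seq_len(W + 2 * p) - p, 1), W)]
  }
  ip <- pad(img, 2)
  naive <- matrix(0L, 16, 16)
  for (r in 1:16) for (c in 1:16) {
    bits <- integer(8)
    for (k in 0:7) {
      a <- 2 * pi * k / 8
      o <- c(-sin(a), cos(a))
      o <- ifelse(abs(o - round(o)) < 1e-9, round(o), o)
      rr <- r + o[1]; cc <- c + o[2]
      r0 <- floor(rr); c0 <- floor(cc); fr <- rr - r0; fc <- cc - c0
      val <- (1 - fr) * (1 - fc) * ip[r0 + 2, c0 + 2] +
        fr * (1 - fc) * ip[r0 + 3, c0 + 2] +
        (1 - fr) * fc * ip[r0 + 2, c0 + 3] + fr * fc * ip[r0 + 3, c0 + 3]
      bits[k + 1] <- as.integer(val >= img[r, c])
    }
    u <- sum(bits != bits[c(2:8, 1)])
    naive[r, c] <- if (u <= 2) sum(bits) else 9L
  }
  expect_identical(codes, naive)
  expect_true(all(codes >= 0 & codes <= 9))
})

test_that("2D LBP is constant on flat images and 90-degree equivariant", {
  expect_equal(length(unique(as.vector(lbp2d(matrix(5, 9, 9))))), 1)
  rot90m <- function(m) t(m)[ncol(m):1, ]
  set.seed(8)
  for (i in 1:5) {
    img <- matrix(rnorm(144), 12, 12)
    a <- lbp2d(rot90m(img), 1, 8)
    b <- rot90m(lbp2d(img, 1, 8))
    # interior comparison: replicate padding can break fp ties on the rim
    expect_identical(a[2:11, 2:11], b[2:11, 2:11])
  }
  expect_error(lbp2d(matrix(0, 2, 2), radius = 1), "size error")
})

test_that("3D LBP: flat volumes give zero energies and zero kurtosis", {
  m <- lbp3d(array(0.5, c(8, 8, 8)))
  expect_lt(max(abs(m$band_energies)), 1e-20)
  expect_equal(max(abs(m$kurtosis)), 0)
  expect_equal(dim(m$band_energies), c(8L, 8L, 8L, 3L))
  expect_error(lbp3d(array(0, c(8, 8, 8)), n_dirs = 6, sh_order = 2),
               "configuration error")
})

test_that("3D LBP central impulse matches a direct SH-projection oracle", {
  d <- c(9, 9, 9)
  vol <- array(0, d)
  vol[5, 5, 5] <- 1
  m <- lbp3d(vol, radius_vox = 2, sh_order = 2, n_dirs = 26)
  # oracle: at the center voxel, each direction samples 0 (radius-2 shell
  # has no weight on the impulse for integer-snapped axis dirs; fractional
  # corner/edge dirs interpolate zeros as well since |off| = 2 > sqrt(3))
  # so f_j = -1 for all j; project on closed-form real SH in Cartesian form
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  dirs <- g / sqrt(rowSums(g^2))
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  Y <- cbind(sqrt(1 / (4 * pi)) + 0 * x,                       # l=0
             sqrt(3 / (4 * pi)) * y,                           # l=1
             sqrt(3 / (4 * pi)) * z,
             sqrt(3 / (4 * pi)) * x,
             sqrt(15 / (4 * pi)) * x * y,                      # l=2
             sqrt(15 / (4 * pi)) * y * z,
             sqrt(5 / (16 * pi)) * (3 * z^2 - 1),
             sqrt(15 / (4 * pi)) * x * z,
             sqrt(15 / (16 * pi)) * (x^2 - y^2))
  f <- rep(-1, 26)
  # sampled neighbor values at the center voxel, trilinear, radius 2
  for (j in 1:26) {
    off <- dirs[j, ] * 2
    fl <- floor(off); fr <- off - fl
    val <- 0
    for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
      w <- (if (cx) fr[1] else 1 - fr[1]) * (if (cy) fr[2] else 1 - fr[2]) *
        (if (cz) fr[3] else 1 - fr[3])
      pos <- c(5, 5, 5) + fl + c(cx, cy, cz)
      v <- if (all(pos >= 1 & pos <= 9)) vol[pos[1], pos[2], pos[3]] else 0
      val <- val + w * v
    }
    f[j] <- val - 1
  }
  coef <- crossprod(Y, f) / 26
  bands <- c(sum(coef[1]^2), sum(coef[2:4]^2), sum(coef[5:9]^2))
  got <- m$band_energies[5, 5, 5, ]
  expect_equal(as.numeric(got), bands, tolerance = 1e-10)
})

test_that("3D LBP scalar encoding is normalized and scale-invariant", {
  set.seed(9)
  m <- lbp3d(array(runif(12^3), c(12, 12, 12)))
  s <- lbp3d_scalar(m)
  expect_true(all(s$voxels >= 0 & s$voxels <= 1))
  expect_equal(min(s$voxels), 0)
  expect_equal(max(s$voxels), 1)
  m2 <- m
  m2$band_energies <- m$band_energies * 2
  expect_equal(lbp3d_scalar(m2)$voxels, s$voxels)
  z <- m
  z$band_energies <- z$band_energies * 0
  expect_true(all(lbp3d_scalar(z)$voxels == 0))
})

test_that("dense SIFT obeys shape, norm and flat-patch contracts", {
  set.seed(10)
  img <- matrix(rnorm(96 * 80), 96, 80)
  ds <- dense_sift(img, 4)
  expect_equal(dim(ds$descriptors), c(24L, 20L, 128L))
  n <- sqrt(rowSums(matrix(ds$descriptors, ncol = 128)^2))
  expect_true(all(n <= 1 + 1e-12))
  ds1 <- dense_sift(img[1:15, 1:10], 1)
  expect_equal(dim(ds1$descriptors)[1:2], c(15L, 10L))
  expect_true(all(dense_sift(matrix(2, 20, 20), 4)$descriptors == 0))
  expect_error(dense_sift(matrix(0, 3, 3), 5), "size error")
})

test_that("dense SIFT histograms match a brute-force oracle on an oriented bar", {
  bar <- matrix(0, 32, 32)
  bar[, 16:17] <- 10
  db <- dense_sift(bar, 4)
  ctr <- db$descriptors[4, 4, ]
  got_bins <- sapply(0:7, function(b) sum(ctr[seq(b + 1, 128, by = 8)]))
  # oracle: central-difference gradients, angle = atan2(d/drow, d/dcol),
  # hard 8-bin histogram over the 16x16 window around node (13, 13)
  H <- 32; W <- 32
  padm <- bar[pmin(pmax(0:(H + 1), 1), H), pmin(pmax(0:(W + 1), 1), W)]
  gr <- (padm[3:(H + 2), 2:(W + 1)] - padm[1:H, 2:(W + 1)]) / 2
  gc <- (padm[2:(H + 1), 3:(W + 2)] - padm[2:(H + 1), 1:W]) / 2
  mag <- sqrt(gr^2 + gc^2)
  bin <- pmin(floor((atan2(gr, gc) %% (2 * pi)) / (pi / 4)), 7)
  rows <- (13 - 8):(13 + 7); cols <- (13 - 8):(13 + 7)
  want_bins <- sapply(0:7, function(b) sum(mag[rows, cols][bin[rows, cols] == b]))
  # compare dominant-orientation structure (descriptor is normalized and
  # clipped, so magnitudes differ but the supported/dominant bins agree)
  expect_equal(which(got_bins > 0), which(want_bins > 0))
  expect_setequal(which(got_bins == max(got_bins)),
                  which(want_bins == max(want_bins)))
})

test_that("dense SIFT translates with the image by whole steps", {
  set.seed(11)
  img <- matrix(rnorm(64 * 64), 64, 64)
  sh <- rbind(matrix(rnorm(4 * 64), 4, 64), img[1:60, ])
  a <- dense_sift(img, 4)$descriptors
  b <- dense_sift(sh, 4)$descriptors
  # interior nodes: node (i+1, j) of the shifted image sees the content of
  # node (i, j); windows touching pasted rows/borders excluded
  expect_equal(b[5:14, 4:13, ], a[4:13, 4:13, ], tolerance = 1e-12)
})
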