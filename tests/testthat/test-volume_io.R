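test_that("NIfTI round-trip preserves grid, spacing and labels", {
  set.seed(1)
  v <- ct_volume(array(rnorm(8 * 10 * 6), c(8, 10, 6)),
                 spacing_mm = c(0.8, 0.8, 2.5))
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, p)
  v2 <- read_volume(p)
  expect_equal(v2$voxels, v$voxels)
  expect_equal(v2$spacing_mm, v$spacing_mm)

  lab <- label_volume(array(sample(0:2, 480, TRUE), c(8, 10, 6)))
  pl <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(lab, pl)
  lab2 <- read_labels(pl)
  expect_identical(lab2$labels, lab$labels)
})

test_that("non-integer label files are a format error", {
  img <- array(c(0, 1, 1.5, 2), c(2, 2, 1))
  p <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(img), p)
  expect_error(read_labels(p), "format error")
  expect_error(read_volume(file.path(tempdir(), "nope.nii.gz")), "I/O")
})

test_that("preprocess clips to percentiles and maps onto [0, 1]", {
  v <- ct_volume(array(0:999, c(10, 10, 10)))
  out <- preprocess(v)
  expect_equal(min(out$voxels), 0)
  expect_equal(max(out$voxels), 1)
  expect_true(out$normalized)
  expect_error(preprocess(out), "already")

  # degenerate constant volume
  cv <- ct_volume(array(7, c(4, 4, 4)))
  expect_warning(z <- preprocess(cv), "constant")
  expect_true(all(z$voxels == 0))

  # percentile + rescale oracle at lo = 10, hi = 90 on 0..99
  v2 <- ct_volume(array(0:99, c(10, 10, 1)))
  got <- preprocess(v2, 10, 90)$voxels
  q <- stats::quantile(0:99, c(0.1, 0.9), names = FALSE)
  want <- (pmin(pmax(0:99, q[1]), q[2]) - q[1]) / (q[2] - q[1])
  expect_equal(as.numeric(got), want)
})

test_that("preprocess is idempotent on [0,1] data up to re-clipping", {
  set.seed(2)
  x <- array(runif(1000), c(10, 10, 10))
  once <- preprocess(ct_volume(x))
  again <- preprocess(ct_volume(once$voxels))
  expect_lt(max(abs(once$voxels - again$voxels)), 0.05)
})

test_that("crop and paste are inverse on the boxed region", {
  set.seed(3)
  arr <- array(rnorm(24 * 20 * 16), c(24, 20, 16))
  v <- ct_volume(arr)
  for (i in 1:100) {
    size <- sapply(c(24, 20, 16), function(n) sample(n, 1))
    origin <- sapply(seq_len(3), function(a)
      sample(0:(c(24, 20, 16)[a] - size[a]), 1))
    box <- bounding_box(origin, size)
    sub <- crop(v, box)
    expect_equal(dim(sub$voxels), as.integer(size))
    # slicing oracle
    expect_equal(sub$voxels,
                 arr[origin[1] + 1:size[1], origin[2] + 1:size[2],
                     origin[3] + 1:size[3], drop = FALSE])
    back <- paste_volume(sub, box, dim(arr))
    expect_equal(back[origin[1] + 1:size[1], origin[2] + 1:size[2],
                      origin[3] + 1:size[3], drop = FALSE], sub$voxels)
    outside <- back
    outside[origin[1] + 1:size[1], origin[2] + 1:size[2],
            origin[3] + 1:size[3]] <- 0
    expect_true(all(outside == 0))
  }
  # identity crop
  full <- crop(v, bounding_box(c(0, 0, 0), dim(arr)))
  expect_equal(full$voxels, arr)
  expect_error(crop(v, bounding_box(c(20, 0, 0), c(10, 4, 4))), "bounds")
})
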