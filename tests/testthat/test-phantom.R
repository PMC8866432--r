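test_that("invalid configurations name the offending field", {
  expect_error(phantom_config(tumor_radius_mm = 0), "tumor_radius_mm")
  expect_error(phantom_config(pancreas_axes_mm = c(10, -1, 5)),
               "pancreas_axes_mm")
  expect_error(phantom_config(spacing_mm = c(0, 1, 1)), "spacing_mm")
  expect_error(phantom_config(tumor_radius_mm = 30), "tumor_radius_mm")
})

test_that("phantoms are deterministic under seed", {
  cfg <- tiny_phantom_config(seed = 4L)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$labels$labels, b$labels$labels)
  v1 <- generate_vessel_phantom(cfg)
  v2 <- generate_vessel_phantom(cfg)
  expect_identical(v1$image$voxels, v2$image$voxels)
})

test_that("pancreas voxel count matches brute-force ellipsoid enumeration", {
  cfg <- phantom_config(shape = c(96, 96, 96), pancreas_axes_mm = c(20, 12, 10),
                        spacing_mm = c(1, 1, 1), seed = 2L)
  ph <- generate_phantom(cfg)
  ctr <- ph$meta$pancreas_center_mm
  ax <- ph$meta$pancreas_axes_mm
  inside <- 0L
  for (k in 0:95) {
    zt <- ((k - ctr[3]) / ax[3])^2
    if (zt > 1) next
    xs <- (0:95 - ctr[1])^2 / ax[1]^2
    ys <- (0:95 - ctr[2])^2 / ax[2]^2
    inside <- inside + sum(outer(xs, ys, `+`) + zt <= 1)
  }
  expect_identical(sum(ph$labels$labels > 0L), as.integer(inside))
})

test_that("tumor is non-empty and contained in the pancreas ellipsoid", {
  for (s in 1:4) {
    ph <- generate_phantom(tiny_phantom_config(seed = s))
    lab <- ph$labels$labels
    expect_gt(sum(lab == 2L), 0)
    expect_gt(sum(lab == 1L), 0)
    # every tumor voxel center lies inside the analytic pancreas ellipsoid
    idx <- which(lab == 2L, arr.ind = TRUE) - 1
    ctr <- ph$meta$pancreas_center_mm; ax <- ph$meta$pancreas_axes_mm
    en <- ((idx[, 1] - ctr[1]) / ax[1])^2 + ((idx[, 2] - ctr[2]) / ax[2])^2 +
      ((idx[, 3] - ctr[3]) / ax[3])^2
    expect_true(all(en <= 1))
  }
})

test_that("vessel phantom labels are disjoint tubes with exact counts when straight", {
  cfg <- phantom_config(shape = c(48, 48, 40), vessel_waviness_mm = 0,
                        vessel_radius_mm = 2, seed = 3L,
                        pancreas_axes_mm = c(10, 8, 6), tumor_radius_mm = 3)
  vp <- generate_vessel_phantom(cfg)
  lab <- vp$labels$labels
  expect_setequal(unique(as.vector(lab)), c(0L, 1L, 2L))
  # straight tube of radius 2 mm along z, 40 slices at 1 mm: labeled count
  # equals brute-force voxel-center distance-to-axis enumeration
  base <- vp$meta$sma_base_mm
  xs <- (0:47 - base[1])^2
  ys <- (0:47 - base[2])^2
  disk <- sum(outer(xs, ys, `+`) <= 4)
  expect_identical(sum(lab == 1L), as.integer(disk * 40L))
})

test_that("cohorts split 70-30, reproducibly, with readable files", {
  dir <- withr::local_tempdir()
  cfg <- tiny_phantom_config()
  man <- generate_cohort(10, cfg, split_fraction = 0.7, seed = 5L,
                         out_dir = dir)
  expect_equal(sum(man$split == "train"), 7)
  expect_equal(sum(man$split == "test"), 3)
  man2 <- generate_cohort(10, cfg, split_fraction = 0.7, seed = 5L,
                          out_dir = withr::local_tempdir())
  expect_identical(man$split, man2$split)
  expect_identical(man$case_id, man2$case_id)
  # n = 2, fraction 0.5
  man3 <- generate_cohort(2, cfg, split_fraction = 0.5, seed = 1L,
                          out_dir = withr::local_tempdir())
  expect_equal(sort(man3$split), c("test", "train"))
  # round-trip: written labels read back with identical histogram
  cfg1 <- cfg
  cfg1$seed <- (5L * 131L + 1L * 7919L) %% 2147483647L
  ph <- generate_phantom(cfg1)
  lab <- read_labels(man$label_path[1])
  expect_identical(table(lab$labels), table(ph$labels$labels))
})
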