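test_that("sliding-window origins match arithmetic enumeration", {
  o <- sliding_window_positions(c(512, 512, 96))
  ox <- sort(unique(o[, 1]))
  expect_equal(ox, c(seq(0, 400, by = 50), 448))
  expect_equal(length(ox), 10)
  oz <- sort(unique(o[, 3]))
  expect_equal(oz, c(0, 20, 32))
  o2 <- sliding_window_positions(c(100, 100, 100), 64, 20, 20)
  expect_equal(sort(unique(o2[, 1])), c(0, 20, 36))
  o3 <- sliding_window_positions(c(64, 70, 64))
  expect_equal(sort(unique(o3[, 1])), 0)
  expect_error(sliding_window_positions(c(60, 70, 70)), "size error")
  # windows stay in bounds and cover the full extent on each axis
  for (shape in list(c(130, 100, 70), c(64, 64, 64), c(200, 90, 130))) {
    pos <- sliding_window_positions(shape)
    expect_true(all(pos >= 0))
    expect_true(all(t(t(pos) + 64) <= matrix(shape, nrow(pos), 3,
                                             byrow = TRUE)))
    for (a in 1:3) {
      covered <- rep(FALSE, shape[a])
      for (org in unique(pos[, a])) covered[org + 1:64] <- TRUE
      expect_true(all(covered))
    }
  }
})

test_that("gravity center and box placement follow the stated arithmetic", {
  expect_equal(gravity_center(matrix(c(0, 0, 0), 1) + 32), c(32, 32, 32))
  expect_equal(gravity_center(rbind(c(10, 10, 10), c(20, 20, 20))),
               c(15, 15, 15))
  set.seed(1)
  for (i in 1:20) {
    ctr <- matrix(sample(0:100, 9, TRUE), 3)
    expect_equal(gravity_center(ctr), round(colMeans(ctr)))
  }
  b <- make_bbox(c(50, 50, 50), c(20, 20, 20), c(100, 100, 100))
  expect_equal(b$origin, c(40L, 40L, 40L))
  b0 <- make_bbox(c(0, 0, 0), c(64, 64, 64), c(100, 100, 100))
  expect_equal(b0$origin, c(0L, 0L, 0L))
  expect_error(make_bbox(c(0, 0, 0), c(128, 64, 64), c(100, 100, 100)),
               "size error")
  for (i in 1:50) {
    ctr <- sample(0:95, 3, TRUE)
    bb <- make_bbox(ctr, c(40, 30, 20), c(96, 96, 96))
    expect_true(all(bb$origin >= 0))
    expect_true(all(bb$origin + bb$size <= c(96, 96, 96)))
    expect_equal(bb$size, c(40L, 30L, 20L))
  }
})

test_that("sub-volume sampling respects class definitions and fails honestly", {
  ph <- generate_phantom(phantom_config(seed = 31))
  v <- preprocess(ph$image)
  lab <- ph$labels
  sv <- sample_subvolumes(v, lab, n_per_class = 2, fg_min_fraction = 0.01,
                          seed = 1, compute_payload = FALSE)
  fg_mask <- lab$labels > 0
  for (s in sv) {
    frac <- mean(fg_mask[s$origin[1] + 1:64, s$origin[2] + 1:64,
                         s$origin[3] + 1:64])
    if (s$label == "foreground") expect_gte(frac, 0.01)
    else expect_equal(frac, 0)
    expect_true(all(s$origin >= 0 & s$origin + 64 <= dim(v$voxels)))
  }
  # all-background labels cannot yield foreground windows
  empty <- label_volume(array(0L, dim(v$voxels)))
  expect_error(sample_subvolumes(v, empty, n_per_class = 1, seed = 1,
                                 compute_payload = FALSE, max_tries = 50),
               "sampling error")
  # fg_min_fraction = 0 keeps any window touching the organ
  sv0 <- sample_subvolumes(v, lab, n_per_class = 1, fg_min_fraction = 0,
                           seed = 2, compute_payload = FALSE)
  expect_true(any(vapply(sv0, function(s) s$label == "foreground",
                         logical(1))))
})

test_that("the 3D CNN separates structured from flat payloads", {
  cfg <- localizer_config(widths = c(2, 2, 4, 4, 4), window = 32L,
                          epochs = 15L, batch_size = 4L)
  set.seed(41)
  mk <- function(structured) {
    pay <- array(runif(32^3, 0, 0.05), c(32, 32, 32))
    if (structured) pay[9:24, 9:24, 9:24] <- pay[9:24, 9:24, 9:24] + 0.9
    pay
  }
  subs <- c(
    lapply(1:8, function(i) list(payload = mk(TRUE), label = "foreground")),
    lapply(1:8, function(i) list(payload = mk(FALSE), label = "background")))
  expect_error(train_localizer(subs[1:8], cfg, seed = 1), "data error")
  model <- train_localizer(subs, cfg, seed = 1)
  expect_lt(tail(model$epoch_loss, 1), model$epoch_loss[1])
  preds <- vapply(subs, function(s) predict_localizer(model, s$payload),
                  numeric(1))
  acc <- mean((preds > 0.5) == c(rep(TRUE, 8), rep(FALSE, 8)))
  expect_equal(acc, 1)
  # determinism under the seed
  model2 <- train_localizer(subs, cfg, seed = 1)
  expect_identical(model$epoch_loss, model2$epoch_loss)
})
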