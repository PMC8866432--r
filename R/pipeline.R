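# Orchestration: slice-level augmentation, vessel fine-tuning, cascade
# training and whole-volume prediction (localize -> crop -> per-slice
# inference with both networks -> 3D fusion -> paste back).

map_coords <- function(img, src_r, src_c, interp = c("bilinear", "nearest"),
                       fill = 0) {
  interp <- match.arg(interp)
  H <- nrow(img); W <- ncol(img)
  if (interp == "nearest") {
    r <- round(src_r); c <- round(src_c)
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    out <- rep(fill, length(src_r))
    out[ok] <- img[cbind(r[ok], c[ok])]
  } else {
    r0 <- floor(src_r); c0 <- floor(src_c)
    fr <- src_r - r0; fc <- src_c - c0
    out <- rep(as.numeric(fill), length(src_r))
    gv <- function(r, c) {
      ok <- r >= 1 & r <= H & c >= 1 & c <= W
      v <- rep(as.numeric(fill), length(r))
      v[ok] <- img[cbind(r[ok], c[ok])]
      v
    }
    out <- (1 - fr) * (1 - fc) * gv(r0, c0) + fr * (1 - fc) * gv(r0 + 1, c0) +
      (1 - fr) * fc * gv(r0, c0 + 1) + fr * fc * gv(r0 + 1, c0 + 1)
  }
  matrix(out, H, W)
}

#' Rotate a 2D image about its center
#'
#' @param img numeric matrix.
#' @param angle_deg counter-clockwise rotation in degrees.
#' @param interp `"bilinear"` for intensities, `"nearest"` for labels.
#' @param fill value for samples falling outside the image.
#' @return rotated matrix of the same shape.
#' @export
rotate_image <- function(img, angle_deg, interp = "bilinear", fill = 0) {
  H <- nrow(img); W <- ncol(img)
  a <- angle_deg * pi / 180
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  gr <- matrix(seq_len(H), H, W) - cr
  gc <- matrix(seq_len(W), H, W, byrow = TRUE) - cc
  src_r <- cos(a) * gr + sin(a) * gc + cr
  src_c <- -sin(a) * gr + cos(a) * gc + cc
  map_coords(img, src_r, src_c, interp, fill)
}

#' Shift a 2D image
#' @inheritParams rotate_image
#' @param dr,dc shift in rows/columns (may be fractional).
#' @return shifted matrix.
#' @export
shift_image <- function(img, dr, dc, interp = "bilinear", fill = 0) {
  H <- nrow(img); W <- ncol(img)
  gr <- matrix(seq_len(H), H, W) - dr
  gc <- matrix(seq_len(W), H, W, byrow = TRUE) - dc
  map_coords(img, gr, gc, interp, fill)
}

#' Flip a 2D image
#' @param img matrix.
#' @param axis 1 flips rows (vertical), 2 flips columns (horizontal).
#' @return flipped matrix.
#' @export
flip_image <- function(img, axis = 2L) {
  if (axis == 1L) img[rev(seq_len(nrow(img))), , drop = FALSE]
  else img[, rev(seq_len(ncol(img))), drop = FALSE]
}

#' Random geometric augmentation of an image/label pair
#'
#' Applies the same random flip, rotation (default up to +/-15 degrees)
#' and shift (default up to +/-10% of the image size) to both grids; the
#' image is interpolated bilinearly, labels nearest-neighbor so the class
#' set is preserved. With all toggles off the pair is returned unchanged.
#'
#' @param image 2D intensity matrix.
#' @param labels aligned integer matrix.
#' @param ops list of toggles: `rotate`, `flip`, `shift`.
#' @param seed RNG seed.
#' @param max_angle_deg rotation range.
#' @param shift_frac shift range as a fraction of each dimension.
#' @return list with transformed `image` and `labels`.
#' @export
augment <- function(image, labels, ops = list(rotate = TRUE, flip = TRUE,
                                              shift = TRUE),
                    seed = NULL, max_angle_deg = 15, shift_frac = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  img <- image; lab <- labels
  if (isTRUE(ops$flip)) {
    if (stats::runif(1) < 0.5) { img <- flip_image(img, 2); lab <- flip_image(lab, 2) }
    if (stats::runif(1) < 0.5) { img <- flip_image(img, 1); lab <- flip_image(lab, 1) }
  }
  if (isTRUE(ops$rotate)) {
    a <- stats::runif(1, -max_angle_deg, max_angle_deg)
    img <- rotate_image(img, a, "bilinear", fill = min(img))
    lab <- rotate_image(lab, a, "nearest", fill = 0)
  }
  if (isTRUE(ops$shift)) {
    dr <- round(stats::runif(1, -shift_frac, shift_frac) * nrow(img))
    dc <- round(stats::runif(1, -shift_frac, shift_frac) * ncol(img))
    img <- shift_image(img, dr, dc, "bilinear", fill = min(img))
    lab <- shift_image(lab, dr, dc, "nearest", fill = 0)
  }
  list(image = img, labels = matrix(as.integer(lab), nrow(lab), ncol(lab)))
}

#' Expand a vessel training set by augmentation
#'
#' Each case contributes itself plus `factor - 1` randomly transformed
#' copies (translation, flipping, rotation), enlarging the set `factor`
#' times; deterministic under `seed`.
#'
#' @param cases list of `list(image = matrix, labels = matrix)` pairs.
#' @param factor expansion factor (12).
#' @param seed RNG seed.
#' @return list of `factor * length(cases)` items.
#' @export
expand_vessel_set <- function(cases, factor = 12L, seed = 1L) {
  if (length(cases) == 0) stop("non-empty case list required")
  out <- list()
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    out[[length(out) + 1L]] <- cs
    for (k in seq_len(factor - 1L)) {
      out[[length(out) + 1L]] <-
        augment(cs$image, cs$labels, seed = seed + i * 1000L + k)
    }
  }
  out
}

#' Fine-tune a pretrained segmentation network for vessels
#'
#' Reinitializes the class head for the vessel label set (background, SMA,
#' SMV), keeps every backbone weight, and trains at a small learning rate.
#' With `epochs = 0` the backbone is returned untouched (head freshly
#' initialized only).
#'
#' @param pretrained a trained `tauseg_net` (PDAC task).
#' @param samples slice samples as for [train_segnet()], vessel labels.
#' @param epochs passes over the sample list.
#' @param batch_size slices per step.
#' @param lr Adam learning rate (1e-5 for fine-tuning).
#' @param n_classes vessel classes including background.
#' @param seed RNG seed.
#' @param ... further arguments to [train_segnet()].
#' @return fine-tuned network.
#' @export
finetune_vessels <- function(pretrained, samples, epochs = 30L,
                             batch_size = 4L, lr = 1e-5, n_classes = 3L,
                             seed = 1L, ...) {
  net <- pretrained
  set.seed(seed)
  hd <- dense_init(net$widths[1], n_classes)
  net$params$head.w <- hd$w
  net$params$head.b <- hd$b
  net$n_classes <- as.integer(n_classes)
  net$loss_history <- NULL
  if (epochs == 0) return(net)
  steps <- epochs * ceiling(length(samples) / batch_size)
  train_segnet(net, samples, steps = steps, batch_size = batch_size,
               lr = lr, seed = seed, ...)
}

#' Build slice-level training samples from a cropped case
#'
#' Cuts the cropped volume into axial 2D slices, one-hot encodes the
#' labels, and (optionally) attaches the texture tensors TAU-Net consumes:
#' dense SIFT at stride `sift_step` and the matching slice of the 3D-LBP
#' scalar volume.
#'
#' @param volume normalized, cropped [ct_volume()].
#' @param labels aligned [label_volume()].
#' @param with_texture attach `tx` for TAU-Net.
#' @param lbp_volume precomputed [lbp3d_scalar()] volume of the crop
#'   (computed here if NULL and needed).
#' @param sift_step SIFT stride (4: descriptors live on the scale-4 grid).
#' @param every keep every `every`-th slice.
#' @param fg_only keep only slices containing foreground.
#' @param n_classes classes for one-hot encoding.
#' @return list of samples `list(x, U, tx, z)`.
#' @export
slice_samples <- function(volume, labels, with_texture = FALSE,
                          lbp_volume = NULL, sift_step = 4L, every = 1L,
                          fg_only = TRUE, n_classes = 3L) {
  vox <- volume$voxels
  lab <- labels$labels
  if (with_texture && is.null(lbp_volume))
    lbp_volume <- lbp3d_scalar(lbp3d(volume))
  zs <- seq(1, dim(vox)[3], by = every)
  out <- list()
  for (z in zs) {
    lz <- lab[, , z]
    if (fg_only && !any(lz > 0)) next
    sl <- vox[, , z]
    tx <- NULL
    if (with_texture)
      tx <- list(sift = sift_feature_tensor(sl, sift_step),
                 lbp = lbp_feature_tensor(lbp_volume$voxels[, , z]))
    out[[length(out) + 1L]] <- list(x = array(sl, dim = c(dim(sl), 1)),
                                    U = one_hot(lz, n_classes), tx = tx,
                                    z = z)
  }
  out
}

# Round a box size up so the in-plane dims are divisible by 32 and fit.
fit_box_size <- function(size, shape) {
  size <- as.integer(size)
  size[1:2] <- pmin(as.integer(ceiling(size[1:2] / 32) * 32), shape[1:2])
  size[1:2] <- (size[1:2] %/% 32) * 32
  size[3] <- min(size[3], shape[3])
  size
}

true_center <- function(labels) {
  idx <- which(labels$labels > 0L, arr.ind = TRUE)
  round(colMeans(idx)) - 1L
}

net_slice_probs <- function(net, volume, lbp_volume, sift_step = 4L) {
  vox <- volume$voxels
  d <- dim(vox)
  probs <- array(0, dim = c(d, net$n_classes))
  needs_tx <- any(net$tex_channels > 0)
  for (z in seq_len(d[3])) {
    sl <- vox[, , z]
    tx <- NULL
    if (needs_tx)
      tx <- list(sift = sift_feature_tensor(sl, sift_step),
                 lbp = lbp_feature_tensor(lbp_volume$voxels[, , z]))
    probs[, , z, ] <- segnet_forward(net, sl, tx)
  }
  probs
}

#' Train the full coarse-to-fine cascade on a phantom cohort
#'
#' Trains the localizer on 3D-LBP sub-volumes, the Attention U-Net and
#' TAU-Net on slices cropped around the (ground-truth) pancreas box of the
#' training cases, and the 3D hybrid fuser on the two networks' stacked
#' probability maps.
#'
#' @param manifest cohort manifest from [generate_cohort()].
#' @param widths network channel widths.
#' @param steps optimizer steps per segmentation network.
#' @param batch_size slices per step.
#' @param lr segmentation learning rate.
#' @param fuser_steps fuser optimizer steps.
#' @param loc_config [localizer_config()].
#' @param loc_cases cap on training cases for the localizer stage.
#' @param margin bounding-box margin (voxels).
#' @param every slice subsampling stride for training.
#' @param n_fuser_cases training cases used for the fuser.
#' @param seed RNG seed.
#' @return list with `localizer`, `net_a`, `net_b`, `fuser`, `box_size`.
#' @export
fit_cascade <- function(manifest, widths = c(8, 16, 32, 64, 64),
                        steps = 300L, batch_size = 4L, lr = 1e-3,
                        fuser_steps = 60L, loc_config = localizer_config(),
                        loc_cases = Inf, margin = 16L, every = 2L,
                        n_fuser_cases = 2L, seed = 1L) {
  shape <- dim(read_labels(manifest$label_path[1])$labels)
  box_size <- fit_box_size(cohort_bbox_size(manifest, margin), shape)
  localizer <- train_localizer(manifest, loc_config, seed = seed,
                               max_cases = loc_cases)

  tr <- manifest[manifest$split == "train", , drop = FALSE]
  samples_a <- list(); samples_b <- list()
  crops <- list()
  for (i in seq_len(nrow(tr))) {
    v <- preprocess(read_volume(tr$image_path[i]))
    lab <- read_labels(tr$label_path[i])
    box <- make_bbox(true_center(lab), box_size, dim(v$voxels))
    cv <- crop(v, box); cl <- crop(lab, box)
    lbpv <- lbp3d_scalar(lbp3d(cv))
    samples_a <- c(samples_a, slice_samples(cv, cl, FALSE, every = every,
                                            fg_only = FALSE))
    samples_b <- c(samples_b, slice_samples(cv, cl, TRUE, lbp_volume = lbpv,
                                            every = every, fg_only = FALSE))
    if (length(crops) < n_fuser_cases)
      crops[[length(crops) + 1L]] <- list(v = cv, l = cl, lbp = lbpv)
  }

  net_a <- build_attention_unet(widths, seed = seed + 1L)
  net_a <- train_segnet(net_a, samples_a, steps = steps,
                        batch_size = batch_size, lr = lr, seed = seed + 1L)
  net_b <- build_tau_net(widths, seed = seed + 2L)
  net_b <- train_segnet(net_b, samples_b, steps = steps,
                        batch_size = batch_size, lr = lr, seed = seed + 2L)

  pairs <- lapply(crops, function(cr) {
    list(a = net_slice_probs(net_a, cr$v, cr$lbp),
         b = net_slice_probs(net_b, cr$v, cr$lbp),
         labels = cr$l$labels)
  })
  fuser <- build_hybrid_fuser("average")
  fuser <- train_fuser(fuser, pairs, steps = fuser_steps, seed = seed + 3L)

  list(localizer = localizer, net_a = net_a, net_b = net_b, fuser = fuser,
       box_size = box_size)
}

#' Segment a whole volume with the trained cascade
#'
#' Localization, cropping, per-slice inference with both networks,
#' stacking into 3D probability maps, hybrid fusion, argmax labeling, and
#' pasting back into full-volume coordinates (background outside the box).
#'
#' @param volume a [ct_volume()] (preprocessed automatically if raw).
#' @param localizer,net_a,net_b,fuser trained cascade components, e.g.
#'   from [fit_cascade()].
#' @param box_size fine-stage bounding-box size (in-plane dims must be
#'   divisible by 32).
#' @param sift_step SIFT stride for texture inputs.
#' @param box optional precomputed [bounding_box()] (e.g. a stored coarse
#'   result); skips the localization stage.
#' @param stride_xy,stride_z sliding-window strides for localization.
#' @return a [label_volume()]; the detected [bounding_box()] is attached
#'   as attribute `"box"`.
#' @export
predict_volume <- function(volume, localizer, net_a, net_b, fuser,
                           box_size, sift_step = 4L, box = NULL,
                           stride_xy = 50L, stride_z = 20L) {
  if ((is.null(localizer) && is.null(box)) || is.null(net_a) ||
      is.null(net_b) || is.null(fuser))
    stop("configuration error: all cascade models must be provided")
  if (!volume$normalized) volume <- preprocess(volume)
  shape <- dim(volume$voxels)
  if (is.null(box)) {
    box_size <- fit_box_size(box_size, shape)
    center <- predict_center(localizer, volume, stride_xy, stride_z)
    box <- make_bbox(center, box_size, shape)
  }
  sub <- crop(volume, box)
  lbpv <- lbp3d_scalar(lbp3d(sub))
  pa <- net_slice_probs(net_a, sub, lbpv, sift_step)
  pb <- net_slice_probs(net_b, sub, lbpv, sift_step)
  fp <- fuse(pa, pb, fuser)
  d <- dim(fp)
  lab <- max.col(matrix(fp, ncol = d[4]), ties.method = "first") - 1L
  lab <- array(as.integer(lab), dim = d[1:3])
  full <- paste_volume(lab, box, shape, fill = 0L)
  out <- label_volume(full, spacing_mm = volume$spacing_mm)
  attr(out, "box") <- box
  out
}

#' Evaluate the cascade on the test split of a cohort
#'
#' @param manifest cohort manifest.
#' @param fit cascade list from [fit_cascade()].
#' @param class_id class to score (2 = tumor).
#' @return list with per-case scores and the [aggregate_scores()] summary.
#' @export
evaluate_cascade <- function(manifest, fit, class_id = 2L) {
  te <- manifest[manifest$split == "test", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(te))) {
    v <- read_volume(te$image_path[i])
    lab <- read_labels(te$label_path[i])
    pred <- predict_volume(v, fit$localizer, fit$net_a, fit$net_b,
                           fit$fuser, fit$box_size)
    rows[[i]] <- score_case(lab, pred, class_id = class_id,
                            spacing_mm = lab$spacing_mm)
  }
  scores <- do.call(rbind, rows)
  list(cases = scores, summary = aggregate_scores(scores))
}
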