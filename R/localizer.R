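# Coarse stage: find the pancreas-containing bounding box by classifying
# 3D-LBP-encoded 64^3 sub-volumes with a small 3D CNN, then taking the
# gravity center of the windows predicted foreground.

#' Localizer configuration
#'
#' Five convolution blocks (each `filters_per_block` 3x3x3 convolutions,
#' per-sample normalization, leaky-ReLU) with 2x2x2 stride-2 max pooling,
#' a dense 2-way softmax head, Adam with polynomial learning-rate decay,
#' cross-entropy loss.
#'
#' @param filters_per_block convolutions per block (2 or 3, the ablation of
#'   the coarse stage).
#' @param widths channel widths of the five blocks.
#' @param lr base learning rate.
#' @param gamma polynomial decay exponent.
#' @param batch_size mini-batch size.
#' @param epochs training epochs.
#' @param n_per_class sub-volumes sampled per class per case when training
#'   from a cohort manifest.
#' @param fg_min_fraction minimum pancreas/tumor overlap fraction for a
#'   foreground sub-volume.
#' @param window sub-volume side (64).
#' @param lbp_radius,lbp_order 3D-LBP payload parameters.
#' @param lrelu_slope leaky-ReLU negative slope.
#' @return a `localizer_config` list.
#' @export
localizer_config <- function(filters_per_block = 2L,
                             widths = c(4, 8, 16, 32, 32),
                             lr = 0.01, gamma = 0.1, batch_size = 5L,
                             epochs = 30L, n_per_class = 2L,
                             fg_min_fraction = 0.01, window = 64L,
                             lbp_radius = 2, lbp_order = 2L,
                             lrelu_slope = 0.01) {
  stopifnot(filters_per_block >= 1, length(widths) == 5, all(widths >= 1),
            lr > 0, batch_size >= 1, epochs >= 0)
  structure(list(filters_per_block = as.integer(filters_per_block),
                 widths = widths, lr = lr, gamma = gamma,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 n_per_class = as.integer(n_per_class),
                 fg_min_fraction = fg_min_fraction,
                 window = as.integer(window), lbp_radius = lbp_radius,
                 lbp_order = as.integer(lbp_order),
                 lrelu_slope = lrelu_slope),
            class = "localizer_config")
}

#' Full-volume 3D-LBP payload map
#'
#' The scalar-encoded 3D-LBP volume from which all sub-volume payloads are
#' cropped, so training and sliding-window inference see identically
#' normalized features.
#'
#' @param volume normalized [ct_volume()].
#' @param config [localizer_config()] (LBP parameters).
#' @return a normalized [ct_volume()].
#' @export
payload_map <- function(volume, config = localizer_config()) {
  lbp3d_scalar(lbp3d(volume, radius_vox = config$lbp_radius,
                     sh_order = config$lbp_order))
}

#' 3D-LBP scalar payload of a sub-volume
#'
#' @param map full-volume payload map from [payload_map()] (a normalized
#'   [ct_volume()] is computed on the fly if a raw volume is supplied
#'   together with `config`).
#' @param origin 0-based window origin.
#' @param config [localizer_config()] (window size).
#' @return 3D array in `[0, 1]`.
#' @export
subvolume_payload <- function(map, origin, config = localizer_config()) {
  w <- config$window
  crop(map, bounding_box(origin, rep(w, 3)))$voxels
}

#' Sample balanced foreground/background sub-volumes
#'
#' Draws uniform-random 64^3 windows and keeps `n_per_class` whose
#' pancreas/tumor overlap fraction is at least `fg_min_fraction`
#' (foreground) and `n_per_class` with zero overlap (background). The
#' payload of each sub-volume is the 3D-LBP scalar encoding of its crop.
#'
#' @param volume normalized [ct_volume()], at least 64 voxels per axis.
#' @param labels aligned [label_volume()]; classes > 0 are foreground.
#' @param n_per_class sub-volumes to return per class.
#' @param fg_min_fraction overlap threshold for the foreground class.
#' @param seed RNG seed.
#' @param config [localizer_config()].
#' @param max_tries sampling attempts before giving up.
#' @param compute_payload set FALSE to skip the LBP payload (geometry-only
#'   uses).
#' @param map optional precomputed [payload_map()] (computed here
#'   otherwise).
#' @return list of sub-volumes: `origin`, `size`, `payload`, `label`
#'   (`"foreground"`/`"background"`), `overlap_fraction`.
#' @export
sample_subvolumes <- function(volume, labels, n_per_class = 2L,
                              fg_min_fraction = 0.01, seed = 1L,
                              config = localizer_config(),
                              max_tries = 500L * n_per_class,
                              compute_payload = TRUE, map = NULL) {
  w <- config$window
  shape <- dim(volume$voxels)
  if (any(shape < w)) stop("size error: volume smaller than the window")
  set.seed(seed)
  fg_mask <- labels$labels > 0L
  fg <- list(); bg <- list()
  tries <- 0L
  while ((length(fg) < n_per_class || length(bg) < n_per_class) &&
         tries < max_tries) {
    tries <- tries + 1L
    origin <- vapply(1:3, function(a) sample.int(shape[a] - w + 1L, 1L) - 1L,
                     integer(1))
    frac <- mean(fg_mask[origin[1] + seq_len(w), origin[2] + seq_len(w),
                         origin[3] + seq_len(w)])
    item <- list(origin = origin, size = rep(w, 3L), overlap_fraction = frac)
    if (frac > 0 && frac >= fg_min_fraction && length(fg) < n_per_class) {
      item$label <- "foreground"
      fg[[length(fg) + 1L]] <- item
    } else if (frac == 0 && length(bg) < n_per_class) {
      item$label <- "background"
      bg[[length(bg) + 1L]] <- item
    }
  }
  if (length(fg) < n_per_class || length(bg) < n_per_class)
    stop("sampling error: achieved ", length(fg), " foreground and ",
         length(bg), " background sub-volumes of ", n_per_class,
         " requested")
  out <- c(fg, bg)
  if (compute_payload) {
    if (is.null(map)) map <- payload_map(volume, config)
    out <- lapply(out, function(it) {
      it$payload <- subvolume_payload(map, it$origin, config)
      it
    })
  }
  out
}

#' Sliding-window origins covering a volume
#'
#' Per axis: `0, s, 2s, ...` up to the last stride-aligned origin, plus the
#' end-aligned origin `E - w` when the stride grid does not already reach
#' it, so the windows cover the full extent. The Cartesian product over
#' the three axes is returned.
#'
#' @param shape volume shape (voxels).
#' @param window window side.
#' @param stride_xy stride along x and y.
#' @param stride_z stride along z.
#' @return integer matrix (n x 3) of 0-based origins.
#' @export
sliding_window_positions <- function(shape, window = 64L, stride_xy = 50L,
                                     stride_z = 20L) {
  axis_origins <- function(E, w, s) {
    if (E < w) stop("size error: axis smaller than window")
    o <- seq(0L, E - w, by = s)
    if (o[length(o)] != E - w) o <- c(o, E - w)
    as.integer(o)
  }
  ox <- axis_origins(shape[1], window, stride_xy)
  oy <- axis_origins(shape[2], window, stride_xy)
  oz <- axis_origins(shape[3], window, stride_z)
  as.matrix(expand.grid(x = ox, y = oy, z = oz))
}

# ---------------------------------------------------------------------------
# 3D CNN classifier
# ---------------------------------------------------------------------------

loc_init <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- config$widths
  nc <- config$filters_per_block
  P <- list()
  cin <- 1L
  for (l in 1:5) {
    for (j in seq_len(nc)) {
      k <- conv3d_init(3, if (j == 1) cin else w[l], w[l])
      P[[sprintf("b%d.c%d.w", l, j)]] <- k$w
      P[[sprintf("b%d.c%d.b", l, j)]] <- k$b
      n <- norm_init(w[l])
      P[[sprintf("b%d.n%d.g", l, j)]] <- n$g
      P[[sprintf("b%d.n%d.b", l, j)]] <- n$b
    }
    cin <- w[l]
  }
  side <- config$window / 2^5
  hd <- dense_init(as.integer(side^3 * w[5]), 2L)
  P$head.w <- hd$w
  P$head.b <- hd$b
  P
}

loc_fwd <- function(P, config, x, train = TRUE) {
  if (length(dim(x)) == 3) x <- array(x, dim = c(dim(x), 1))
  caches <- list()
  h <- x
  for (l in 1:5) {
    for (j in seq_len(config$filters_per_block)) {
      z <- conv3d_fwd_cpp(h, P[[sprintf("b%d.c%d.w", l, j)]],
                          P[[sprintf("b%d.c%d.b", l, j)]], 1L)
      if (train) {
        n <- inorm_fwd(z, P[[sprintf("b%d.n%d.g", l, j)]],
                       P[[sprintf("b%d.n%d.b", l, j)]])
        a <- lrelu_fwd(n$y, config$lrelu_slope)
        caches[[sprintf("b%d.%d", l, j)]] <- list(x = h, n = n$cache,
                                                  a = a$cache)
        h <- a$y
      } else {
        y <- inorm_eval(z, P[[sprintf("b%d.n%d.g", l, j)]],
                        P[[sprintf("b%d.n%d.b", l, j)]])
        h <- y * (config$lrelu_slope + (1 - config$lrelu_slope) * (y > 0))
      }
    }
    mp <- maxpool3d_fwd_cpp(h)
    if (train) caches[[sprintf("p%d", l)]] <- list(idx = mp$idx,
                                                   dims = dim(h))
    h <- mp$y
  }
  v <- matrix(as.numeric(h), nrow = 1)
  logits <- v %*% P$head.w + matrix(P$head.b, 1)
  p <- exp(logits - max(logits))
  p <- p / sum(p)
  list(probs = as.numeric(p), cache = if (train)
    list(caches = caches, v = v, hdim = dim(h), probs = p))
}

loc_bwd <- function(P, config, cache, dlogits) {
  g <- list()
  g$head.w <- crossprod(cache$v, dlogits)
  g$head.b <- as.numeric(dlogits)
  dh <- array(as.numeric(dlogits %*% t(P$head.w)), dim = cache$hdim)
  for (l in 5:1) {
    pc <- cache$caches[[sprintf("p%d", l)]]
    dh <- maxpool_bwd_cpp(dh, pc$idx, pc$dims)
    for (j in rev(seq_len(config$filters_per_block))) {
      cc <- cache$caches[[sprintf("b%d.%d", l, j)]]
      d <- lrelu_bwd(dh, cc$a)
      nb <- inorm_bwd(d, cc$n)
      g[[sprintf("b%d.n%d.g", l, j)]] <- nb$dg
      g[[sprintf("b%d.n%d.b", l, j)]] <- nb$db
      cb <- conv3d_bwd_cpp(cc$x, P[[sprintf("b%d.c%d.w", l, j)]], nb$dx, 1L)
      g[[sprintf("b%d.c%d.w", l, j)]] <- cb$dw
      g[[sprintf("b%d.c%d.b", l, j)]] <- cb$db
      dh <- cb$dx
    }
  }
  g
}

subvols_from_manifest <- function(manifest, config, seed, max_cases = Inf) {
  tr <- manifest[manifest$split == "train", , drop = FALSE]
  if (nrow(tr) > max_cases) tr <- tr[seq_len(max_cases), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(tr))) {
    v <- preprocess(read_volume(tr$image_path[i]))
    lab <- read_labels(tr$label_path[i])
    sv <- sample_subvolumes(v, lab, n_per_class = config$n_per_class,
                            fg_min_fraction = config$fg_min_fraction,
                            seed = seed + i, config = config)
    out <- c(out, sv)
  }
  out
}

#' Train the pancreas localizer
#'
#' Cross-entropy training of the 3D CNN on balanced foreground/background
#' 3D-LBP sub-volume payloads. Deterministic given the seed (single
#' threaded).
#'
#' @param x a cohort manifest (data.frame from [generate_cohort()]) or a
#'   list of sub-volumes as returned by [sample_subvolumes()].
#' @param config a [localizer_config()].
#' @param seed RNG seed (weights, sampling, shuffling).
#' @param max_cases cap on the number of training cases drawn from a
#'   manifest.
#' @return a `tauseg_localizer` model with `epoch_loss` history.
#' @export
train_localizer <- function(x, config = localizer_config(), seed = 1L,
                            max_cases = Inf) {
  subs <- if (is.data.frame(x))
    subvols_from_manifest(x, config, seed, max_cases) else x
  labels01 <- vapply(subs, function(s) s$label == "foreground", logical(1))
  if (length(unique(labels01)) < 2)
    stop("data error: training set contains a single class")
  set.seed(seed)
  P <- loc_init(config, seed = seed)
  st <- adam_state(P)
  n <- length(subs)
  steps_total <- config$epochs * ceiling(n / config$batch_size)
  step <- 0L
  epoch_loss <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (bs in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      step <- step + 1L
      tot <- NULL
      lsum <- 0
      for (i in bs) {
        fw <- loc_fwd(P, config, subs[[i]]$payload)
        y <- as.integer(labels01[i]) + 1L
        p <- pmax(fw$probs, 1e-12)
        lsum <- lsum + (-log(p[y]))
        dlog <- matrix(fw$probs, 1)
        dlog[1, y] <- dlog[1, y] - 1  # softmax + NLL
        g <- loc_bwd(P, config, fw$cache, dlog)
        tot <- acc_grads(tot, g)
      }
      tot <- scale_grads(tot, 1 / length(bs))
      losses <- c(losses, lsum / length(bs))
      upd <- adam_step(P, tot, st,
                       poly_decay(config$lr, step, steps_total, config$gamma))
      P <- upd$params
      st <- upd$state
    }
    epoch_loss[ep] <- mean(losses)
  }
  structure(list(params = P, config = config, epoch_loss = epoch_loss),
            class = "tauseg_localizer")
}

#' Classify a sub-volume payload
#' @param model a `tauseg_localizer`.
#' @param payload 64^3 payload array.
#' @return foreground probability.
#' @export
predict_localizer <- function(model, payload) {
  loc_fwd(model$params, model$config, payload, train = FALSE)$probs[2]
}

#' Predict the pancreas center by sliding-window gravity center
#'
#' Classifies the 3D-LBP payload of every sliding window and returns the
#' unweighted mean of the centers of windows predicted foreground
#' (argmax), rounded to the nearest voxel. If no window is predicted
#' foreground the volume center is returned with a warning.
#'
#' @param model a `tauseg_localizer`.
#' @param volume normalized [ct_volume()].
#' @param stride_xy,stride_z sliding-window strides.
#' @return 0-based voxel triple.
#' @export
predict_center <- function(model, volume, stride_xy = 50L, stride_z = 20L) {
  w <- model$config$window
  shape <- dim(volume$voxels)
  pos <- sliding_window_positions(shape, w, stride_xy, stride_z)
  map <- payload_map(volume, model$config)
  hits <- matrix(0, 0, 3)
  for (i in seq_len(nrow(pos))) {
    payload <- subvolume_payload(map, pos[i, ], model$config)
    if (predict_localizer(model, payload) > 0.5)
      hits <- rbind(hits, pos[i, ] + w / 2)
  }
  if (nrow(hits) == 0) {
    warning("no window predicted foreground: falling back to volume center")
    return(round(shape / 2))
  }
  round(colMeans(hits))
}

#' Gravity center of a set of window centers
#'
#' @param centers matrix (n x 3) of window centers.
#' @return unweighted mean, rounded to the nearest voxel.
#' @export
gravity_center <- function(centers) {
  round(colMeans(as.matrix(centers)))
}

#' Center a fixed-size bounding box, clamped into the volume
#'
#' The box keeps its size; when centering would push it outside the
#' volume it is translated back inside.
#'
#' @param center voxel triple (0-based).
#' @param size box size triple.
#' @param shape volume shape.
#' @return a [bounding_box()].
#' @export
make_bbox <- function(center, size, shape) {
  size <- as.integer(round(size)); shape <- as.integer(shape)
  if (any(size > shape)) stop("size error: box size exceeds volume shape")
  origin <- as.integer(round(center - size / 2))
  origin <- pmin(pmax(origin, 0L), shape - size)
  bounding_box(origin, size)
}

#' Dataset-level bounding-box size
#'
#' Maximum pancreas extent over the cohort plus a margin, the default box
#' size of the fine stage.
#'
#' @param manifest cohort manifest.
#' @param margin voxels added per axis.
#' @return integer size triple.
#' @export
cohort_bbox_size <- function(manifest, margin = 16L) {
  ext <- c(0L, 0L, 0L)
  for (i in seq_len(nrow(manifest))) {
    lab <- read_labels(manifest$label_path[i])$labels
    idx <- which(lab > 0L, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    ext <- pmax(ext, apply(idx, 2, max) - apply(idx, 2, min) + 1L)
  }
  as.integer(ext + margin)
}
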