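# Synthetic CT phantoms: textured ellipsoidal pancreas with an embedded
# low-contrast tumor, tubular vessels, soft-tissue background noise.
# These provide geometric ground truth (analytic shapes rasterized at voxel
# centers) so every downstream module is testable without any dataset.

#' Phantom configuration
#'
#' Defines the geometry and contrast of generated CT-like volumes. Voxel
#' `(i, j, k)` (0-based) sits at physical position `(i, j, k) * spacing_mm`;
#' shapes are rasterized by testing voxel centers against the analytic
#' surface, so labeled voxel counts are exactly recoverable by enumeration.
#'
#' Default intensities are CT-like arbitrary units: background around -50,
#' pancreas around +80, tumor at pancreas + `tumor_contrast` (default -30,
#' emulating the poor tumor/parenchyma contrast of PDAC), vessels around
#' +200. Intra-organ texture is band-limited multiplicative noise so that
#' texture descriptors computed on the organ are informative.
#'
#' @param shape voxel grid triple; every axis must be >= 64 when the volume
#'   is to feed the localizer. The desk-scale default 160 x 160 x 96 keeps
#'   the organ a small fraction of the field of view (as in abdominal CT),
#'   so zero-overlap background sub-volumes exist for localizer training.
#' @param spacing_mm positive voxel spacing triple (mm).
#' @param pancreas_axes_mm ellipsoid semi-axes (mm).
#' @param tumor_radius_mm tumor sphere radius (mm); must fit inside the
#'   pancreas ellipsoid.
#' @param tumor_contrast signed intensity offset of the tumor relative to
#'   pancreas tissue.
#' @param vessel_radius_mm tube radius for vessels (mm).
#' @param vessel_waviness_mm sinusoidal amplitude of the vessel centerlines;
#'   0 gives straight tubes.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param texture_strength relative amplitude of intra-organ texture.
#' @param center_jitter_frac uniform jitter of the pancreas center as a
#'   fraction of the field of view.
#' @param seed integer RNG seed; identical seeds give identical volumes.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(160, 160, 96),
                           spacing_mm = c(1, 1, 1),
                           pancreas_axes_mm = c(20, 12, 10),
                           tumor_radius_mm = 6,
                           tumor_contrast = -30,
                           vessel_radius_mm = 2.5,
                           vessel_waviness_mm = 4,
                           noise_sd = 10,
                           texture_strength = 0.3,
                           center_jitter_frac = 0.05,
                           seed = 1L) {
  cfg <- list(shape = as.integer(shape), spacing_mm = as.numeric(spacing_mm),
              pancreas_axes_mm = as.numeric(pancreas_axes_mm),
              tumor_radius_mm = tumor_radius_mm,
              tumor_contrast = tumor_contrast,
              vessel_radius_mm = vessel_radius_mm,
              vessel_waviness_mm = vessel_waviness_mm,
              noise_sd = noise_sd, texture_strength = texture_strength,
              center_jitter_frac = center_jitter_frac,
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

#' Full-size phantom preset
#'
#' The 512 x 512 x L anisotropic geometry of abdominal CT, for integration
#' runs; desk-scale work uses the 96^3 default of [phantom_config()].
#' @param ... overrides passed to [phantom_config()].
#' @export
phantom_config_fullsize <- function(...) {
  phantom_config(shape = c(512, 512, 96), spacing_mm = c(0.8, 0.8, 2.5),
                 pancreas_axes_mm = c(55, 35, 30), tumor_radius_mm = 12,
                 vessel_radius_mm = 5, ...)
}

validate_phantom_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) stop("configuration error in '", field, "': ", why, call. = FALSE)
  }
  chk(length(cfg$shape) == 3 && all(cfg$shape >= 8), "shape",
      "need a voxel triple >= 8 per axis")
  chk(all(cfg$spacing_mm > 0), "spacing_mm", "must be strictly positive")
  chk(length(cfg$pancreas_axes_mm) == 3 && all(cfg$pancreas_axes_mm > 0),
      "pancreas_axes_mm", "must be 3 strictly positive semi-axes")
  chk(is.numeric(cfg$tumor_radius_mm) && cfg$tumor_radius_mm > 0,
      "tumor_radius_mm", "must be strictly positive")
  chk(cfg$tumor_radius_mm < min(cfg$pancreas_axes_mm), "tumor_radius_mm",
      "tumor must fit inside the pancreas ellipsoid")
  chk(cfg$vessel_radius_mm > 0, "vessel_radius_mm",
      "must be strictly positive")
  chk(cfg$vessel_waviness_mm >= 0, "vessel_waviness_mm",
      "must be non-negative")
  chk(cfg$noise_sd >= 0, "noise_sd", "must be non-negative")
  chk(cfg$texture_strength >= 0, "texture_strength", "must be non-negative")
  invisible(cfg)
}

# Linear resize of a 3D array to a new grid (separable, axis by axis, via
# small dense interpolation matrices so BLAS does the work).
resize_trilinear <- function(arr, newdim) {
  interp_mat <- function(n_out, n_in) {
    if (n_in == 1) return(matrix(1, n_out, 1))
    s <- seq(0, n_in - 1, length.out = n_out)
    lo <- pmin(floor(s), n_in - 2)
    fr <- s - lo
    m <- matrix(0, n_out, n_in)
    m[cbind(seq_len(n_out), lo + 1)] <- 1 - fr
    m[cbind(seq_len(n_out), lo + 2)] <- fr
    m
  }
  d <- dim(arr)
  for (ax in 1:3) {
    d <- dim(arr)
    m <- interp_mat(newdim[ax], d[ax])
    x <- aperm(arr, c(ax, setdiff(1:3, ax)))
    x <- m %*% matrix(x, nrow = d[ax])
    dim(x) <- c(newdim[ax], d[setdiff(1:3, ax)])
    arr <- aperm(x, order(c(ax, setdiff(1:3, ax))))
  }
  arr
}

# Band-limited unit-variance random field: coarse white noise linearly
# upsampled to the target grid.
texture_field <- function(shape, coarse = 4) {
  cd <- pmax(2L, ceiling(shape / coarse))
  f <- resize_trilinear(array(stats::rnorm(prod(cd)), dim = cd), shape)
  s <- stats::sd(f)
  if (s > 0) f <- (f - mean(f)) / s
  f
}

# Physical voxel-center coordinate grids (mm), as three 1D vectors.
coord_axes <- function(shape, spacing) {
  lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a])
}

ellipsoid_mask <- function(shape, spacing, center, axes) {
  co <- coord_axes(shape, spacing)
  tx <- ((co[[1]] - center[1]) / axes[1])^2
  ty <- ((co[[2]] - center[2]) / axes[2])^2
  tz <- ((co[[3]] - center[3]) / axes[3])^2
  outer(outer(tx, ty, `+`), tz, `+`) <= 1
}

sphere_mask <- function(shape, spacing, center, radius) {
  ellipsoid_mask(shape, spacing, center, rep(radius, 3))
}

# Tube along z with sinusoidal centerline; same phase/amplitude for all
# tubes of a phantom so parallel tubes never intersect.
tube_mask <- function(shape, spacing, base_xy, radius, amplitude, phase) {
  co <- coord_axes(shape, spacing)
  z <- co[[3]]
  L <- max(z[length(z)], spacing[3])
  cx <- base_xy[1] + amplitude * sin(2 * pi * z / L + phase)
  cy <- base_xy[2] + amplitude * cos(2 * pi * z / L + phase)
  m <- array(FALSE, dim = shape)
  for (k in seq_len(shape[3])) {
    dx2 <- (co[[1]] - cx[k])^2
    dy2 <- (co[[2]] - cy[k])^2
    m[, , k] <- outer(dx2, dy2, `+`) <= radius^2
  }
  m
}

#' Generate a pancreas/tumor CT phantom
#'
#' Returns an intensity volume and an aligned label volume with classes
#' `{0 = background, 1 = pancreas, 2 = tumor}`. The tumor sphere is placed
#' strictly inside the pancreas ellipsoid; two bright unlabeled vessel
#' tubes run through the background. Deterministic under `config$seed`.
#'
#' @param config a [phantom_config()].
#' @return list with elements `image` ([ct_volume()]), `labels`
#'   ([label_volume()]) and `meta` (analytic geometry: centers, axes, radii
#'   in mm), for use as ground truth in tests and evaluations.
#' @export
generate_phantom <- function(config) {
  validate_phantom_config(config)
  set.seed(config$seed)
  shape <- config$shape; sp <- config$spacing_mm
  fov <- (shape - 1) * sp
  jit <- config$center_jitter_frac * fov
  pc <- fov / 2 + stats::runif(3, -jit, jit)

  # tumor center: random direction, magnitude keeping the sphere inside
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  en_u <- sqrt(sum((u / config$pancreas_axes_mm)^2))
  m_max <- max(0, (1 - config$tumor_radius_mm / min(config$pancreas_axes_mm)) / en_u)
  tc <- pc + stats::runif(1, 0, m_max) * u

  panc <- ellipsoid_mask(shape, sp, pc, config$pancreas_axes_mm)
  tum <- sphere_mask(shape, sp, tc, config$tumor_radius_mm) & panc
  if (!any(tum))
    stop("configuration error in 'tumor_radius_mm': no voxel center falls ",
         "inside the tumor sphere at this spacing")

  labels <- array(0L, dim = shape)
  labels[panc] <- 1L
  labels[tum] <- 2L

  img <- array(-50, dim = shape)
  tex <- texture_field(shape)
  organ <- 80 * (1 + config$texture_strength * tex)
  tumor_int <- (80 + config$tumor_contrast) * (1 + config$texture_strength * tex)
  img[panc] <- organ[panc]
  img[tum] <- tumor_int[tum]

  # unlabeled bright tubes in the background (vascular clutter)
  phase <- stats::runif(1, 0, 2 * pi)
  off <- min(fov[1:2]) * 0.30
  v1 <- tube_mask(shape, sp, fov[1:2] / 2 + c(off, off * 0.4),
                  config$vessel_radius_mm, config$vessel_waviness_mm, phase)
  v2 <- tube_mask(shape, sp, fov[1:2] / 2 + c(off + 3 * config$vessel_radius_mm,
                                              -off * 0.4),
                  config$vessel_radius_mm, config$vessel_waviness_mm, phase)
  ves <- (v1 | v2) & labels == 0L
  img[ves] <- 200

  img <- img + stats::rnorm(length(img), sd = config$noise_sd)
  dim(img) <- shape

  list(image = ct_volume(img, sp),
       labels = label_volume(labels, spacing_mm = sp),
       meta = list(pancreas_center_mm = pc, tumor_center_mm = tc,
                   pancreas_axes_mm = config$pancreas_axes_mm,
                   tumor_radius_mm = config$tumor_radius_mm))
}

#' Generate a vessel CT phantom
#'
#' Two disjoint bright tubular structures following smooth 3D curves,
#' labeled `{0 = background, 1 = SMA, 2 = SMV}`, over a soft-tissue
#' background containing an unlabeled pancreas-like ellipsoid.
#'
#' @inheritParams generate_phantom
#' @return list with `image`, `labels`, `meta` as in [generate_phantom()].
#' @export
generate_vessel_phantom <- function(config) {
  validate_phantom_config(config)
  set.seed(config$seed + 1L)
  shape <- config$shape; sp <- config$spacing_mm
  fov <- (shape - 1) * sp
  r <- config$vessel_radius_mm
  sep <- 2 * r + 4
  phase <- stats::runif(1, 0, 2 * pi)
  jit <- stats::runif(2, -0.03, 0.03) * fov[1:2]
  sma_base <- fov[1:2] / 2 + c(-sep / 2, 0) + jit
  smv_base <- fov[1:2] / 2 + c(sep / 2, 0) + jit
  sma <- tube_mask(shape, sp, sma_base, r, config$vessel_waviness_mm, phase)
  smv <- tube_mask(shape, sp, smv_base, r, config$vessel_waviness_mm, phase)
  smv <- smv & !sma  # parallel construction keeps them disjoint anyway

  labels <- array(0L, dim = shape)
  labels[sma] <- 1L
  labels[smv] <- 2L

  img <- array(-50, dim = shape)
  tex <- texture_field(shape)
  panc <- ellipsoid_mask(shape, sp, fov / 2 + c(0, -0.2 * fov[2], 0),
                         config$pancreas_axes_mm)
  organ <- 80 * (1 + config$texture_strength * tex)
  img[panc] <- organ[panc]
  img[sma | smv] <- 200
  img <- img + stats::rnorm(length(img), sd = config$noise_sd)
  dim(img) <- shape

  list(image = ct_volume(img, sp),
       labels = label_volume(labels, class_names = c("background", "SMA", "SMV"),
                             spacing_mm = sp),
       meta = list(vessel_radius_mm = r, phase = phase,
                   sma_base_mm = sma_base, smv_base_mm = smv_base))
}

#' Generate a phantom cohort on disk
#'
#' Writes `n` phantom cases as NIfTI image/label pairs plus a JSON manifest
#' recording a reproducible random train/test split with
#' `|train| = round(split_fraction * n)`.
#'
#' @param n number of cases (>= 2).
#' @param config base [phantom_config()]; each case gets a derived seed.
#' @param split_fraction training fraction in (0, 1); the default follows
#'   the usual random 70-30 protocol.
#' @param seed split/case-seed RNG seed.
#' @param out_dir output directory (created if needed).
#' @param task `"pancreas"` or `"vessel"`.
#' @return data.frame manifest (case_id, image_path, label_path, split),
#'   also written to `out_dir/manifest.json`.
#' @export
generate_cohort <- function(n, config, split_fraction = 0.7, seed = 1L,
                            out_dir, task = c("pancreas", "vessel")) {
  task <- match.arg(task)
  if (n < 2) stop("n must be >= 2")
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must be in (0, 1)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create ", out_dir)
  set.seed(seed)
  n_train <- round(split_fraction * n)
  train_idx <- sample(n, n_train)
  case_seeds <- (as.integer(seed) * 131L + seq_len(n) * 7919L) %% 2147483647L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config
    cfg$seed <- case_seeds[i]
    ph <- if (task == "pancreas") generate_phantom(cfg)
          else generate_vessel_phantom(cfg)
    cid <- sprintf("case_%03d", i)
    ip <- file.path(out_dir, paste0(cid, "_image.nii.gz"))
    lp <- file.path(out_dir, paste0(cid, "_label.nii.gz"))
    write_volume(ph$image, ip)
    write_volume(ph$labels, lp)
    rows[[i]] <- data.frame(case_id = cid, image_path = ip, label_path = lp,
                            split = if (i %in% train_idx) "train" else "test",
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  attr(manifest, "task") <- task
  manifest
}

#' Read a cohort manifest written by [generate_cohort()]
#' @param path manifest.json path or its directory.
#' @return data.frame manifest.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
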