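# Classic texture descriptors fused into the segmentation networks:
# rotation-invariant uniform 2D LBP, rotation-invariant 3D LBP built from
# spherical-harmonic band energies plus kurtosis, and dense SIFT maps.

pad_replicate_2d <- function(img, p) {
  H <- nrow(img); W <- ncol(img)
  ri <- pmin(pmax(seq_len(H + 2 * p) - p, 1), H)
  ci <- pmin(pmax(seq_len(W + 2 * p) - p, 1), W)
  img[ri, ci, drop = FALSE]
}

pad_replicate_3d <- function(arr, p) {
  d <- dim(arr)
  ix <- lapply(1:3, function(a) pmin(pmax(seq_len(d[a] + 2 * p) - p, 1), d[a]))
  arr[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

# Bilinear sample of padded image at constant offset `off` for every pixel
# of the original grid; `p` is the pad width of `imgp`.
shift_bilinear_2d <- function(imgp, off, p, H, W) {
  f <- floor(off); r <- off - f
  g <- function(di, dj) imgp[seq_len(H) + p + f[1] + di,
                             seq_len(W) + p + f[2] + dj, drop = FALSE]
  (1 - r[1]) * (1 - r[2]) * g(0, 0) + r[1] * (1 - r[2]) * g(1, 0) +
    (1 - r[1]) * r[2] * g(0, 1) + r[1] * r[2] * g(1, 1)
}

shift_trilinear_3d <- function(arrp, off, p, d) {
  shift3d_cpp(arrp, as.integer(d), as.integer(p), as.numeric(off))
}

#' Rotation-invariant uniform 2D LBP codes
#'
#' Compares `n_points` circularly sampled neighbors (bilinear interpolation,
#' replicate padding) against the center pixel and emits the
#' rotation-invariant uniform code: the number of set bits when the circular
#' bit pattern has at most two 0/1 transitions, else `n_points + 1`. Codes
#' therefore lie in `[0, n_points + 1]`.
#'
#' @param image numeric matrix, at least `2 * radius + 1` on each side.
#' @param radius sampling circle radius in pixels (>= 1).
#' @param n_points number of circle samples (>= 4); multiples of 4 make the
#'   code map exactly equivariant under 90-degree rotations.
#' @return integer matrix of codes, same shape as `image`.
#' @export
lbp2d <- function(image, radius = 1, n_points = 8L) {
  if (radius < 1) stop("radius must be >= 1")
  if (n_points < 4) stop("n_points must be >= 4")
  H <- nrow(image); W <- ncol(image)
  if (min(H, W) < 2 * radius + 1)
    stop("size error: image smaller than 2*radius + 1")
  p <- ceiling(radius) + 1L
  imgp <- pad_replicate_2d(image, p)
  P <- as.integer(n_points)
  bits <- matrix(0L, H * W, P)
  for (k in seq_len(P)) {
    a <- 2 * pi * (k - 1) / P
    off <- radius * c(-sin(a), cos(a))
    # snap near-integer offsets so cardinal directions sample exactly
    snap <- abs(off - round(off)) < 1e-9
    off[snap] <- round(off[snap])
    s <- shift_bilinear_2d(imgp, off, p, H, W)
    bits[, k] <- as.integer(s >= image)
  }
  trans <- rowSums(bits != bits[, c(2:P, 1), drop = FALSE])
  code <- ifelse(trans <= 2, rowSums(bits), P + 1L)
  matrix(as.integer(code), H, W)
}

# double factorial (2m-1)!!
dfact_odd <- function(m) if (m == 0) 1 else prod(seq(1, 2 * m - 1, by = 2))

# Associated Legendre P_l^m(x) (Condon-Shortley phase), l >= m >= 0.
alegendre <- function(l, m, x) {
  pmm <- (-1)^m * dfact_odd(m) * (1 - x^2)^(m / 2)
  if (l == m) return(pmm)
  pm1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pm1)
  for (ll in (m + 2):l) {
    p <- ((2 * ll - 1) * x * pm1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pm1; pm1 <- p
  }
  pm1
}

# Real orthonormal spherical harmonics evaluated at unit directions.
# Returns a J x (L+1)^2 matrix plus the band (l) of each column.
sh_basis <- function(dirs, L) {
  z <- dirs[, 3]
  phi <- atan2(dirs[, 2], dirs[, 1])
  M <- (L + 1)^2
  Y <- matrix(0, nrow(dirs), M)
  band <- integer(M)
  col <- 1
  for (l in 0:L) for (m in -l:l) {
    am <- abs(m)
    N <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - am) / factorial(l + am))
    P <- alegendre(l, am, z)
    Y[, col] <- if (m == 0) N * P
                else if (m > 0) sqrt(2) * N * P * cos(am * phi)
                else sqrt(2) * N * P * sin(am * phi)
    band[col] <- l
    col <- col + 1
  }
  list(Y = Y, band = band)
}

lbp3d_dirs <- function(n_dirs) {
  if (n_dirs == 26) {
    g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
    g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else if (n_dirs == 6) {
    g <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  } else {
    stop("configuration error: n_dirs must be 6 or 26 (symmetric designs ",
         "closed under 90-degree rotations)")
  }
  g / sqrt(rowSums(g^2))
}

#' Rotation-invariant 3D LBP map
#'
#' For every voxel, intensity differences to `n_dirs` quasi-uniform
#' directions on a sphere of radius `radius_vox` (trilinear interpolation,
#' replicate padding) are projected onto real spherical harmonics up to
#' order `sh_order`. The per-band energy (sum over m of squared
#' coefficients) is invariant under any rotation that permutes the
#' direction set -- exactly so, for the default 26-direction design, under
#' all 24 axis-aligned 90-degree rotations. The kurtosis of the difference
#' sample is kept as a separate channel (0 for zero-variance samples).
#'
#' @param volume a normalized [ct_volume()] or a bare 3D array.
#' @param radius_vox sphere radius in voxels (>= 1).
#' @param sh_order maximum spherical-harmonic order L (>= 0).
#' @param n_dirs number of sphere directions; must satisfy
#'   `n_dirs >= (sh_order + 1)^2` and be one of the symmetric designs
#'   (6 or 26).
#' @return object of class `lbp3d_map`: `band_energies` array
#'   `(X, Y, Z, L + 1)`, `kurtosis` array `(X, Y, Z)`, plus parameters.
#' @export
lbp3d <- function(volume, radius_vox = 2, sh_order = 2L, n_dirs = 26L) {
  spacing <- c(1, 1, 1)
  if (inherits(volume, "ct_volume")) {
    if (!volume$normalized)
      stop("volume must be normalized (run preprocess() first)")
    spacing <- volume$spacing_mm
    arr <- volume$voxels
  } else arr <- volume
  if (radius_vox < 1) stop("radius_vox must be >= 1")
  if (sh_order < 0) stop("sh_order must be >= 0")
  if (n_dirs < (sh_order + 1)^2)
    stop("configuration error: n_dirs too small for requested sh_order")
  dirs <- lbp3d_dirs(n_dirs)
  J <- nrow(dirs)
  sh <- sh_basis(dirs, sh_order)
  d <- dim(arr)
  N <- prod(d)
  p <- as.integer(ceiling(radius_vox))
  arrp <- pad_replicate_3d(arr, p)
  ctr <- as.numeric(arr)

  core <- lbp3d_core_cpp(arrp, as.numeric(arr), as.integer(d),
                         as.integer(p), dirs * radius_vox, sh$Y)
  coef <- core$coef
  m1 <- core$m1; m2 <- core$m2; m3 <- core$m3; m4 <- core$m4
  v <- m2 - m1^2
  m4c <- m4 - 4 * m3 * m1 + 6 * m2 * m1^2 - 3 * m1^4
  # zero-variance convention: samples whose variance is at floating-point
  # dust level (relative to the volume's liveliest neighborhood) get 0
  scale_floor <- (1e-13 * (max(abs(arr)) + 1))^2
  vthr <- max(max(v, 0) * 1e-12, scale_floor)
  kurt <- numeric(N)
  live <- v > vthr
  kurt[live] <- m4c[live] / v[live]^2

  L <- sh_order
  be <- array(0, dim = c(d, L + 1))
  for (l in 0:L) {
    cols <- which(sh$band == l)
    e <- rowSums(coef[, cols, drop = FALSE]^2)
    be[, , , l + 1] <- e
  }
  structure(list(band_energies = be, kurtosis = array(kurt, dim = d),
                 radius_vox = radius_vox, sh_order = sh_order,
                 n_dirs = n_dirs, dirs = dirs, spacing_mm = spacing),
            class = "lbp3d_map")
}

#' Scalar encoding of a 3D LBP map
#'
#' Reduces the multi-band invariant map to one scalar per voxel: the
#' min-max-normalized sum of band energies (optionally with the kurtosis
#' channel added after its own min-max normalization). This is the volume
#' the localizer classifies and the slice source for last-layer fusion.
#'
#' @param map an [lbp3d()] result.
#' @param encoding `"energy_sum"` (default) or `"energy_kurt"`.
#' @return a normalized [ct_volume()] with values in `[0, 1]`.
#' @export
lbp3d_scalar <- function(map, encoding = c("energy_sum", "energy_kurt")) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(map, "lbp3d_map"))
  d <- dim(map$kurtosis)
  L1 <- dim(map$band_energies)[4]
  s <- rowSums(matrix(map$band_energies, ncol = L1))
  minmax <- function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(x * 0)
    (x - rng[1]) / (rng[2] - rng[1])
  }
  s <- minmax(s)
  if (encoding == "energy_kurt") s <- minmax(s + minmax(as.numeric(map$kurtosis)))
  ct_volume(array(s, dim = d), spacing_mm = map$spacing_mm, normalized = TRUE)
}

#' Dense SIFT descriptor grid
#'
#' 128-component gradient-orientation-histogram descriptors (4 x 4 spatial
#' cells of side `step`, 8 orientation bins) computed at every node of a
#' grid with stride `step`; no keypoint detection. Descriptors are
#' L2-normalized with the usual clip(0.2)-renormalize step; flat patches
#' yield zero vectors, so every descriptor norm lies in `[0, 1]`.
#'
#' @param image numeric matrix.
#' @param step sampling stride (>= 1); the grid has
#'   `ceiling(H / step) x ceiling(W / step)` nodes.
#' @return object of class `dense_sift_map` with `descriptors` array
#'   `(grid_h, grid_w, 128)` and the geometry parameters.
#' @export
dense_sift <- function(image, step = 4L) {
  step <- as.integer(step)
  if (step < 1) stop("step must be >= 1")
  H <- nrow(image); W <- ncol(image)
  if (step > min(H, W)) stop("size error: step larger than image")
  ip <- pad_replicate_2d(image, 1)
  gr <- (ip[3:(H + 2), 2:(W + 1)] - ip[1:H, 2:(W + 1)]) / 2
  gc <- (ip[2:(H + 1), 3:(W + 2)] - ip[2:(H + 1), 1:W]) / 2
  mag <- sqrt(gr^2 + gc^2)
  ang <- atan2(gr, gc) %% (2 * pi)
  bin <- pmin(floor(ang / (pi / 4)), 7)

  rs <- seq(1, H, by = step); cs <- seq(1, W, by = step)
  gh <- length(rs); gw <- length(cs)
  desc <- array(0, dim = c(gh, gw, 128))

  # integral image per orientation bin; cell sums by rectangle differences
  for (b in 0:7) {
    m <- mag * (bin == b)
    S <- matrix(0, H + 1, W + 1)
    S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
    rect <- function(r0, r1, c0, c1) {
      r0 <- pmax(r0, 1); c0 <- pmax(c0, 1)
      r1 <- pmin(r1, H); c1 <- pmin(c1, W)
      bad_r <- r0 > r1; bad_c <- c0 > c1
      r0 <- pmin(r0, H); r1 <- pmax(r1, 1)
      c0 <- pmin(c0, W); c1 <- pmax(c1, 1)
      out <- outer(seq_len(gh), seq_len(gw), function(i, j)
        S[cbind(r1[i] + 1, c1[j] + 1)] - S[cbind(r0[i], c1[j] + 1)] -
          S[cbind(r1[i] + 1, c0[j])] + S[cbind(r0[i], c0[j])])
      out[bad_r, ] <- 0
      out[, bad_c] <- 0
      out
    }
    for (u in 1:4) for (v in 1:4) {
      r0 <- rs + (u - 3L) * step; r1 <- r0 + step - 1L
      c0 <- cs + (v - 3L) * step; c1 <- c0 + step - 1L
      ch <- ((u - 1) * 4 + (v - 1)) * 8 + b + 1
      desc[, , ch] <- rect(r0, r1, c0, c1)
    }
  }

  dm <- matrix(desc, ncol = 128)
  nrm <- sqrt(rowSums(dm^2))
  nz <- nrm > 0
  dm[nz, ] <- dm[nz, , drop = FALSE] / nrm[nz]
  dm <- pmin(dm, 0.2)
  nrm2 <- sqrt(rowSums(dm^2))
  nz <- nrm2 > 0
  dm[nz, ] <- dm[nz, , drop = FALSE] / nrm2[nz]
  desc <- array(dm, dim = c(gh, gw, 128))
  structure(list(descriptors = desc, step = step, cells = 4L, bins = 8L),
            class = "dense_sift_map")
}

#' Standardized texture feature tensors for network fusion
#'
#' Dense SIFT (or the LBP scalar slice) standardized per channel to zero
#' mean and unit variance over the image, the form in which texture maps
#' are concatenated into the network.
#'
#' @param image 2D slice (normalized intensities).
#' @param step SIFT sampling stride.
#' @return array `(H/step, W/step, 128)`.
#' @export
sift_feature_tensor <- function(image, step = 4L) {
  ds <- dense_sift(image, step)
  m <- matrix(ds$descriptors, ncol = 128)
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  m <- sweep(m, 2, mu)
  pos <- s > 0
  m[, pos] <- sweep(m[, pos, drop = FALSE], 2, s[pos], `/`)
  m[, !pos] <- 0
  array(m, dim = dim(ds$descriptors))
}

#' Standardized LBP scalar slice for last-layer fusion
#' @param slice 2D matrix from the LBP scalar volume.
#' @return `(H, W, 1)` array, standardized.
#' @export
lbp_feature_tensor <- function(slice) {
  s <- stats::sd(slice)
  out <- if (s > 0) (slice - mean(slice)) / s else slice * 0
  array(out, dim = c(nrow(slice), ncol(slice), 1))
}
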