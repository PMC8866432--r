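# Shared fixtures and independent oracles used across the suite.

# small deterministic phantom config for fast tests
tiny_phantom_config <- function(seed = 1L, ...) {
  phantom_config(shape = c(72, 72, 72), pancreas_axes_mm = c(16, 10, 8),
                 tumor_radius_mm = 5, seed = seed, ...)
}

# --- axis-aligned rotations ------------------------------------------------

# all 24 proper rotations as (axis permutation, per-axis flips)
rotations24 <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) for (f1 in c(1, -1)) for (f2 in c(1, -1))
    for (f3 in c(1, -1)) {
      R <- matrix(0, 3, 3)
      flips <- c(f1, f2, f3)
      for (a in 1:3) R[a, p[a]] <- flips[a]
      if (abs(det(R) - 1) < 1e-9)
        out[[length(out) + 1]] <- list(perm = p, flips = flips)
    }
  out
}

apply_rot <- function(arr, rot) {
  a <- aperm(arr, rot$perm)
  idx <- lapply(1:3, function(k) {
    n <- dim(a)[k]
    if (rot$flips[k] < 0) n:1 else 1:n
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# --- morphology oracle -----------------------------------------------------

# dilation-based boundary oracle: mask pixel is boundary iff some
# in-window neighbor (k x k, clipped at borders) is background
boundary_oracle <- function(mask, k = 3L) {
  H <- nrow(mask); W <- ncol(mask); r <- (k - 1) / 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] == 0) next
    win <- mask[max(1, i - r):min(H, i + r), max(1, j - r):min(W, j + r)]
    if (any(win == 0)) out[i, j] <- 1
  }
  out
}

# --- misc ------------------------------------------------------------------

rand_label_slice <- function(H = 16, W = 16, n_classes = 3, seed = 1) {
  set.seed(seed)
  matrix(sample(0:(n_classes - 1), H * W, replace = TRUE), H, W)
}

rand_probs <- function(H = 16, W = 16, C = 3, seed = 1) {
  set.seed(seed)
  z <- array(stats::rnorm(H * W * C), c(H, W, C))
  m <- exp(matrix(z, ncol = C))
  array(m / rowSums(m), c(H, W, C))
}

coverage_of_box <- function(box, labels) {
  inb <- array(FALSE, dim(labels))
  inb[box$origin[1] + seq_len(box$size[1]),
      box$origin[2] + seq_len(box$size[2]),
      box$origin[3] + seq_len(box$size[3])] <- TRUE
  mean(inb[labels > 0])
}
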