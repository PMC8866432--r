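# Composite imbalance-aware loss: weighted pixel-wise cross entropy (WPCE),
# generalized Dice loss (GDL), and a differentiable boundary-F1 loss whose
# boundary bands are built with stride-1 max filters. Every loss returns a
# scalar; with `with_grad = TRUE` it also returns the analytic gradient
# with respect to the prediction V, so the same code drives both training
# and finite-difference verification.

#' One-hot encoding of an integer label grid
#'
#' @param labels integer array/matrix with values `0..n_classes-1`.
#' @param n_classes number of classes (background = class 0 = channel 1).
#' @return array with one extra trailing channel dimension.
#' @export
one_hot <- function(labels, n_classes = 3L) {
  d <- dim(labels)
  if (is.null(d)) d <- length(labels)
  out <- array(0, dim = c(d, n_classes))
  m <- matrix(out, ncol = n_classes)
  m[cbind(seq_along(labels), as.integer(labels) + 1L)] <- 1
  array(m, dim = c(d, n_classes))
}

as_class_matrix <- function(x) {
  d <- dim(x)
  C <- d[length(d)]
  list(m = matrix(x, ncol = C), d = d, C = C)
}

#' Weighted pixel-wise cross entropy (WPCE)
#'
#' Mean over voxels of `-sum_c W_c U_ic log(V_ic)` with the background
#' weight fixed to 1 and each foreground class weighted by the
#' background-to-class pixel-count ratio `W_c = n_B / n_c`, computed on the
#' batch at hand. A class absent from the batch gets weight 0 with a
#' warning.
#'
#' @param U one-hot target array `(..., C)`, background in channel 1.
#' @param V prediction array of the same shape, values in (0, 1).
#' @param weights optional fixed per-class weights overriding the
#'   `n_B / n_c` rule.
#' @param eps clamp keeping `log` finite.
#' @param with_grad also return `grad`, d(loss)/dV.
#' @return scalar loss, or `list(value, grad)` when `with_grad`.
#' @export
wpce <- function(U, V, weights = NULL, eps = 1e-7, with_grad = FALSE) {
  stopifnot(all(dim(U) == dim(V)))
  u <- as_class_matrix(U); v <- as_class_matrix(V)
  N <- nrow(u$m)
  counts <- colSums(u$m)
  if (is.null(weights)) {
    nB <- counts[1]
    weights <- c(1, nB / counts[-1])
    if (any(counts[-1] == 0)) {
      warning("class absent from batch: weight set to 0")
      weights[c(FALSE, counts[-1] == 0)] <- 0
    }
  }
  vc <- pmin(pmax(v$m, eps), 1)
  wl <- sweep(u$m * log(vc), 2, weights, `*`)
  value <- -sum(wl) / N
  if (!with_grad) return(value)
  g <- -sweep(u$m / vc, 2, weights, `*`) / N
  g[v$m < eps | v$m > 1] <- 0
  grad <- array(g, dim = dim(V))
  list(value = value, grad = grad)
}

#' Generalized Dice loss (GDL)
#'
#' `1 - 2 (sum_c W_c sum_i V U + eps) / (sum_c W_c sum_i (V + U) + eps)`
#' with inverse-squared-volume class weights `W_c = 1 / (sum_i U_ic)^2`;
#' classes with no target voxels get weight 0. Supply the channels you
#' want weighted -- all one-hot channels for multi-class training, or a
#' single binary foreground channel.
#'
#' @inheritParams wpce
#' @param eps smoothing term guarding the ratio.
#' @return scalar in `[0, 1]`, or `list(value, grad)`.
#' @export
gdl <- function(U, V, eps = 1e-5, with_grad = FALSE) {
  stopifnot(all(dim(U) == dim(V)))
  du <- dim(U)
  C <- if (is.matrix(U) || is.null(du)) 1L else du[length(du)]
  um <- matrix(U, ncol = C)
  vm <- matrix(V, ncol = C)
  S <- colSums(um)
  W <- ifelse(S > 0, 1 / S^2, 0)
  num <- sum(W * colSums(vm * um)) + eps
  den <- sum(W * colSums(vm + um)) + eps
  value <- max(0, 1 - 2 * num / den)
  if (!with_grad) return(value)
  # d/dV_ic = -2 (W_c U_ic den - num W_c) / den^2
  g <- -2 * (sweep(um, 2, W, `*`) * den - matrix(W, nrow(um), ncol(um),
                                                 byrow = TRUE) * num) / den^2
  grad <- array(g, dim = dim(V))
  list(value = value, grad = grad)
}

maxfilt <- function(x, k) maxfilt2d_fwd_cpp(as.matrix(x), as.integer(k))

#' Inner boundary band of a binary mask
#'
#' `max_pool(1 - mask, theta0) - (1 - mask)`: a stride-1 max filter widens
#' the segment complement, and subtracting the original complement leaves
#' the inner boundary band of width `(theta0 - 1) / 2`. Windows are clipped
#' at the image border.
#'
#' @param mask binary matrix.
#' @param theta0 odd kernel size >= 3.
#' @return binary matrix marking the boundary band.
#' @export
extract_boundary <- function(mask, theta0 = 3L) {
  if (theta0 < 3 || theta0 %% 2 == 0) stop("theta0 must be odd and >= 3")
  if (!all(mask %in% c(0, 1))) stop("domain error: mask must be binary")
  mask <- as.matrix(mask)
  comp <- 1 - mask
  maxfilt(comp, theta0)$y - comp
}

# Soft boundary band with gradient bookkeeping.
soft_boundary <- function(v, theta0) {
  comp <- 1 - v
  mf <- maxfilt(comp, theta0)
  list(b = mf$y - comp, idx = mf$idx)
}

bf1_single <- function(ub, vb_info, theta, with_grad) {
  vb <- vb_info$b
  ub_ext <- maxfilt(ub, theta)$y
  vext <- maxfilt(vb, theta)
  vb_ext <- vext$y
  su <- sum(ub)
  sv <- sum(vb)
  if (su == 0) return(NULL)  # caller skips the class
  num_p <- sum(vb * ub_ext)
  num_r <- sum(ub * vb_ext)
  P <- if (sv > 0) num_p / sv else 0
  R <- num_r / su
  if (P + R == 0) {
    # both boundary bands miss each other's extension: worst case
    if (!with_grad) return(list(value = 1))
    return(list(value = 1, dvb = matrix(0, nrow(ub), ncol(ub)),
                vb_info = vb_info, vext_idx = vext$idx))
  }
  bf1 <- 2 * P * R / (P + R)
  value <- 1 - bf1
  if (!with_grad) return(list(value = value))
  dP <- -2 * R^2 / (P + R)^2
  dR <- -2 * P^2 / (P + R)^2
  # P = sum(vb * ub_ext) / sv
  dvb <- if (sv > 0) dP * (ub_ext * sv - num_p) / sv^2
         else matrix(0, nrow(ub), ncol(ub))
  # R depends on vb through vb_ext = maxfilt(vb, theta)
  dvb_ext <- dR * ub / su
  dvb <- dvb + maxfilt2d_bwd_cpp(dvb_ext, vext$idx)
  list(value = value, dvb = dvb, vb_info = vb_info, vext_idx = vext$idx)
}

#' Differentiable boundary-F1 loss
#'
#' Boundary bands of ground truth and (soft) prediction are built with
#' stride-1 max filters of size `theta0`, extended with max filters of size
#' `theta`; precision is the fraction of the predicted band falling inside
#' the extended true band and recall vice versa, and the loss is
#' `1 - 2PR / (P + R)`. Computed per foreground class and averaged; classes
#' with an empty ground-truth boundary are skipped with a warning, and a
#' degenerate `P = R = 0` case scores loss 1. The prediction enters
#' everywhere as its soft values, so the loss is differentiable in V
#' (max filters route gradients to their argmax).
#'
#' @param U binary matrix or one-hot array `(H, W, C)` (channel 1 =
#'   background, skipped).
#' @param V soft prediction of the same shape, values in `[0, 1]`.
#' @param theta0 boundary kernel (odd, >= 3).
#' @param theta extension kernel (odd, >= theta0).
#' @param with_grad also return d(loss)/dV.
#' @return scalar loss in `[0, 1]`, or `list(value, grad)`.
#' @export
boundary_f1_loss <- function(U, V, theta0 = 3L, theta = 3L,
                             with_grad = FALSE) {
  if (theta < theta0) stop("theta must be >= theta0")
  stopifnot(all(dim(U) == dim(V)))
  multi <- length(dim(U)) == 3
  classes <- if (multi) 2:dim(U)[3] else 1L
  vals <- c()
  grad <- if (with_grad) array(0, dim = dim(V)) else NULL
  for (cc in classes) {
    ub01 <- if (multi) U[, , cc] else as.matrix(U)
    vv <- if (multi) V[, , cc] else as.matrix(V)
    ub <- extract_boundary(ub01, theta0)
    if (sum(ub) == 0) {
      warning("empty ground-truth boundary: class skipped")
      next
    }
    vb_info <- soft_boundary(vv, theta0)
    res <- bf1_single(ub, vb_info, theta, with_grad)
    vals <- c(vals, res$value)
    if (with_grad && !is.null(res$dvb)) {
      # vb = maxfilt(1 - v, theta0) - (1 - v): gradient has a direct +dvb
      # term and a -(routed) term through the max filter
      dv <- res$dvb - maxfilt2d_bwd_cpp(res$dvb, vb_info$idx)
      if (multi) grad[, , cc] <- grad[, , cc] + dv else grad <- grad + dv
    }
  }
  if (length(vals) == 0) {
    value <- NA_real_
    if (with_grad) return(list(value = value, grad = grad))
    return(value)
  }
  value <- mean(vals)
  if (with_grad) list(value = value, grad = grad / length(vals)) else value
}

#' Composite total loss
#'
#' `0.33 * WPCE + 0.33 * GDL + 0.33 * BF1` with the printed weights as
#' defaults; each component can be reweighted or switched off, mirroring
#' the loss-ablation arms (GDL only, WPCE only, pairs, triple).
#'
#' @param U one-hot target `(H, W, C)`, background in channel 1.
#' @param V prediction of the same shape.
#' @param weights length-3 numeric: WPCE, GDL, BF1 coefficients.
#' @param theta0,theta boundary-loss kernels.
#' @param with_grad also return d(loss)/dV.
#' @return scalar, or `list(value, grad, components)`.
#' @export
total_loss <- function(U, V, weights = c(0.33, 0.33, 0.33), theta0 = 3L,
                       theta = 3L, with_grad = FALSE) {
  comp <- c(wpce = 0, gdl = 0, bf1 = 0)
  grad <- if (with_grad) array(0, dim = dim(V)) else NULL
  get <- function(res) if (with_grad) res$value else res
  if (weights[1] != 0) {
    r <- wpce(U, V, with_grad = with_grad)
    comp["wpce"] <- get(r)
    if (with_grad) grad <- grad + weights[1] * r$grad
  }
  if (weights[2] != 0) {
    r <- gdl(U, V, with_grad = with_grad)
    comp["gdl"] <- get(r)
    if (with_grad) grad <- grad + weights[2] * r$grad
  }
  if (weights[3] != 0) {
    r <- boundary_f1_loss(U, V, theta0, theta, with_grad = with_grad)
    val <- get(r)
    if (is.na(val)) val <- 0  # no class had a boundary: component inert
    comp["bf1"] <- val
    if (with_grad && !is.null(r$grad)) grad <- grad + weights[3] * r$grad
  }
  value <- sum(weights * comp)
  if (!with_grad) return(value)
  list(value = value, grad = grad, components = comp)
}
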