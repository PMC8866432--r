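# Evaluation metrics: confusion counts, Dice / recall / precision, the
# 95th-percentile Hausdorff distance in mm, and pooled-vs-per-case
# aggregation.

#' Voxelwise confusion counts
#'
#' @param U,V binary grids of identical shape (ground truth, prediction).
#' @return list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(U, V) {
  if (!all(dim(U) == dim(V))) stop("shape mismatch")
  u <- as.logical(U); v <- as.logical(V)
  tp <- sum(u & v)
  list(tp = tp, fp = sum(v) - tp, fn = sum(u) - tp,
       tn = length(u) - sum(u | v))
}

#' Dice similarity coefficient
#'
#' `2 * |intersection(U, V)| / (|U| + |V|)`; two empty masks score 1 by
#' convention.
#' @inheritParams confusion_counts
#' @return ratio in `[0, 1]`.
#' @export
dice <- function(U, V) {
  cc <- confusion_counts(U, V)
  den <- 2 * cc$tp + cc$fp + cc$fn
  if (den == 0) return(1)
  2 * cc$tp / den
}

#' Recall (sensitivity)
#' @inheritParams confusion_counts
#' @return `TP / (TP + FN)`; 1 when the ground truth is empty.
#' @export
recall <- function(U, V) {
  cc <- confusion_counts(U, V)
  if (cc$tp + cc$fn == 0) return(1)
  cc$tp / (cc$tp + cc$fn)
}

#' Precision (positive predictive value)
#' @inheritParams confusion_counts
#' @return `TP / (TP + FP)`; 1 when the prediction is empty.
#' @export
precision <- function(U, V) {
  cc <- confusion_counts(U, V)
  if (cc$tp + cc$fp == 0) return(1)
  cc$tp / (cc$tp + cc$fp)
}

# Surface voxels: mask voxels with at least one 6-connected background
# neighbor (voxels on the grid border count as surface).
surface_voxels <- function(mask) {
  mask <- mask != 0
  d <- dim(mask)
  interior <- array(TRUE, dim = d)
  shift_and <- function(m, ax, dir) {
    out <- array(FALSE, dim = d)
    idx_src <- idx_dst <- lapply(d, seq_len)
    n <- d[ax]
    if (n == 1) return(out)
    if (dir > 0) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) for (dir in c(-1, 1))
    interior <- interior & shift_and(mask, ax, dir)
  which(mask & !interior, arr.ind = TRUE)
}

as3d <- function(x) {
  if (length(dim(x)) == 2) array(x, dim = c(dim(x), 1)) else x
}

# For each row of `a` (n x 3 mm coords), the distance to the nearest row
# of `b`, computed in chunks to bound memory.
min_dists <- function(a, b, chunk = 2000L) {
  n <- nrow(a)
  out <- numeric(n)
  bb <- rowSums(b^2)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    am <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(am^2), bb, `+`) - 2 * am %*% t(b)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' 95th percentile of the pooled symmetric surface-to-surface distances
#' between two masks, with voxel coordinates scaled by `spacing_mm`.
#' Surfaces are mask voxels with a 6-connected background neighbor.
#'
#' @inheritParams confusion_counts
#' @param spacing_mm voxel spacing triple (mm).
#' @param q percentile in `[0, 1]`; 1 gives the exact Hausdorff distance.
#' @return distance in mm, or `NA` (with a warning) if either mask is
#'   empty.
#' @export
hd95 <- function(U, V, spacing_mm = c(1, 1, 1), q = 0.95) {
  U <- as3d(U); V <- as3d(V)
  if (!all(dim(U) == dim(V))) stop("shape mismatch")
  su <- surface_voxels(U)
  sv <- surface_voxels(V)
  if (nrow(su) == 0 || nrow(sv) == 0) {
    warning("empty mask: Hausdorff distance undefined")
    return(NA_real_)
  }
  sp <- spacing_mm[seq_len(3)]
  a <- sweep(su - 1, 2, sp, `*`)
  b <- sweep(sv - 1, 2, sp, `*`)
  d <- c(min_dists(a, b), min_dists(b, a))
  stats::quantile(d, q, names = FALSE, type = 7)
}

#' Per-class scores for one case
#'
#' @param truth,pred [label_volume()] objects or integer arrays.
#' @param class_id foreground class value to score.
#' @param spacing_mm voxel spacing for the Hausdorff distance.
#' @return one-row data.frame: dice, recall, precision, hd95_mm plus the
#'   counts needed for pooled aggregation.
#' @export
score_case <- function(truth, pred, class_id = 2L, spacing_mm = c(1, 1, 1)) {
  tl <- if (inherits(truth, "label_volume")) truth$labels else truth
  pl <- if (inherits(pred, "label_volume")) pred$labels else pred
  U <- tl == class_id
  V <- pl == class_id
  cc <- confusion_counts(U, V)
  h <- if (sum(U) > 0 && sum(V) > 0) hd95(U, V, spacing_mm) else NA_real_
  data.frame(class_id = class_id, dice = dice(U, V), recall = recall(U, V),
             precision = precision(U, V), hd95_mm = h, tp = cc$tp,
             size_u = cc$tp + cc$fn, size_v = cc$tp + cc$fp)
}

#' Aggregate case-level scores
#'
#' Per-case summary: mean and SD of the case Dice values. Global summary:
#' Dice of voxel counts pooled over all cases before forming the ratio.
#'
#' @param case_scores list of [score_case()] rows (or a data.frame with
#'   columns `dice`, `tp`, `size_u`, `size_v`).
#' @return list with `dice_global`, `dice_per_case_mean`,
#'   `dice_per_case_sd`, `n_cases`.
#' @export
aggregate_scores <- function(case_scores) {
  df <- if (is.data.frame(case_scores)) case_scores
        else do.call(rbind, case_scores)
  if (nrow(df) < 1) stop("need at least one case")
  den <- sum(df$size_u) + sum(df$size_v)
  list(dice_global = if (den == 0) 1 else 2 * sum(df$tp) / den,
       dice_per_case_mean = mean(df$dice),
       dice_per_case_sd = if (nrow(df) > 1) stats::sd(df$dice) else 0,
       n_cases = nrow(df))
}
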