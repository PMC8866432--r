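# Volume containers, NIfTI round-trips, intensity preprocessing, cropping.

#' CT volume container
#'
#' A 3D scalar intensity grid with voxel spacing (mm), a 4x4 affine and a
#' flag recording whether the clip/normalize preprocessing has been applied.
#' Voxel indexing is 0-based with axis order (x, y, z) throughout the
#' package; bounding boxes are half-open `[origin, origin + size)`.
#'
#' @param voxels numeric 3D array.
#' @param spacing_mm positive length-3 voxel spacing in mm.
#' @param affine 4x4 orientation matrix; defaults to a scaled identity.
#' @param normalized logical; TRUE once [preprocess()] has mapped the
#'   volume into `[0, 1]`.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing_mm = c(1, 1, 1), affine = NULL,
                      normalized = FALSE) {
  if (length(dim(voxels)) != 3) stop("voxels must be a 3D array")
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 strictly positive values")
  if (is.null(affine)) affine <- diag(c(spacing_mm, 1))
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 affine = affine, normalized = isTRUE(normalized)),
            class = "ct_volume")
}

#' Label volume container
#'
#' Integer class grid aligned to a [ct_volume()]. Classes are `0..C-1` in
#' the order of `class_names` (background first).
#'
#' @param labels integer 3D array.
#' @param class_names ordered class names, background first.
#' @inheritParams ct_volume
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(labels,
                         class_names = c("background", "pancreas", "tumor"),
                         spacing_mm = c(1, 1, 1), affine = NULL) {
  if (length(dim(labels)) != 3) stop("labels must be a 3D array")
  if (any(labels != round(labels)))
    stop("format error: non-integer label values")
  lab <- array(as.integer(round(labels)), dim = dim(labels))
  if (any(lab < 0) || any(lab > length(class_names) - 1))
    stop("labels out of range for the declared class set")
  if (is.null(affine)) affine <- diag(c(spacing_mm, 1))
  structure(list(labels = lab, class_names = class_names,
                 spacing_mm = as.numeric(spacing_mm), affine = affine),
            class = "label_volume")
}

#' Bounding box in voxel coordinates
#'
#' 0-based origin, half-open extent.
#' @param origin integer length-3, `>= 0`.
#' @param size integer length-3, strictly positive.
#' @return an object of class `bounding_box`.
#' @export
bounding_box <- function(origin, size) {
  origin <- as.integer(round(origin)); size <- as.integer(round(size))
  if (length(origin) != 3 || any(origin < 0)) stop("origin must be >= 0")
  if (length(size) != 3 || any(size < 1)) stop("size must be >= 1")
  structure(list(origin = origin, size = size), class = "bounding_box")
}

check_box <- function(box, shape) {
  if (any(box$origin + box$size > shape))
    stop("bounds error: box exceeds volume shape")
  invisible(TRUE)
}

#' Read a CT volume from NIfTI
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return a [ct_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  img <- RNifti::readNifti(path)
  sp <- attr(img, "pixdim")[1:3]
  aff <- unclass(RNifti::xform(img))
  ct_volume(array(as.numeric(img), dim = dim(img)), spacing_mm = abs(sp),
            affine = aff)
}

#' Read a label volume from NIfTI
#'
#' Values must be integral; anything else is a format error.
#' @inheritParams read_volume
#' @param class_names ordered class names, background first.
#' @return a [label_volume()].
#' @export
read_labels <- function(path,
                        class_names = c("background", "pancreas", "tumor")) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  img <- RNifti::readNifti(path)
  v <- as.numeric(img)
  if (any(abs(v - round(v)) > 1e-6))
    stop("format error: label file contains non-integer values")
  sp <- attr(img, "pixdim")[1:3]
  label_volume(array(round(v), dim = dim(img)), class_names = class_names,
               spacing_mm = abs(sp), affine = unclass(RNifti::xform(img)))
}

#' Write a volume (image or labels) to NIfTI
#'
#' @param v a [ct_volume()] or [label_volume()].
#' @param path output path (`.nii.gz` recommended).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  arr <- if (inherits(v, "label_volume")) v$labels else v$voxels
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- v$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Percentile clipping and min-max normalization
#'
#' Clips intensities to the `[lo_pct, hi_pct]` percentiles computed over all
#' voxels of the volume, then maps the clipped range affinely onto `[0, 1]`.
#' A constant volume (degenerate percentile range) is returned as all zeros
#' with a warning.
#'
#' @param v a [ct_volume()], not yet normalized.
#' @param lo_pct,hi_pct percentiles in `[0, 100]`, `lo_pct < hi_pct`.
#' @return a normalized [ct_volume()] with values in `[0, 1]`.
#' @export
preprocess <- function(v, lo_pct = 0.5, hi_pct = 99.5) {
  stopifnot(inherits(v, "ct_volume"))
  if (v$normalized) stop("volume is already normalized")
  if (lo_pct < 0 || hi_pct > 100 || lo_pct >= hi_pct)
    stop("require 0 <= lo_pct < hi_pct <= 100")
  q <- stats::quantile(v$voxels, c(lo_pct, hi_pct) / 100, names = FALSE,
                       type = 7)
  if (q[1] == q[2]) {
    warning("constant volume: returning all zeros")
    out <- array(0, dim = dim(v$voxels))
  } else {
    out <- (pmin(pmax(v$voxels, q[1]), q[2]) - q[1]) / (q[2] - q[1])
  }
  ct_volume(out, v$spacing_mm, v$affine, normalized = TRUE)
}

#' Crop a volume to a bounding box
#'
#' @param v a [ct_volume()] or [label_volume()].
#' @param box a [bounding_box()] within bounds.
#' @return object of the same class covering exactly `box`.
#' @export
crop <- function(v, box) {
  arr <- if (inherits(v, "label_volume")) v$labels else v$voxels
  check_box(box, dim(arr))
  o <- box$origin; s <- box$size
  sub <- arr[o[1] + seq_len(s[1]), o[2] + seq_len(s[2]),
             o[3] + seq_len(s[3]), drop = FALSE]
  if (inherits(v, "label_volume"))
    label_volume(sub, v$class_names, v$spacing_mm, v$affine)
  else ct_volume(sub, v$spacing_mm, v$affine, normalized = v$normalized)
}

#' Paste a cropped sub-volume back into full-volume coordinates
#'
#' Inverse of [crop()]: values are written at their original coordinates,
#' the rest of the grid is `fill`.
#'
#' @param sub cropped [ct_volume()] / [label_volume()] or bare array.
#' @param box the [bounding_box()] the crop came from.
#' @param full_shape shape of the full grid.
#' @param fill value outside the box.
#' @return array of shape `full_shape`.
#' @export
paste_volume <- function(sub, box, full_shape, fill = 0) {
  arr <- if (inherits(sub, "label_volume")) sub$labels
         else if (inherits(sub, "ct_volume")) sub$voxels else sub
  if (!all(dim(arr) == box$size)) stop("sub-volume does not match box size")
  check_box(box, full_shape)
  full <- array(fill, dim = full_shape)
  o <- box$origin; s <- box$size
  full[o[1] + seq_len(s[1]), o[2] + seq_len(s[2]), o[3] + seq_len(s[3])] <- arr
  full
}
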