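#' CT volume container
#'
#' A `ct_volume` holds a dense 3D grid of CT attenuation values in Hounsfield
#' units (HU) together with its per-axis voxel spacing and optional
#' contrast-phase / timepoint tags. The axis order is fixed as (z, y, x):
#' the first array axis is the slice axis, matching the acquisition geometry
#' of abdominal CT where the through-plane direction is the anisotropic one.
#'
#' @param voxels 3D numeric array of HU values, axis order (z, y, x).
#' @param spacing Numeric length-3 vector of voxel edge lengths in mm,
#'   ordered (z, y, x). All components must be positive.
#' @param phase Contrast phase: `"arterial"`, `"portal_venous"` or
#'   `"unknown"`.
#' @param timepoint Acquisition timepoint relative to ablation therapy:
#'   `"pre"`, `"post"` or `"unknown"`.
#' @return An object of class `ct_volume`.
#' @examples
#' vol <- ct_volume(array(0, c(4, 8, 8)))
#' dim(vol$voxels)
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1),
                      phase = c("unknown", "arterial", "portal_venous"),
                      timepoint = c("unknown", "pre", "post")) {
  phase <- match.arg(phase)
  timepoint <- match.arg(timepoint)
  check_grid(voxels, spacing, finite = TRUE)
  structure(
    list(voxels = voxels, spacing = as.numeric(spacing),
         phase = phase, timepoint = timepoint),
    class = "ct_volume"
  )
}

#' Binary segmentation mask
#'
#' A `binary_mask` is a 3D grid over \{0, 1\} aligned with a companion
#' [ct_volume()]: same shape, same (z, y, x) spacing. The `label` records
#' which structure the mask delineates.
#'
#' @param voxels 3D array containing only 0 and 1.
#' @param spacing Per-axis voxel spacing in mm, ordered (z, y, x).
#' @param label One of `"liver"`, `"tumor"`, `"ablation"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing = c(1, 1, 1),
                        label = c("liver", "tumor", "ablation")) {
  label <- match.arg(label)
  check_grid(voxels, spacing, finite = TRUE)
  if (!all(voxels == 0 | voxels == 1))
    stop_raunet("mask voxels must be exactly 0 or 1", "raunet_invalid_mask")
  storage.mode(voxels) <- "double"
  structure(
    list(voxels = voxels, spacing = as.numeric(spacing), label = label),
    class = "binary_mask"
  )
}

check_grid <- function(voxels, spacing, finite = TRUE) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop_raunet("voxels must be a 3D array (z, y, x)", "raunet_invalid_grid")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_raunet("spacing must be 3 positive finite values (z, y, x) in mm",
                "raunet_invalid_grid")
  if (finite && anyNA(voxels))
    stop_raunet("voxel values must be finite", "raunet_nonfinite")
  if (finite && !all(is.finite(voxels)))
    stop_raunet("voxel values must be finite", "raunet_nonfinite")
  invisible(TRUE)
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, phase=%s, timepoint=%s\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              x$phase, x$timepoint))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, spacing %s mm, label=%s, |mask|=%d\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              x$label, as.integer(sum(x$voxels))))
  invisible(x)
}

#' Clip Hounsfield units to the abdominal soft-tissue window
#'
#' CT attenuation outside the liver window carries no information for liver
#' or lesion segmentation (bone, air, contrast pooling); values are clipped
#' to `[lo, hi]` before resampling and normalization. Bounds are inclusive
#' and the operation is idempotent.
#'
#' @param vol A [ct_volume()].
#' @param lo,hi Clip window in HU (defaults -100 and 200).
#' @return A [ct_volume()] with all voxels in `[lo, hi]`.
#' @export
clip_hu <- function(vol, lo = -100, hi = 200) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!(lo < hi))
    stop_raunet("clip window requires lo < hi", "raunet_invalid_window")
  if (!all(is.finite(vol$voxels)))
    stop_raunet("voxel values must be finite", "raunet_nonfinite")
  vol$voxels[] <- pmin(pmax(vol$voxels, lo), hi)
  vol
}

#' Normalize clipped HU values to the unit interval
#'
#' Affine map of the clip window onto the unit interval (`lo` -> 0,
#' `hi` -> 1), the input scaling used for network training. The volume must
#' already be clipped; out-of-window values are rejected rather than
#' silently squashed.
#'
#' @inheritParams clip_hu
#' @return A [ct_volume()]-shaped object with voxels in `[0, 1]`.
#' @export
normalize_intensity <- function(vol, lo = -100, hi = 200) {
  stopifnot(inherits(vol, "ct_volume"))
  rng <- range(vol$voxels)
  if (rng[1] < lo || rng[2] > hi)
    stop_raunet(
      "voxels outside the [lo, hi] window; apply clip_hu() before normalizing",
      "raunet_not_clipped")
  vol$voxels[] <- (vol$voxels - lo) / (hi - lo)
  vol
}

#' Resample a volume or mask to isotropic voxels
#'
#' Resamples the grid to `target_spacing` mm per axis. Volumes use trilinear
#' interpolation; masks must use nearest-neighbour so the output stays
#' binary. The output extent per axis is `round(shape * spacing / target)`
#' with ties rounded up.
#'
#' @param grid A [ct_volume()] or [binary_mask()].
#' @param target_spacing Target isotropic voxel size in mm (default 1.0).
#' @param interp `"linear"` or `"nearest"`. Defaults to `"linear"` for
#'   volumes and `"nearest"` for masks.
#' @return A resampled object of the same class with spacing
#'   `(target, target, target)`.
#' @export
resample_isotropic <- function(grid, target_spacing = 1.0, interp = NULL) {
  is_mask <- inherits(grid, "binary_mask")
  if (!is_mask && !inherits(grid, "ct_volume"))
    stop_raunet("grid must be a ct_volume or binary_mask",
                "raunet_invalid_grid")
  if (target_spacing <= 0)
    stop_raunet("target_spacing must be > 0", "raunet_invalid_spacing")
  interp <- interp %||% if (is_mask) "nearest" else "linear"
  interp <- match.arg(interp, c("linear", "nearest"))
  if (is_mask && interp == "linear")
    stop_raunet("masks must be resampled with nearest interpolation",
                "raunet_mask_interp")

  x <- grid$voxels
  sp <- grid$spacing
  if (all(abs(sp - target_spacing) < 1e-9)) {
    grid$spacing <- rep(target_spacing, 3)
    return(grid)
  }
  out_shape <- pmax(1L, as.integer(floor(dim(x) * sp / target_spacing + 0.5)))
  # voxel-centre aligned source coordinates (0-based), clamped to the grid
  src <- lapply(1:3, function(a) {
    s <- (seq_len(out_shape[a]) - 1) * target_spacing / sp[a]
    pmin(pmax(s, 0), dim(x)[a] - 1)
  })
  if (interp == "nearest") {
    idx <- lapply(src, function(s) as.integer(floor(s + 0.5)) + 1L)
    out <- x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    out <- trilinear_gather(x, src, out_shape)
  }
  dim(out) <- out_shape
  grid$voxels <- out
  grid$spacing <- rep(target_spacing, 3)
  grid
}

trilinear_gather <- function(x, src, out_shape) {
  n <- dim(x)
  f0 <- lapply(1:3, function(a) pmin(floor(src[[a]]), n[a] - 1))
  fr <- lapply(1:3, function(a) src[[a]] - f0[[a]])
  i0 <- lapply(f0, function(v) as.integer(v) + 1L)
  i1 <- lapply(1:3, function(a) pmin(i0[[a]] + 1L, n[a]))

  P <- prod(out_shape)
  gz <- rep.int(seq_len(out_shape[1]), times = out_shape[2] * out_shape[3])
  gy <- rep.int(rep(seq_len(out_shape[2]), each = out_shape[1]),
                times = out_shape[3])
  gx <- rep(seq_len(out_shape[3]), each = out_shape[1] * out_shape[2])

  wz <- fr[[1]][gz]; wy <- fr[[2]][gy]; wx <- fr[[3]][gx]
  out <- numeric(P)
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    iz <- (if (cz == 0) i0[[1]] else i1[[1]])[gz]
    iy <- (if (cy == 0) i0[[2]] else i1[[2]])[gy]
    ix <- (if (cx == 0) i0[[3]] else i1[[3]])[gx]
    w <- (if (cz == 0) 1 - wz else wz) *
         (if (cy == 0) 1 - wy else wy) *
         (if (cx == 0) 1 - wx else wx)
    out <- out + w * x[cbind(iz, iy, ix)]
  }
  out
}

#' Read and write volumes and masks as NIfTI
#'
#' Volumes and masks are exchanged as NIfTI-1 images (`.nii` / `.nii.gz`).
#' On disk NIfTI stores the in-plane axes fastest; the reader permutes to
#' the package's (z, y, x) axis order and reads the voxel spacing from the
#' header `pixdim`. Masks are written as unsigned 8-bit.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param vol,mask Object to write.
#' @param phase,timepoint Tags attached to the volume on read (NIfTI has no
#'   standard slot for contrast phase).
#' @param label Mask label attached on read.
#' @return `read_volume()` a [ct_volume()]; `read_mask()` a [binary_mask()];
#'   the writers return the path invisibly.
#' @name volume_nifti
NULL

read_nifti_array <- function(path) {
  if (!file.exists(path))
    stop_raunet(sprintf("file not found: %s", path), "raunet_io_missing")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop_raunet(sprintf("not a readable NIfTI file: %s (%s)",
                                        path, conditionMessage(e)),
                                "raunet_io_malformed"))
  if (length(dim(img)) != 3L)
    stop_raunet(sprintf("expected a 3D image, got %dD: %s",
                        length(dim(img)), path), "raunet_io_ndim")
  sp_xyz <- RNifti::pixdim(img)
  arr <- array(as.numeric(img), dim = dim(img))
  list(voxels = aperm(arr, c(3, 2, 1)), spacing = rev(sp_xyz[1:3]))
}

#' @rdname volume_nifti
#' @export
read_volume <- function(path, phase = "unknown", timepoint = "unknown") {
  g <- read_nifti_array(path)
  ct_volume(g$voxels, g$spacing, phase = phase, timepoint = timepoint)
}

#' @rdname volume_nifti
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  write_nifti_array(vol$voxels, vol$spacing, path, datatype = "float")
  invisible(path)
}

#' @rdname volume_nifti
#' @export
read_mask <- function(path, label = "liver") {
  g <- read_nifti_array(path)
  v <- g$voxels
  v[] <- as.numeric(v > 0.5)
  binary_mask(v, g$spacing, label = label)
}

#' @rdname volume_nifti
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  write_nifti_array(mask$voxels, mask$spacing, path, datatype = "uint8")
  invisible(path)
}

write_nifti_array <- function(voxels, spacing, path, datatype) {
  arr <- aperm(voxels, c(3, 2, 1)) # back to x-fastest file order
  RNifti::pixdim(arr) <- rev(spacing)
  RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = datatype)
}
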