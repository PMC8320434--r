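# Cascaded inference: slice-wise liver segmentation restricts the search
# volume to a bounding box around the liver, inside which two 3D patch
# scales are tiled with overlap, predicted, stitched and merged.

#' Bounding box
#'
#' Axis-aligned box with 0-based per-axis voxel offsets and extents, in the
#' (z, y, x) axis order.
#'
#' @param start Integer length-3 vector of 0-based offsets.
#' @param size Integer length-3 vector of extents.
#' @return An object of class `bounding_box`.
#' @export
bounding_box <- function(start, size) {
  start <- as.integer(start); size <- as.integer(size)
  if (length(start) != 3 || length(size) != 3 || any(start < 0) ||
      any(size < 1))
    stop_raunet("bounding_box needs 3 nonnegative starts and positive sizes",
                "raunet_invalid_params")
  structure(list(start = start, size = size), class = "bounding_box")
}

#' Patch tiling specification
#'
#' @param patch_size Per-axis patch extents (z, y, x); the two scales used
#'   by the lesion models are 20x30x30 and 40x60x60.
#' @param overlap_fraction Fractional per-axis overlap between neighbouring
#'   patches (default 0.10). The voxel overlap is
#'   `round(overlap_fraction * patch_size)` per axis.
#' @return An object of class `patch_spec`.
#' @export
patch_spec <- function(patch_size, overlap_fraction = 0.10) {
  patch_size <- as.integer(patch_size)
  if (length(patch_size) != 3 || any(patch_size < 1))
    stop_raunet("patch_size must be 3 positive extents", "raunet_invalid_params")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop_raunet("overlap_fraction must lie in [0, 1)", "raunet_invalid_params")
  structure(list(patch_size = patch_size,
                 overlap_fraction = overlap_fraction),
            class = "patch_spec")
}

#' Slice-wise liver segmentation
#'
#' Runs the 2D model over every axial slice of a preprocessed volume
#' independently and stacks the thresholded outputs into a 3D liver mask
#' aligned with the input. Slices are zero-padded to the model's
#' downsampling multiple and predictions cropped back.
#'
#' @param vol A preprocessed (clipped, resampled, normalized) [ct_volume()].
#' @param liver_model A 2D `ra_unet_model`.
#' @param threshold Probability threshold for the binary mask.
#' @param chunk Number of slices run per forward pass (memory/speed
#'   trade-off).
#' @return A [binary_mask()] with `label = "liver"`.
#' @export
segment_liver <- function(vol, liver_model, threshold = 0.5, chunk = 8L) {
  stopifnot(inherits(vol, "ct_volume"),
            inherits(liver_model, "ra_unet_model"))
  if (liver_model$spec$dimensionality != 2)
    stop_raunet("segment_liver needs a 2D model", "raunet_spec_mismatch")
  d <- dim(vol$voxels)
  mult <- 2L^liver_model$spec$levels
  target <- as.integer(ceiling(d[2:3] / mult) * mult)
  out <- array(0, d)
  for (zs in split(seq_len(d[1]), ceiling(seq_len(d[1]) / chunk))) {
    batch <- array(0, c(1L, target, 1L, length(zs)))
    for (k in seq_along(zs))
      batch[1, seq_len(d[2]), seq_len(d[3]), 1, k] <- vol$voxels[zs[k], , ]
    pr <- forward_graph(liver_model, batch, training = FALSE)$out
    out[zs, , ] <- aperm(array(pr[1, seq_len(d[2]), seq_len(d[3]), 1, ],
                               c(d[2], d[3], length(zs))), c(3, 1, 2))
  }
  binary_mask(array(as.numeric(out >= threshold), d), vol$spacing,
              label = "liver")
}

#' Liver bounding box
#'
#' Box of the requested size centred on the liver-mask centroid and clamped
#' to the volume bounds. If the mask's tight extent exceeds the requested
#' size on an axis, the box is enlarged on that axis to the tight extent
#' plus a 5-voxel margin on each side (then clamped to the volume).
#'
#' @param liver_mask A nonempty [binary_mask()].
#' @param size Requested box extents (z, y, x); default 200x300x300.
#' @param margin Extra margin (voxels per side) applied when the tight
#'   extent exceeds the requested size.
#' @return A [bounding_box()].
#' @export
liver_bbox <- function(liver_mask, size = c(200, 300, 300), margin = 5L) {
  stopifnot(inherits(liver_mask, "binary_mask"))
  idx <- which(liver_mask$voxels == 1)
  if (length(idx) == 0)
    stop_raunet("liver mask is empty; no liver found", "raunet_empty_mask")
  shp <- dim(liver_mask$voxels)
  sub <- arrayInd(idx, shp)
  centroid <- colMeans(sub)
  tight <- apply(sub, 2, function(v) diff(range(v)) + 1L)
  size <- pmin(as.integer(pmax(size, ifelse(tight > size,
                                            tight + 2L * margin, size))),
               shp)
  # centroid is 1-based; voxel i spans [i-1, i) in continuous 0-based coords
  start <- as.integer(round(centroid - 0.5 - size / 2))
  start <- pmax(0L, pmin(start, shp - size))
  bounding_box(start, size)
}

#' Tile a bounding box with overlapping patches
#'
#' Per axis the stride is `patch - round(overlap * patch)`; starts run
#' 0, stride, 2*stride, ... and the final start is clamped to
#' `box - patch` so the far edge is always covered. Every voxel of the box
#' is covered by at least one patch.
#'
#' @param box A [bounding_box()].
#' @param spec A [patch_spec()].
#' @return An object of class `patch_grid`: list with `box`, `spec` and
#'   `starts` (n x 3 integer matrix of 0-based offsets relative to the
#'   box, z-major order).
#' @export
tile_patches <- function(box, spec) {
  stopifnot(inherits(box, "bounding_box"), inherits(spec, "patch_spec"))
  p <- spec$patch_size
  if (any(p > box$size))
    stop_raunet("patch larger than bounding box", "raunet_invalid_params")
  axis_starts <- lapply(1:3, function(a) {
    stride <- p[a] - as.integer(round(spec$overlap_fraction * p[a]))
    stride <- max(1L, stride)
    s <- seq.int(0L, box$size[a] - p[a], by = stride)
    if (s[length(s)] < box$size[a] - p[a])
      s <- c(s, box$size[a] - p[a])
    as.integer(s)
  })
  g <- expand.grid(x = axis_starts[[3]], y = axis_starts[[2]],
                   z = axis_starts[[1]])
  starts <- as.matrix(g[, c("z", "y", "x")])
  dimnames(starts) <- NULL
  structure(list(box = box, spec = spec, starts = starts),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %d patches of %s in a %s box\n",
              nrow(x$starts), paste(x$spec$patch_size, collapse = "x"),
              paste(x$box$size, collapse = "x")))
  invisible(x)
}

# extract one patch (start 0-based, relative to the full array)
extract_patch <- function(arr, start, size) {
  arr[start[1] + seq_len(size[1]), start[2] + seq_len(size[2]),
      start[3] + seq_len(size[3]), drop = FALSE]
}

#' Stitch patch masks back into a box-sized mask
#'
#' Overlapping predictions are merged by union: a voxel is foreground iff
#' any covering patch marks it as foreground.
#'
#' @param grid A `patch_grid` from [tile_patches()].
#' @param patch_masks List of 0/1 arrays (or [binary_mask()]), one per grid
#'   start, each of the grid's patch size.
#' @return A 0/1 array of the box size.
#' @export
stitch <- function(grid, patch_masks) {
  stopifnot(inherits(grid, "patch_grid"))
  n <- nrow(grid$starts)
  if (length(patch_masks) != n)
    stop_raunet(sprintf("expected %d patch masks, got %d", n,
                        length(patch_masks)), "raunet_shape_mismatch")
  p <- grid$spec$patch_size
  out <- array(0, grid$box$size)
  for (i in seq_len(n)) {
    m <- patch_masks[[i]]
    if (inherits(m, "binary_mask")) m <- m$voxels
    if (!identical(as.integer(dim(m)), p))
      stop_raunet(sprintf("patch %d has shape %s, expected %s", i,
                          paste(dim(m), collapse = "x"),
                          paste(p, collapse = "x")), "raunet_shape_mismatch")
    s <- grid$starts[i, ]
    iz <- s[1] + seq_len(p[1]); iy <- s[2] + seq_len(p[2])
    ix <- s[3] + seq_len(p[3])
    out[iz, iy, ix] <- pmax(out[iz, iy, ix], m)
  }
  out
}

#' Merge predictions from the two patch scales
#'
#' The multi-scale ensemble keeps every voxel segmented at either scale
#' (voxel-wise union); commutative, associative and idempotent.
#'
#' @param mask_a,mask_b [binary_mask()] objects or 0/1 arrays of equal
#'   shape.
#' @return Same kind as `mask_a`.
#' @export
merge_scales <- function(mask_a, mask_b) {
  a <- if (inherits(mask_a, "binary_mask")) mask_a$voxels else mask_a
  b <- if (inherits(mask_b, "binary_mask")) mask_b$voxels else mask_b
  if (!identical(dim(a), dim(b)))
    stop_raunet("merge_scales: shape mismatch", "raunet_shape_mismatch")
  m <- pmax(a, b)
  if (inherits(mask_a, "binary_mask")) {
    mask_a$voxels <- m
    mask_a
  } else m
}

#' Sample class-balanced training patches
#'
#' Draws `n_per_class` foreground patches (centred on a voxel drawn
#' uniformly from the lesion mask) and `n_per_class` background patches
#' (centred on a voxel drawn uniformly from liver-minus-lesion), with patch
#' windows clamped to the volume bounds. With `n_per_class = 36` this
#' yields the 72-patch balanced batches of the full-scale protocol.
#'
#' @param vol Preprocessed [ct_volume()].
#' @param lesion_mask,liver_mask Aligned [binary_mask()] objects.
#' @param spec A [patch_spec()] (only `patch_size` is used).
#' @param n_per_class Patches per class.
#' @param seed Integer seed; identical seeds give identical patch lists.
#' @return List of `list(input, target, class)` pairs, foreground first.
#' @export
sample_training_patches <- function(vol, lesion_mask, liver_mask, spec,
                                    n_per_class, seed) {
  stopifnot(inherits(vol, "ct_volume"), inherits(spec, "patch_spec"))
  d <- dim(vol$voxels)
  if (!identical(d, dim(lesion_mask$voxels)) ||
      !identical(d, dim(liver_mask$voxels)))
    stop_raunet("masks must be aligned with the volume",
                "raunet_shape_mismatch")
  if (any(spec$patch_size > d))
    stop_raunet("patch size exceeds the volume", "raunet_invalid_params")
  fg_pool <- which(lesion_mask$voxels == 1)
  bg_pool <- which(liver_mask$voxels == 1 & lesion_mask$voxels == 0)
  if (n_per_class > 0 && length(fg_pool) == 0)
    stop_raunet("no lesion voxels to sample foreground patches from",
                "raunet_empty_mask")
  if (n_per_class > 0 && length(bg_pool) == 0)
    stop_raunet("no liver background voxels to sample from",
                "raunet_empty_mask")
  set.seed(seed)
  draw <- function(pool, n) pool[sample.int(length(pool), n, replace = TRUE)]
  centers <- c(draw(fg_pool, n_per_class), draw(bg_pool, n_per_class))
  cls <- rep(c("foreground", "background"), each = n_per_class)
  p <- spec$patch_size
  lapply(seq_along(centers), function(i) {
    ctr <- arrayInd(centers[i], d)[1, ]
    start <- pmax(0L, pmin(as.integer(ctr - 1L - (p %/% 2L)),
                           as.integer(d - p)))
    list(input = extract_patch(vol$voxels, start, p),
         target = extract_patch(lesion_mask$voxels, start, p),
         class = cls[i])
  })
}

#' Pipeline configuration
#'
#' Bundles the preprocessing and cascade settings with the full-scale
#' defaults: clip window -100..200 HU, 1 mm isotropic resampling, a
#' 200x300x300 liver bounding box, patch scales 20x30x30 and 40x60x60 at
#' 10% overlap, probability threshold 0.5, union merging and a 2-voxel
#' liver dilation for the final lesion gating.
#'
#' @param clip Clip window `c(lo, hi)` in HU.
#' @param target_spacing Isotropic resampling target in mm.
#' @param box_size Liver bounding-box extents.
#' @param patch_sizes List of per-scale patch extents.
#' @param overlap_fraction Tiling overlap.
#' @param threshold Probability threshold.
#' @param merge `"union"` (binary union of scales and overlaps) or
#'   `"mean"` (average probabilities, then threshold).
#' @param liver_dilation Voxel radius by which the liver mask is dilated
#'   before gating the lesion prediction.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(clip = c(-100, 200), target_spacing = 1.0,
                            box_size = c(200, 300, 300),
                            patch_sizes = list(c(20, 30, 30), c(40, 60, 60)),
                            overlap_fraction = 0.10, threshold = 0.5,
                            merge = c("union", "mean"), liver_dilation = 2L) {
  merge <- match.arg(merge)
  structure(
    list(clip = clip, target_spacing = target_spacing,
         box_size = as.integer(box_size),
         patch_sizes = lapply(patch_sizes, as.integer),
         overlap_fraction = overlap_fraction, threshold = threshold,
         merge = merge, liver_dilation = as.integer(liver_dilation)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# probability patches for one scale over a patch grid
predict_scale <- function(vol_box, grid, model) {
  p <- grid$spec$patch_size
  mult <- 2L^model$spec$levels
  lapply(seq_len(nrow(grid$starts)), function(i) {
    patch <- extract_patch(vol_box, grid$starts[i, ], p)
    pad <- pad_to_multiple(patch, mult)
    pm <- predict(model, pad$padded)
    crop_to(pm$voxels, p)
  })
}

#' Run the full segmentation cascade on one raw volume
#'
#' Executes the complete two-stage inference: clip to the HU window,
#' resample to isotropic spacing, normalize, segment the liver slice-wise
#' with the 2D model, place the liver bounding box, tile each patch scale
#' with overlap inside the box, predict and stitch each scale, merge the
#' scales, and gate the lesion mask by the dilated liver mask before
#' embedding it back into the full resampled grid.
#'
#' @param vol A raw (unpreprocessed) [ct_volume()].
#' @param liver_model Trained 2D `ra_unet_model`.
#' @param lesion_models List of trained 3D models, one per patch scale (in
#'   the order of `config$patch_sizes`).
#' @param config A [pipeline_config()].
#' @param lesion_label Label for the returned lesion mask (`"tumor"` or
#'   `"ablation"`).
#' @return List with `liver` and `lesion` [binary_mask()] on the resampled
#'   grid, plus the [bounding_box()] used.
#' @export
run_pipeline <- function(vol, liver_model, lesion_models,
                         config = pipeline_config(),
                         lesion_label = "tumor") {
  stopifnot(inherits(vol, "ct_volume"), inherits(config, "pipeline_config"))
  if (length(lesion_models) != length(config$patch_sizes))
    stop_raunet("need one lesion model per patch scale",
                "raunet_invalid_params")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_raunet(sprintf("[%s] %s", name, conditionMessage(e)),
                  "raunet_pipeline_stage")
    })
  }
  v <- stage("preprocess", {
    v <- clip_hu(vol, config$clip[1], config$clip[2])
    v <- resample_isotropic(v, config$target_spacing)
    normalize_intensity(v, config$clip[1], config$clip[2])
  })
  liver <- stage("liver_segmentation",
                 segment_liver(v, liver_model, config$threshold))
  box <- stage("bounding_box", liver_bbox(liver, config$box_size))
  vol_box <- extract_patch(v$voxels, box$start, box$size)

  lesion_box <- stage("lesion_segmentation", {
    if (config$merge == "union") {
      per_scale <- lapply(seq_along(config$patch_sizes), function(k) {
        grid <- tile_patches(box, patch_spec(config$patch_sizes[[k]],
                                             config$overlap_fraction))
        probs <- predict_scale(vol_box, grid, lesion_models[[k]])
        masks <- lapply(probs, function(pr)
          array(as.numeric(pr >= config$threshold), dim(pr)))
        stitch(grid, masks)
      })
      Reduce(merge_scales, per_scale)
    } else {
      # average overlapping probabilities across patches and scales
      acc <- array(0, box$size)
      cnt <- array(0, box$size)
      for (k in seq_along(config$patch_sizes)) {
        grid <- tile_patches(box, patch_spec(config$patch_sizes[[k]],
                                             config$overlap_fraction))
        probs <- predict_scale(vol_box, grid, lesion_models[[k]])
        p <- grid$spec$patch_size
        for (i in seq_len(nrow(grid$starts))) {
          s <- grid$starts[i, ]
          iz <- s[1] + seq_len(p[1]); iy <- s[2] + seq_len(p[2])
          ix <- s[3] + seq_len(p[3])
          acc[iz, iy, ix] <- acc[iz, iy, ix] + probs[[i]]
          cnt[iz, iy, ix] <- cnt[iz, iy, ix] + 1
        }
      }
      array(as.numeric(acc / pmax(cnt, 1) >= config$threshold), box$size)
    }
  })

  d <- dim(v$voxels)
  lesion_full <- array(0, d)
  lesion_full[box$start[1] + seq_len(box$size[1]),
              box$start[2] + seq_len(box$size[2]),
              box$start[3] + seq_len(box$size[3])] <- lesion_box
  liver_dil <- cpp_dilate_box(array(as.integer(liver$voxels), d), d,
                              config$liver_dilation)
  lesion_full <- lesion_full * as.numeric(liver_dil)

  list(liver = liver,
       lesion = binary_mask(array(as.numeric(lesion_full), d), v$spacing,
                            label = lesion_label),
       bbox = box)
}
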