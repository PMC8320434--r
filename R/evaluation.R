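#' Dice similarity coefficient
#'
#' Spatial overlap between a reference standard RS and a predicted
#' segmentation PS: `2 * |RS intersect PS| / (|RS| + |PS|)`. Defined as 1
#' when both masks are empty (two empty segmentations agree perfectly).
#' For binary masks `dsc == 1 - dice_loss` exactly (with smoothing
#' disabled).
#'
#' @param rs,ps [binary_mask()] objects or bare 0/1 arrays of equal shape.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(rs, ps) {
  a <- if (inherits(rs, "binary_mask")) rs$voxels else rs
  b <- if (inherits(ps, "binary_mask")) ps$voxels else ps
  if (!identical(dim(a), dim(b)))
    stop_raunet("dsc: shape mismatch", "raunet_shape_mismatch")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' Label connected lesion components
#'
#' Decomposes a binary mask into connected components ("lesions") under
#' 26-neighbourhood connectivity (voxels touching by face, edge or corner
#' belong together; 6-neighbourhood is available as an option). Component
#' volumes are voxel count times voxel volume, reported in cm^3.
#'
#' @param mask A [binary_mask()] (or 0/1 array; spacing then defaults to
#'   1 mm isotropic).
#' @param connectivity 26 (default) or 6.
#' @return An object of class `lesion_set`: list with `components` (data
#'   frame: `id`, `n_voxels`, `volume_cm3`), `labels` (integer array,
#'   0 = background) and `spacing`.
#' @export
label_lesions <- function(mask, connectivity = 26) {
  if (!connectivity %in% c(6, 26))
    stop_raunet("connectivity must be 6 or 26", "raunet_invalid_params")
  v <- if (inherits(mask, "binary_mask")) mask$voxels else mask
  spacing <- if (inherits(mask, "binary_mask")) mask$spacing else c(1, 1, 1)
  m <- array(as.integer(v != 0), dim(v))
  lab <- cpp_label_components(m, dim(m), as.integer(connectivity))
  n <- max(lab)
  comp <- if (n > 0) {
    counts <- tabulate(lab[lab > 0L], nbins = n)
    data.frame(id = seq_len(n), n_voxels = counts,
               volume_cm3 = counts * prod(spacing) / 1000)
  } else {
    data.frame(id = integer(0), n_voxels = integer(0),
               volume_cm3 = numeric(0))
  }
  structure(list(components = comp, labels = lab, spacing = spacing),
            class = "lesion_set")
}

#' @export
print.lesion_set <- function(x, ...) {
  cat(sprintf("<lesion_set> %d components, total %.2f cm^3\n",
              nrow(x$components), sum(x$components$volume_cm3)))
  invisible(x)
}

#' Filter lesions by minimum volume
#'
#' Keeps components with volume `>= min_volume` (inclusive bound). With the
#' default 0.5 cm^3 this is the sub-analysis threshold corresponding to
#' roughly spherical lesions above 1 cm diameter, below which CT detection
#' is unreliable in clinical practice.
#'
#' @param lesions A `lesion_set`.
#' @param min_volume Minimum component volume in cm^3.
#' @return A `lesion_set` containing only the retained components (labels
#'   of removed components are zeroed).
#' @export
filter_by_volume <- function(lesions, min_volume = 0.5) {
  stopifnot(inherits(lesions, "lesion_set"))
  keep <- lesions$components$volume_cm3 >= min_volume
  drop_ids <- lesions$components$id[!keep]
  if (length(drop_ids) > 0)
    lesions$labels[lesions$labels %in% drop_ids] <- 0L
  lesions$components <- lesions$components[keep, , drop = FALSE]
  lesions
}

#' Match predicted lesions to reference lesions
#'
#' A reference lesion counts as detected (TP) if at least one predicted
#' component overlaps it by at least `min_overlap` of the reference
#' volume (default: any shared voxel); undetected reference lesions are FN;
#' predicted components overlapping no reference lesion are FP.
#'
#' @param ref,pred `lesion_set` objects from same-shaped masks.
#' @param min_overlap Minimum fraction of the reference lesion that must be
#'   covered before it counts as detected (0 = any voxel).
#' @return List with counts `TP`, `FN`, `FP` and the per-reference-lesion
#'   detection indicator `detected`.
#' @export
match_lesions <- function(ref, pred, min_overlap = 0) {
  stopifnot(inherits(ref, "lesion_set"), inherits(pred, "lesion_set"))
  if (!identical(dim(ref$labels), dim(pred$labels)))
    stop_raunet("match_lesions: parent masks have different shapes",
                "raunet_shape_mismatch")
  nr <- nrow(ref$components)
  np <- nrow(pred$components)
  both <- ref$labels > 0L & pred$labels > 0L
  if (any(both)) {
    pairs <- unique(cbind(ref$labels[both], pred$labels[both]))
    ov <- tapply(rep(1L, sum(both)),
                 list(factor(ref$labels[both], levels = seq_len(nr)),
                      factor(pred$labels[both], levels = seq_len(np))),
                 sum, default = 0L)
    covered <- rowSums(ov)
    frac <- covered / pmax(ref$components$n_voxels, 1L)
    detected <- if (min_overlap == 0) covered > 0 else frac >= min_overlap
    pred_hit <- unique(pairs[, 2])
  } else {
    detected <- rep(FALSE, nr)
    pred_hit <- integer(0)
  }
  list(TP = sum(detected), FN = nr - sum(detected),
       FP = np - length(unique(pred_hit)), detected = as.logical(detected))
}

#' Lesion-level detection statistics
#'
#' Aggregates per-case TP/FN/FP counts into detection sensitivity
#' `TP / (TP + FN)`, precision `TP / (TP + FP)`, their harmonic mean F1,
#' and false positives per image `FP / n_images`. Degenerate cases follow
#' the conventions: sensitivity is `NA` when there are no reference
#' lesions; precision with no predictions is 1 when there are also no
#' reference lesions and `NA` otherwise; F1 is 0 when sensitivity and
#' precision are both 0.
#'
#' @param matches A single match result from [match_lesions()], a list of
#'   them (one per case), or explicit counts via `TP=`, `FN=`, `FP=`.
#' @param n_images Number of images over which FP/image is normalised.
#' @return An object of class `detection_report`.
#' @export
detection_stats <- function(matches, n_images) {
  if (n_images < 1)
    stop_raunet("n_images must be >= 1", "raunet_invalid_params")
  if (!is.null(matches$TP)) matches <- list(matches)
  tp <- sum(vapply(matches, `[[`, numeric(1), "TP"))
  fn <- sum(vapply(matches, `[[`, numeric(1), "FN"))
  fp <- sum(vapply(matches, `[[`, numeric(1), "FP"))
  sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  prec <- if (tp + fp == 0) {
    if (tp + fn == 0) 1 else NA_real_
  } else tp / (tp + fp)
  f1 <- f1_score(sens, prec)
  structure(
    list(TP = tp, FN = fn, FP = fp, sensitivity = sens, precision = prec,
         f1 = f1, fp_per_image = fp / n_images, n_images = n_images),
    class = "detection_report"
  )
}

#' @rdname detection_stats
#' @param sensitivity,precision Detection rates in `[0, 1]`.
#' @export
f1_score <- function(sensitivity, precision) {
  if (is.na(sensitivity) || is.na(precision)) return(NA_real_)
  if (sensitivity + precision == 0) return(0)
  2 * sensitivity * precision / (sensitivity + precision)
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf(
    "<detection_report> TP=%d FN=%d FP=%d | sens %.3f prec %.3f F1 %.3f | %.2f FP/image\n",
    x$TP, x$FN, x$FP, x$sensitivity, x$precision, x$f1, x$fp_per_image))
  invisible(x)
}

#' Volumetric agreement between reference and predicted lesion volumes
#'
#' Pearson correlation plus Bland-Altman statistics of predicted minus
#' reference volumes: bias (mean difference) and 95% limits of agreement
#' (bias +/- 1.96 SD of the differences).
#'
#' @param ref_volumes,pred_volumes Equal-length numeric vectors (cm^3),
#'   length >= 3, with nonzero variance.
#' @return An object of class `agreement_report` with `r`, `bias`,
#'   `loa_low`, `loa_high` and the difference vector.
#' @export
volume_agreement <- function(ref_volumes, pred_volumes) {
  if (length(ref_volumes) != length(pred_volumes))
    stop_raunet("volume lists must have equal length", "raunet_shape_mismatch")
  if (length(ref_volumes) < 3)
    stop_raunet("need at least 3 paired volumes", "raunet_invalid_params")
  if (sd(ref_volumes) == 0 || sd(pred_volumes) == 0)
    stop_raunet("volumes have zero variance; correlation undefined",
                "raunet_invalid_params")
  d <- pred_volumes - ref_volumes
  bias <- mean(d)
  s <- sd(d)
  structure(
    list(r = cor(ref_volumes, pred_volumes), bias = bias,
         loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
         differences = d, ref = ref_volumes, pred = pred_volumes),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> r=%.3f bias=%.2f cm^3, 95%% LoA [%.2f, %.2f]\n",
    x$r, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Bland-Altman and correlation plots
#'
#' @param agreement An `agreement_report`.
#' @param path Output image path (`.png` or `.svg`); `NULL` draws on the
#'   current device.
#' @param what `"bland_altman"` or `"correlation"`.
#' @return The path (or `NULL`), invisibly.
#' @export
plot_agreement <- function(agreement, path = NULL,
                           what = c("bland_altman", "correlation")) {
  stopifnot(inherits(agreement, "agreement_report"))
  what <- match.arg(what)
  if (!is.null(path)) {
    if (grepl("\\.svg$", path)) grDevices::svg(path, width = 5, height = 5)
    else grDevices::png(path, width = 600, height = 600)
    on.exit(grDevices::dev.off())
  }
  if (what == "bland_altman") {
    m <- (agreement$ref + agreement$pred) / 2
    graphics::plot(m, agreement$differences,
                   xlab = "mean volume (cm^3)",
                   ylab = "predicted - reference (cm^3)",
                   main = "Bland-Altman", pch = 19)
    graphics::abline(h = c(agreement$bias, agreement$loa_low,
                           agreement$loa_high),
                     lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
  } else {
    graphics::plot(agreement$ref, agreement$pred,
                   xlab = "reference volume (cm^3)",
                   ylab = "predicted volume (cm^3)",
                   main = sprintf("r = %.3f", agreement$r), pch = 19)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(path)
}
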