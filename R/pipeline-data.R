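# Helpers bridging phantom cases / on-disk cohorts and network training.

#' Preprocess a CT volume for the networks
#'
#' Applies the standard preprocessing chain: clip to the HU window,
#' resample to isotropic spacing, normalize to `[0, 1]`.
#'
#' @param vol A raw [ct_volume()].
#' @param config A [pipeline_config()].
#' @return A preprocessed [ct_volume()].
#' @export
preprocess_ct <- function(vol, config = pipeline_config()) {
  v <- clip_hu(vol, config$clip[1], config$clip[2])
  v <- resample_isotropic(v, config$target_spacing)
  normalize_intensity(v, config$clip[1], config$clip[2])
}

# a "case" is the list structure returned by generate_case() / load_case()

#' Load a phantom case written by [write_cohort()]
#'
#' @param case_dir Per-case directory containing the NIfTI files.
#' @return The same structure as [generate_case()] (without `lesions`).
#' @export
load_case <- function(case_dir) {
  if (!dir.exists(case_dir))
    stop_raunet(sprintf("case directory not found: %s", case_dir),
                "raunet_io_missing")
  vols <- list(
    pre_arterial = c("arterial", "pre"), pre_venous = c("portal_venous", "pre"),
    post_arterial = c("arterial", "post"),
    post_venous = c("portal_venous", "post"))
  volumes <- lapply(names(vols), function(nm) {
    read_volume(file.path(case_dir, paste0(nm, ".nii.gz")),
                phase = vols[[nm]][1], timepoint = vols[[nm]][2])
  })
  names(volumes) <- names(vols)
  masks <- lapply(c("liver", "tumor", "ablation"), function(nm)
    read_mask(file.path(case_dir, paste0("mask_", nm, ".nii.gz")), label = nm))
  names(masks) <- c("liver", "tumor", "ablation")
  list(volumes = volumes, masks = masks)
}

# pick the case volume for a task/phase combination
case_volume <- function(case, task, phase) {
  key <- paste0(if (task == "ablation") "post" else "pre",
                if (phase == "arterial") "_arterial" else "_venous")
  case$volumes[[key]]
}

#' Build slice samples for the 2D liver model
#'
#' Preprocesses each case volume and extracts axial slices paired with the
#' liver-mask slices. Slices are drawn seeded, biased towards
#' liver-containing slices (empty slices teach the model the background
#' but carry little gradient signal under the dice loss).
#'
#' @param cases List of cases ([generate_case()] structures).
#' @param phase `"portal_venous"` or `"arterial"`.
#' @param timepoint `"pre"` or `"post"` (selects the volume; the liver mask
#'   is shared).
#' @param n_per_case Slices drawn per case.
#' @param seed Integer seed.
#' @param p_liver Fraction of slices drawn from liver-containing levels.
#' @param config A [pipeline_config()].
#' @param pad_multiple Slices are zero-padded to this per-axis multiple so
#'   they survive the network's pooling path (2^levels).
#' @return List of `list(input, target)` slice pairs.
#' @export
make_liver_slice_samples <- function(cases, phase = "portal_venous",
                                     timepoint = "pre", n_per_case = 6,
                                     seed = 1, p_liver = 0.85,
                                     config = pipeline_config(),
                                     pad_multiple = 16L) {
  set.seed(seed)
  out <- list()
  for (case in cases) {
    key <- paste0(timepoint, if (phase == "arterial") "_arterial"
                  else "_venous")
    v <- preprocess_ct(case$volumes[[key]], config)
    liver <- case$masks$liver$voxels
    nz <- dim(v$voxels)[1]
    has_liver <- which(vapply(seq_len(nz),
                              function(z) any(liver[z, , ] == 1),
                              logical(1)))
    n_fg <- min(length(has_liver), max(1L, round(p_liver * n_per_case)))
    zs <- has_liver[sample.int(length(has_liver), n_fg)]
    n_bg <- n_per_case - n_fg
    rest <- setdiff(seq_len(nz), has_liver)
    if (n_bg > 0 && length(rest) > 0)
      zs <- c(zs, rest[sample.int(length(rest), min(n_bg, length(rest)),
                                  replace = TRUE)])
    for (z in zs)
      out[[length(out) + 1]] <- list(
        input = pad_to_multiple(v$voxels[z, , ], pad_multiple)$padded,
        target = pad_to_multiple(liver[z, , ], pad_multiple)$padded)
  }
  out
}

#' Build balanced 3D patch samples for the lesion models
#'
#' Preprocesses each case and draws class-balanced patches at one scale via
#' [sample_training_patches()]; the lesion mask is the tumor mask for the
#' `"tumor"` task (pre-treatment volumes) and the ablation mask for the
#' `"ablation"` task (post-treatment volumes).
#'
#' @param cases List of cases.
#' @param task `"tumor"` or `"ablation"`.
#' @param spec A [patch_spec()] for the scale being trained.
#' @param phase Contrast phase to sample from.
#' @param n_per_class_per_case Foreground (= background) patches per case.
#' @param seed Integer seed.
#' @param config A [pipeline_config()].
#' @param pad_multiple Patches are zero-padded to this per-axis multiple
#'   (8 for the 3-level 3D networks: 20x30x30 -> 24x32x32).
#' @return List of `list(input, target, class)` patch samples.
#' @export
make_lesion_patch_samples <- function(cases, task = "tumor",
                                      spec = patch_spec(c(20, 30, 30)),
                                      phase = "portal_venous",
                                      n_per_class_per_case = 8, seed = 1,
                                      config = pipeline_config(),
                                      pad_multiple = 8L) {
  if (!task %in% c("tumor", "ablation"))
    stop_raunet("task must be tumor or ablation", "raunet_invalid_params")
  out <- list()
  for (i in seq_along(cases)) {
    case <- cases[[i]]
    v <- preprocess_ct(case_volume(case, task, phase), config)
    lesion <- case$masks[[task]]
    ps <- sample_training_patches(v, lesion, case$masks$liver, spec,
                                  n_per_class_per_case, seed + i)
    ps <- lapply(ps, function(p) {
      p$input <- pad_to_multiple(p$input, pad_multiple)$padded
      p$target <- pad_to_multiple(p$target, pad_multiple)$padded
      p
    })
    out <- c(out, ps)
  }
  out
}
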