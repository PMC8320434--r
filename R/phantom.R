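#' Synthetic multi-phase abdominal CT phantom parameters
#'
#' The phantom generator produces seeded, fully synthetic multi-phase
#' (arterial / portal venous), multi-timepoint (pre / post ablation)
#' abdominal CT volumes with exact ground-truth masks, so every pipeline
#' stage is exercisable without any clinical data. A case contains a
#' liver-like lobed ellipsoid at liver-tissue attenuation inside a
#' soft-tissue body; hypodense (venous) / rim-enhanced (arterial) tumors
#' fully inside the liver; and, post-treatment, a larger hypodense ablation
#' zone containing each tumor. Gaussian HU noise is added on top.
#'
#' Lesion volumes are drawn from truncated log-normal distributions whose
#' untruncated mean and SD equal the configured values — the natural
#' right-skewed model for lesion volumes, and the only two-parameter family
#' here whose mean survives the hard lower truncation essentially unshifted
#' (a normal with SD larger than its mean, truncated at ~0, would inflate
#' the mean far above the configured value). Defaults follow the clinical
#' summary statistics: tumors 10.43 +/- 18.52 cm^3 in `[0.06, 82.61]`,
#' ablation zones 56.66 +/- 36.20 cm^3 in `[6.76, 200.78]`, and 1-3 tumors
#' per case with probabilities 46/63, 11/63, 6/63.
#'
#' HU levels are chosen inside the `[-100, 200]` clip window so preprocessing
#' preserves contrast. `"easy"` mode widens the contrasts and removes noise
#' for fast deterministic training tests; `"realistic"` mode uses moderate
#' contrast and additive Gaussian noise.
#'
#' @param volume_shape Grid extents (z, y, x); at least 64 per axis.
#' @param spacing Isotropic voxel size in mm.
#' @param n_tumors `NULL` to sample the per-case tumor count from the
#'   default distribution over 1:3, or a fixed integer (0 allowed).
#' @param tumor_volume_mean,tumor_volume_sd,tumor_volume_range Tumor volume
#'   distribution (cm^3).
#' @param ablation_volume_mean,ablation_volume_sd,ablation_volume_range
#'   Ablation-zone volume distribution (cm^3).
#' @param hu Named list of HU levels (`background`, `liver`, `tumor_venous`,
#'   `tumor_arterial_core`, `tumor_arterial_rim`, `ablation`); `NULL` picks
#'   the mode's defaults.
#' @param noise_sd Additive Gaussian noise SD in HU; `NULL` picks the
#'   mode's default (10 realistic, 0 easy).
#' @param mode `"easy"` or `"realistic"`.
#' @param seed Integer seed; identical parameters produce voxel-identical
#'   cases.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(volume_shape = c(96, 160, 160), spacing = 1.0,
                           n_tumors = NULL,
                           tumor_volume_mean = 10.43,
                           tumor_volume_sd = 18.52,
                           tumor_volume_range = c(0.06, 82.61),
                           ablation_volume_mean = 56.66,
                           ablation_volume_sd = 36.20,
                           ablation_volume_range = c(6.76, 200.78),
                           hu = NULL, noise_sd = NULL,
                           mode = c("realistic", "easy"), seed = 1) {
  mode <- match.arg(mode)
  if (length(volume_shape) != 3 || any(volume_shape < 64))
    stop_raunet("volume_shape must be 3 extents, each >= 64",
                "raunet_invalid_params")
  hu_default <- if (mode == "easy") {
    list(background = -60, liver = 120, tumor_venous = -20,
         tumor_arterial_core = 40, tumor_arterial_rim = 190, ablation = -40)
  } else {
    list(background = 20, liver = 100, tumor_venous = 60,
         tumor_arterial_core = 80, tumor_arterial_rim = 150, ablation = 30)
  }
  structure(
    list(volume_shape = as.integer(volume_shape), spacing = spacing,
         n_tumors = n_tumors,
         tumor_volume_mean = tumor_volume_mean,
         tumor_volume_sd = tumor_volume_sd,
         tumor_volume_range = tumor_volume_range,
         ablation_volume_mean = ablation_volume_mean,
         ablation_volume_sd = ablation_volume_sd,
         ablation_volume_range = ablation_volume_range,
         hu = utils::modifyList(hu_default, hu %||% list()),
         noise_sd = noise_sd %||% (if (mode == "easy") 0 else 10),
         mode = mode, seed = as.integer(seed)),
    class = "phantom_params"
  )
}

# log-normal parameterized by its (untruncated) mean / sd, hard-truncated
# to the configured range by rejection
sample_truncated_volume <- function(n, mean, sd, range) {
  sigma2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - sigma2 / 2
  out <- numeric(0)
  for (i in 1:100) {
    x <- stats::rlnorm(max(n * 2, 16), meanlog = mu, sdlog = sqrt(sigma2))
    out <- c(out, x[x >= range[1] & x <= range[2]])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop_raunet("volume sampler failed to satisfy the truncation range",
              "raunet_phantom_sampling")
}

sample_tumor_count <- function(n) {
  sample.int(3, n, replace = TRUE, prob = c(46, 11, 6) / 63)
}

# squared normalized ellipsoid distance field on the (z,y,x) grid
ellipsoid_field <- function(shape, center, semi) {
  z <- (seq_len(shape[1]) - center[1]) / semi[1]
  y <- (seq_len(shape[2]) - center[2]) / semi[2]
  x <- (seq_len(shape[3]) - center[3]) / semi[3]
  outer(outer(z^2, y^2, `+`), x^2, `+`)
}

# random ellipsoid semi-axes (voxels) with the requested volume (cm^3)
semi_axes_for_volume <- function(volume_cm3, spacing) {
  r <- (volume_cm3 * 1000 / (4 / 3 * pi))^(1 / 3) / spacing
  aspect <- exp(runif(3, log(0.8), log(1.25)))
  aspect <- aspect / prod(aspect)^(1 / 3)
  r * aspect
}

erode_mask <- function(m, r) {
  inv <- 1L - m
  storage.mode(inv) <- "integer"
  1L - cpp_dilate_box(inv, dim(m), as.integer(r))
}

# largest erosion radius that still leaves interior voxels (binary search)
max_erosion_radius <- function(m, upper) {
  if (any(erode_mask(m, upper) == 1L)) return(upper)
  lo <- 0L; hi <- as.integer(upper)
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (any(erode_mask(m, mid) == 1L)) lo <- mid else hi <- mid
  }
  lo
}

#' Generate one synthetic case
#'
#' Builds the four CT volumes (pre/post x arterial/portal-venous) and the
#' three ground-truth masks of a phantom case. Tumor placement requires the
#' whole ablation zone to fit inside the liver; placement is retried with
#' fresh draws a bounded number of times before failing.
#'
#' @param params A [phantom_params()].
#' @return A list with elements `volumes` (named list of [ct_volume()]:
#'   `pre_arterial`, `pre_venous`, `post_arterial`, `post_venous`), `masks`
#'   (named list of [binary_mask()]: `liver`, `tumor`, `ablation`) and
#'   `lesions` (data frame of per-lesion sampled and realized volumes).
#' @export
generate_case <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  set.seed(params$seed)
  shp <- params$volume_shape
  sp <- params$spacing
  hu <- params$hu

  # lobed liver: main ellipsoid plus two overlapping lobes, jittered per case
  c0 <- shp * c(0.5, 0.48, 0.47) + runif(3, -2, 2)
  s0 <- shp * c(0.34, 0.30, 0.32) * exp(runif(3, -0.05, 0.05))
  liver <- ellipsoid_field(shp, c0, s0) <= 1
  for (k in 1:2) {
    ck <- c0 + shp * runif(3, -0.10, 0.10)
    sk <- s0 * exp(runif(3, log(0.45), log(0.7)))
    liver <- liver | (ellipsoid_field(shp, ck, sk) <= 1)
  }
  liver_m <- array(as.integer(liver), shp)

  n_t <- params$n_tumors %||% sample_tumor_count(1)
  tumor_m <- array(0L, shp)
  abl_m <- array(0L, shp)
  rim_m <- array(0L, shp)
  lesions <- list()

  for (ti in seq_len(n_t)) {
    placed <- FALSE
    for (attempt in 1:40) {
      tv <- if (!is.null(params$fixed_tumor_volumes))
        params$fixed_tumor_volumes[ti]
      else sample_truncated_volume(1, params$tumor_volume_mean,
                                   params$tumor_volume_sd,
                                   params$tumor_volume_range)
      av <- if (!is.null(params$fixed_ablation_volumes))
        params$fixed_ablation_volumes[ti]
      else max(sample_truncated_volume(1, params$ablation_volume_mean,
                                       params$ablation_volume_sd,
                                       params$ablation_volume_range),
               1.6 * tv)
      t_semi <- semi_axes_for_volume(tv, sp)
      a_semi <- pmax(semi_axes_for_volume(av, sp), t_semi * 1.15)

      # the whole ablation ellipsoid must fit inside the liver around the
      # tumor center; at a reduced field of view the sampled volumes can
      # exceed what the scaled-down liver admits, in which case both
      # lesions are shrunk isotropically to the largest size the liver
      # interior supports
      need <- as.integer(ceiling(max(a_semi))) + 1L
      occupied <- pmax(tumor_m, abl_m)
      feasible_centers <- function(r) {
        free <- erode_mask(liver_m, r) == 1L
        if (any(occupied == 1L))
          free <- free & cpp_dilate_box(occupied, shp, r) == 0L
        which(free)
      }
      interior <- feasible_centers(need)
      while (length(interior) == 0 && need > 4L) {
        need <- need - 2L
        interior <- feasible_centers(need)
      }
      if (length(interior) == 0) next
      if (need < ceiling(max(a_semi)) + 1) {
        f <- (need - 1) / max(a_semi)
        a_semi <- a_semi * f
        t_semi <- t_semi * f
        tv <- tv * f^3
        av <- av * f^3
        # freshly drawn volumes are not shrunk below the clinical range
        # (retrying draws a smaller lesion instead); fixed volumes from a
        # cohort manifest keep their target and accept the geometric cap
        if (is.null(params$fixed_tumor_volumes) &&
            tv < params$tumor_volume_range[1]) next
      }
      ctr_idx <- interior[sample.int(length(interior), 1)]
      ctr <- arrayInd(ctr_idx, shp)[1, ]

      t_field <- ellipsoid_field(shp, ctr, t_semi)
      tm <- t_field <= 1
      am <- ellipsoid_field(shp, ctr, a_semi) <= 1
      if (!any(tm) || any(tm & !liver) || any(am & !liver)) next
      if (any(tm & (tumor_m == 1L)) || any(am & (abl_m == 1L))) next

      tumor_m[tm] <- 1L
      abl_m[am] <- 1L
      rim <- (t_field <= 1.45) & !tm
      rim_m[rim] <- 1L
      lesions[[length(lesions) + 1]] <- data.frame(
        lesion = ti,
        tumor_volume_cm3 = tv,
        ablation_volume_cm3 = av,
        tumor_voxels = sum(tm),
        ablation_voxels = sum(am))
      placed <- TRUE
      break
    }
    if (!placed)
      stop_raunet("could not place a tumor/ablation pair inside the liver",
                  "raunet_phantom_placement")
  }

  base <- array(hu$background, shp)
  base[liver] <- hu$liver
  tm <- tumor_m == 1L
  am <- abl_m == 1L
  rm_ <- rim_m == 1L

  pre_ven <- base
  pre_ven[tm] <- hu$tumor_venous
  pre_art <- base
  pre_art[tm] <- hu$tumor_arterial_core
  pre_art[rm_] <- hu$tumor_arterial_rim
  post_ven <- base
  post_ven[am] <- hu$ablation
  post_art <- base
  post_art[am] <- hu$ablation

  noisy <- function(v, phase, tp) {
    if (params$noise_sd > 0)
      v <- v + array(rnorm(length(v), 0, params$noise_sd), dim(v))
    ct_volume(v, rep(sp, 3), phase = phase, timepoint = tp)
  }
  list(
    volumes = list(
      pre_arterial = noisy(pre_art, "arterial", "pre"),
      pre_venous = noisy(pre_ven, "portal_venous", "pre"),
      post_arterial = noisy(post_art, "arterial", "post"),
      post_venous = noisy(post_ven, "portal_venous", "post")),
    masks = list(
      liver = binary_mask(array(as.numeric(liver_m), shp), rep(sp, 3),
                          label = "liver"),
      tumor = binary_mask(array(as.numeric(tumor_m), shp), rep(sp, 3),
                          label = "tumor"),
      ablation = binary_mask(array(as.numeric(abl_m), shp), rep(sp, 3),
                             label = "ablation")),
    lesions = if (length(lesions)) do.call(rbind, lesions) else
      data.frame(lesion = integer(0), tumor_volume_cm3 = numeric(0),
                 ablation_volume_cm3 = numeric(0), tumor_voxels = integer(0),
                 ablation_voxels = integer(0))
  )
}

#' Generate a seeded phantom cohort
#'
#' Samples per-case lesion statistics (tumor count and volumes) for
#' `n_cases` phantoms and splits them deterministically into train and test
#' sets. Voxel grids are expensive, so by default only the manifest is
#' produced; `realize_case()` builds the actual volumes of a single case on
#' demand from its per-case seed.
#'
#' @param n_cases Number of cases (>= 2).
#' @param params A [phantom_params()]; the cohort seed derives per-case
#'   seeds from `params$seed`.
#' @param split Length-2 vector of train/test fractions summing to 1.
#' @return An object of class `phantom_cohort`: list with `manifest` (one
#'   row per case: `case_id`, `split`, `seed`, `n_tumors`,
#'   `tumor_volumes_cm3` comma-joined, `mean_tumor_volume_cm3`,
#'   `ablation_volumes_cm3`) and `params`.
#' @export
generate_cohort <- function(n_cases, params = phantom_params(),
                            split = c(train = 48 / 63, test = 15 / 63)) {
  if (n_cases < 2)
    stop_raunet("a cohort needs at least 2 cases", "raunet_invalid_params")
  if (abs(sum(split) - 1) > 1e-8)
    stop_raunet("split fractions must sum to 1", "raunet_invalid_params")
  set.seed(params$seed)
  n_train <- max(1L, round(split[[1]] * n_cases))
  if (n_train >= n_cases) n_train <- n_cases - 1L
  train_ids <- sort(sample.int(n_cases, n_train))

  rows <- lapply(seq_len(n_cases), function(i) {
    n_t <- params$n_tumors %||% sample_tumor_count(1)
    tv <- if (n_t > 0)
      sample_truncated_volume(n_t, params$tumor_volume_mean,
                              params$tumor_volume_sd,
                              params$tumor_volume_range) else numeric(0)
    av <- if (n_t > 0)
      pmax(sample_truncated_volume(n_t, params$ablation_volume_mean,
                                   params$ablation_volume_sd,
                                   params$ablation_volume_range),
           1.6 * tv) else numeric(0)
    data.frame(
      case_id = sprintf("case%03d", i),
      split = if (i %in% train_ids) "train" else "test",
      seed = params$seed + i,
      n_tumors = n_t,
      tumor_volumes_cm3 = paste(signif(tv, 6), collapse = ","),
      mean_tumor_volume_cm3 = if (n_t > 0) mean(tv) else NA_real_,
      ablation_volumes_cm3 = paste(signif(av, 6), collapse = ","))
  })
  structure(list(manifest = do.call(rbind, rows), params = params),
            class = "phantom_cohort")
}

#' @rdname generate_cohort
#' @param cohort A `phantom_cohort`.
#' @param case_id Case identifier from the manifest.
#' @export
realize_case <- function(cohort, case_id) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  row <- cohort$manifest[cohort$manifest$case_id == case_id, ]
  if (nrow(row) != 1)
    stop_raunet(sprintf("unknown case_id: %s", case_id), "raunet_invalid_params")
  p <- cohort$params
  p$seed <- row$seed
  p$n_tumors <- row$n_tumors
  if (row$n_tumors > 0) {
    # realize exactly the lesion volumes recorded in the manifest
    p$fixed_tumor_volumes <-
      as.numeric(strsplit(row$tumor_volumes_cm3, ",")[[1]])
    p$fixed_ablation_volumes <-
      as.numeric(strsplit(row$ablation_volumes_cm3, ",")[[1]])
  }
  generate_case(p)
}

#' Write a realized phantom cohort to disk
#'
#' Writes each case as NIfTI files in a per-case directory
#' (`pre_arterial.nii.gz`, ..., `mask_tumor.nii.gz`) plus a cohort manifest
#' CSV.
#'
#' @param cohort A `phantom_cohort` from [generate_cohort()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop_raunet(sprintf("cannot create output directory: %s", out_dir),
                "raunet_io_unwritable")
  for (cid in cohort$manifest$case_id) {
    cs <- realize_case(cohort, cid)
    cdir <- file.path(out_dir, cid)
    dir.create(cdir, showWarnings = FALSE)
    for (nm in names(cs$volumes))
      write_volume(cs$volumes[[nm]], file.path(cdir, paste0(nm, ".nii.gz")))
    for (nm in names(cs$masks))
      write_mask(cs$masks[[nm]], file.path(cdir, paste0("mask_", nm, ".nii.gz")))
  }
  mpath <- file.path(out_dir, "manifest.csv")
  write.csv(cohort$manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
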