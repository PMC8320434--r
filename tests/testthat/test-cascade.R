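test_that("liver_bbox centres the requested box on the mask centroid", {
  m <- binary_mask(make_sphere_mask(c(60, 80, 80), c(30, 40, 40), 8),
                   label = "liver")
  box <- liver_bbox(m, size = c(20, 30, 30))
  expect_identical(box$size, c(20L, 30L, 30L))
  # the box midpoint sits on the mask centroid to within a voxel
  mid <- box$start + box$size / 2
  expect_true(all(abs(mid - (c(30, 40, 40) - 0.5)) <= 1))
})

test_that("liver_bbox clamps to the volume and expands for large livers", {
  near_edge <- binary_mask(make_sphere_mask(c(40, 40, 40), c(5, 5, 5), 4),
                           label = "liver")
  box <- liver_bbox(near_edge, size = c(20, 20, 20))
  expect_identical(box$size, c(20L, 20L, 20L))
  expect_true(all(box$start >= 0L))
  expect_true(all(box$start + box$size <= c(40L, 40L, 40L)))

  # tight extent 21 > requested 15 -> extent + 2 * margin = 31
  wide <- array(0, c(40, 40, 40))
  wide[10:30, 15:25, 15:25] <- 1
  box2 <- liver_bbox(binary_mask(wide, label = "liver"),
                     size = c(15, 15, 15))
  expect_identical(box2$size[1], 31L)
  expect_identical(box2$size[2:3], c(15L, 15L))

  expect_error(liver_bbox(binary_mask(array(0, c(8, 8, 8)), label = "liver")),
               class = "raunet_empty_mask")
})

test_that("tile_patches reproduces the worked stride examples", {
  # axis 200, patch 40, 10% overlap -> stride 36, final start clamped to 160
  g <- tile_patches(bounding_box(c(0, 0, 0), c(200, 40, 40)),
                    patch_spec(c(40, 40, 40)))
  expect_identical(sort(unique(g$starts[, 1])),
                   c(0L, 36L, 72L, 108L, 144L, 160L))

  # the published geometry: 200x300x300 box, both scales
  box <- bounding_box(c(0, 0, 0), c(200, 300, 300))
  g1 <- tile_patches(box, patch_spec(c(20, 30, 30)))
  expect_identical(nrow(g1$starts), 1331L) # 11^3, exact edge fit
  g2 <- tile_patches(box, patch_spec(c(40, 60, 60)))
  expect_identical(nrow(g2$starts), 216L)  # 6^3

  # patch equal to box -> single patch at the origin
  g3 <- tile_patches(bounding_box(c(0, 0, 0), c(24, 24, 24)),
                     patch_spec(c(24, 24, 24)))
  expect_identical(g3$starts, matrix(0L, 1, 3))

  expect_error(tile_patches(bounding_box(c(0, 0, 0), c(10, 10, 10)),
                            patch_spec(c(20, 10, 10))),
               class = "raunet_invalid_params")
})

test_that("tiling covers every voxel, against a brute-force check", {
  set.seed(77)
  for (trial in 1:60) {
    size <- sample(10:40, 3, replace = TRUE)
    psize <- pmin(size, sample(3:20, 3, replace = TRUE))
    ov <- runif(1, 0, 0.5)
    g <- tile_patches(bounding_box(c(0, 0, 0), size), patch_spec(psize, ov))
    cover <- array(0L, size)
    for (i in seq_len(nrow(g$starts))) {
      s <- g$starts[i, ]
      expect_true(all(s >= 0L & s + psize <= size)) # inside the box
      cover[s[1] + seq_len(psize[1]), s[2] + seq_len(psize[2]),
            s[3] + seq_len(psize[3])] <-
        cover[s[1] + seq_len(psize[1]), s[2] + seq_len(psize[2]),
              s[3] + seq_len(psize[3])] + 1L
    }
    expect_true(all(cover >= 1L))
  }
})

test_that("stitch of the true sub-masks reconstructs the original mask", {
  set.seed(42)
  for (trial in 1:20) {
    size <- sample(15:35, 3, replace = TRUE)
    psize <- pmin(size, sample(4:14, 3, replace = TRUE))
    mask <- array(as.numeric(runif(prod(size)) < 0.2), size)
    g <- tile_patches(bounding_box(c(0, 0, 0), size),
                      patch_spec(psize, runif(1, 0, 0.4)))
    patches <- lapply(seq_len(nrow(g$starts)), function(i)
      raunet:::extract_patch(mask, g$starts[i, ], psize))
    expect_identical(stitch(g, patches), mask)
  }
})

test_that("stitch applies the union rule over overlapping patches", {
  g <- tile_patches(bounding_box(c(0, 0, 0), c(2, 2, 3)),
                    patch_spec(c(2, 2, 2), 0.5))
  expect_identical(nrow(g$starts), 2L) # starts 0 and 1 on the x axis
  a <- array(0, c(2, 2, 2)); a[1, 1, 2] <- 1  # voxel x=2 marked by patch 1
  b <- array(0, c(2, 2, 2))                   # unmarked by patch 2
  out <- stitch(g, list(a, b))
  expect_equal(out[1, 1, 2], 1)
  expect_error(stitch(g, list(a)), class = "raunet_shape_mismatch")
  expect_error(stitch(g, list(a, array(0, c(3, 3, 3)))),
               class = "raunet_shape_mismatch")
})

test_that("merge_scales is a union: commutative, associative, idempotent", {
  set.seed(8)
  arrs <- replicate(3, array(as.numeric(runif(60) < 0.4), c(3, 4, 5)),
                    simplify = FALSE)
  a <- arrs[[1]]; b <- arrs[[2]]; c_ <- arrs[[3]]
  empty <- array(0, dim(a))
  expect_identical(merge_scales(a, empty), a)
  expect_identical(merge_scales(a, a), a)
  expect_identical(merge_scales(a, b), merge_scales(b, a))
  expect_identical(merge_scales(merge_scales(a, b), c_),
                   merge_scales(a, merge_scales(b, c_)))
  expect_gte(sum(merge_scales(a, b)), max(sum(a), sum(b)))
  expect_error(merge_scales(a, array(0, c(2, 2, 2))),
               class = "raunet_shape_mismatch")
})

test_that("balanced patch sampling honours counts, centering and the seed", {
  shape <- c(40, 48, 48)
  liver <- binary_mask(make_sphere_mask(shape, c(20, 24, 24), 16),
                       label = "liver")
  lesion <- binary_mask(make_sphere_mask(shape, c(20, 24, 24), 5),
                        label = "tumor")
  vol <- ct_volume(array(runif(prod(shape)), shape))
  spec <- patch_spec(c(20, 30, 30))
  ps <- sample_training_patches(vol, lesion, liver, spec,
                                n_per_class = 36, seed = 3)
  expect_length(ps, 72) # the full-scale balanced batch size
  fg <- Filter(function(p) p$class == "foreground", ps)
  expect_length(fg, 36)
  for (p in fg) expect_gte(sum(p$target), 1) # every fg patch holds lesion
  for (p in ps) expect_identical(dim(p$input), c(20L, 30L, 30L))

  ps2 <- sample_training_patches(vol, lesion, liver, spec,
                                 n_per_class = 36, seed = 3)
  expect_identical(ps, ps2) # seeded determinism

  empty <- binary_mask(array(0, shape), label = "tumor")
  expect_error(sample_training_patches(vol, empty, liver, spec, 4, 1),
               class = "raunet_empty_mask")
})

test_that("pipeline configuration round-trips through YAML", {
  dirp <- withr::local_tempdir()
  cfg <- pipeline_config(box_size = c(100, 150, 150), threshold = 0.4,
                         merge = "mean", liver_dilation = 3L)
  fp <- file.path(dirp, "pipeline.yaml")
  write_pipeline_config(cfg, fp)
  back <- read_pipeline_config(fp)
  expect_equal(back, cfg)
})

test_that("segment_liver returns an aligned binary mask", {
  set.seed(15)
  m <- build_network(tiny_spec_2d(16))
  vol <- ct_volume(array(runif(6 * 20 * 24), c(6, 20, 24)))
  out <- segment_liver(vol, m, chunk = 4)
  expect_identical(dim(out$voxels), dim(vol$voxels))
  expect_true(all(out$voxels %in% c(0, 1)))
  m3 <- build_network(tiny_spec_3d())
  expect_error(segment_liver(vol, m3), class = "raunet_spec_mismatch")
})

test_that("run_pipeline is deterministic and respects the liver gate", {
  set.seed(16)
  liver_model <- build_network(tiny_spec_2d(16))
  lesion_model <- build_network(tiny_spec_3d(c(8, 8, 8)))
  vol <- ct_volume(array(runif(40 * 48 * 48, -100, 200), c(40, 48, 48)))
  cfg <- pipeline_config(box_size = c(24, 24, 24),
                         patch_sizes = list(c(12, 12, 12)),
                         liver_dilation = 2L)
  r1 <- run_pipeline(vol, liver_model, list(lesion_model), cfg)
  r2 <- run_pipeline(vol, liver_model, list(lesion_model), cfg)
  expect_identical(r1$lesion$voxels, r2$lesion$voxels)
  expect_identical(dim(r1$liver$voxels), dim(vol$voxels))
  # lesion voxels are confined to the dilated liver mask
  dil <- raunet:::cpp_dilate_box(array(as.integer(r1$liver$voxels),
                                       dim(vol$voxels)),
                                 dim(vol$voxels), 2L)
  expect_true(all(r1$lesion$voxels <= as.numeric(dil)))
})
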