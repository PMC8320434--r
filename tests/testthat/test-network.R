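test_that("the default 2D spec matches the published architecture counts", {
  spec <- network_spec_2d()
  expect_identical(spec$levels, 4L)
  expect_identical(spec$channel_schedule, c(32L, 64L, 128L, 256L, 512L))
  expect_identical(spec$n_residual_blocks, 9L)
  expect_identical(spec$n_attention_blocks, 4L)
})

test_that("network_spec validates shape divisibility and schedule length", {
  expect_error(network_spec(2, c(100, 100), 4, c(4, 8, 16, 32, 64)),
               class = "raunet_invalid_spec")
  expect_error(network_spec(2, c(64, 64), 4, c(4, 8, 16)),
               class = "raunet_invalid_spec")
  expect_error(network_spec(4, c(8, 8, 8, 8), 1, c(2, 4)),
               class = "raunet_invalid_spec")
})

test_that("dice_loss matches its closed-form values", {
  a <- array(c(1, 1, 0, 0), c(1, 2, 2))
  b <- array(c(0, 0, 1, 1), c(1, 2, 2))
  expect_equal(dice_loss(a, a), 0)          # perfect overlap
  expect_equal(dice_loss(a, b), 1)          # disjoint masks
  n <- 40
  truth <- array(1, c(2, 4, 5))
  pred <- array(0.5, c(2, 4, 5))
  # 1 - (2 * 0.5 n) / (n + 0.25 n) = 0.2
  expect_equal(dice_loss(truth, pred), 0.2)
  expect_error(dice_loss(a, array(0, c(2, 2, 2))),
               class = "raunet_shape_mismatch")
})

test_that("dice_loss is symmetric and its smoothed form handles empties", {
  set.seed(1)
  for (i in 1:5) {
    a <- array(runif(60), c(3, 4, 5))
    b <- array(runif(60), c(3, 4, 5))
    expect_equal(dice_loss(a, b), dice_loss(b, a))
  }
  z <- array(0, c(2, 2, 2))
  expect_equal(dice_loss(z, z), 0)
  expect_equal(dice_loss(z, z, smooth = 1), 0)
})

test_that("forward pass has the contracted shape and sigmoid range", {
  set.seed(3)
  m2 <- build_network(tiny_spec_2d(16))
  p <- predict(m2, matrix(runif(16 * 16), 16, 16))
  expect_identical(dim(p$voxels), c(16L, 16L))
  expect_true(all(p$voxels >= 0 & p$voxels <= 1))

  m3 <- build_network(tiny_spec_3d(c(8, 8, 8)))
  p3 <- predict(m3, array(runif(512), c(8, 8, 8)))
  expect_identical(dim(p3$voxels), c(8L, 8L, 8L))
  expect_true(all(p3$voxels >= 0 & p3$voxels <= 1))

  # fully convolutional: other divisible shapes are accepted
  p4 <- predict(m3, array(runif(8 * 16 * 16), c(8, 16, 16)))
  expect_identical(dim(p4$voxels), c(8L, 16L, 16L))

  expect_error(predict(m3, array(0, c(7, 8, 8))),
               class = "raunet_shape_mismatch")
  expect_error(predict(m2, array(0, c(8, 8, 8))),
               class = "raunet_shape_mismatch")
})

test_that("analytic gradients agree with finite differences", {
  set.seed(11)
  m <- build_network(tiny_spec_3d(c(8, 8, 8)))
  x <- array(runif(8 * 8 * 8 * 2), c(8, 8, 8, 1, 2))
  y <- array(as.numeric(runif(length(x)) > 0.5), dim(x))
  fg <- raunet:::forward_graph(m, x, training = TRUE, keep = TRUE)
  dout <- raunet:::dice_loss_grad(y, fg$out, smooth = 1)
  grads <- raunet:::backward_graph(m, fg, dout)
  eps <- 1e-5
  for (nm in sample(names(grads), 6)) {
    i <- sample(length(m$params[[nm]]), 1)
    mp <- m
    mp$params[[nm]][i] <- m$params[[nm]][i] + eps
    lp <- dice_loss(y, raunet:::forward_graph(mp, x, training = TRUE)$out, 1)
    mp$params[[nm]][i] <- m$params[[nm]][i] - eps
    lm <- dice_loss(y, raunet:::forward_graph(mp, x, training = TRUE)$out, 1)
    expect_equal(grads[[nm]][i], (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("binarize thresholds at >= and keeps the value set binary", {
  p <- structure(list(voxels = array(0.7, c(2, 2, 2))),
                 class = "probability_map")
  expect_true(all(binarize(p)$voxels == 1))
  p$voxels[] <- 0.3
  expect_true(all(binarize(p)$voxels == 0))
  p$voxels[] <- 0.5
  expect_true(all(binarize(p)$voxels == 1)) # inclusive threshold
  set.seed(2)
  p$voxels[] <- runif(8)
  expect_true(all(binarize(p)$voxels %in% c(0, 1)))
  p$voxels[1] <- 1.4
  expect_error(binarize(p), class = "raunet_invalid_input")
})

test_that("pad_to_multiple pads the published patch sizes and crops back", {
  x <- array(rnorm(20 * 30 * 30), c(20, 30, 30))
  r <- pad_to_multiple(x, 8)
  expect_identical(dim(r$padded), c(24L, 32L, 32L))
  expect_identical(raunet:::crop_to(r$padded, r$original), x)
  x2 <- array(rnorm(40 * 60 * 60), c(40, 60, 60))
  expect_identical(dim(pad_to_multiple(x2, 8)$padded), c(40L, 64L, 64L))
  # padded region is zero-filled
  expect_equal(sum(r$padded) - sum(x), 0)
})

test_that("checkpoints round-trip the model and write a YAML sidecar", {
  set.seed(8)
  dirp <- withr::local_tempdir()
  m <- build_network(tiny_spec_3d())
  ck <- file.path(dirp, "model.rds")
  save_checkpoint(m, ck, train_config = train_config())
  back <- load_checkpoint(ck)
  x <- array(runif(512), c(8, 8, 8))
  expect_identical(predict(back, x)$voxels, predict(m, x)$voxels)
  side <- yaml::read_yaml(file.path(dirp, "model.yaml"))
  expect_identical(side$spec$channel_schedule, c(4L, 8L))
  expect_error(load_checkpoint(file.path(dirp, "none.rds")),
               class = "raunet_io_missing")
})
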