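test_that("training is deterministic given seed, data and config", {
  set.seed(21)
  samples <- lapply(1:4, function(i) make_disc_slice(16, runif(1, 6, 10),
                                                     runif(1, 6, 10), 4))
  cfg <- train_config(learning_rate = 1e-3, max_epochs = 3, batch_size = 2,
                      val_fraction = 0, seed = 7)
  run <- function() {
    set.seed(5)
    m <- build_network(tiny_spec_2d(16))
    train(m, samples, cfg)
  }
  m1 <- run()
  m2 <- run()
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("plateau schedule reduces the learning rate after the patience", {
  set.seed(21)
  samples <- list(make_disc_slice(16))
  # a learning rate this small cannot move the monitored loss, so the
  # plateau counter runs out exactly at plateau_patience
  cfg <- train_config(learning_rate = 1e-14, max_epochs = 8,
                      plateau_patience = 3, early_stop_patience = 100,
                      lr_factor = 0.1, lr_floor = 1e-30, batch_size = 1,
                      val_fraction = 0, seed = 1)
  set.seed(5)
  m <- train(build_network(tiny_spec_2d(16)), samples, cfg)
  lr <- m$history$lr
  expect_equal(lr[1:3], rep(1e-14, 3))
  expect_equal(lr[4], 1e-14 * 0.1)   # drop recorded at patience + 1
  expect_equal(lr[7], 1e-14 * 0.01)  # and again after the next window
  expect_true(all(diff(m$history$lr) <= 0)) # lr history is non-increasing
})

test_that("early stopping halts training before max_epochs", {
  set.seed(21)
  samples <- list(make_disc_slice(16))
  cfg <- train_config(learning_rate = 1e-14, max_epochs = 50,
                      plateau_patience = 40, early_stop_patience = 4,
                      batch_size = 1, val_fraction = 0, seed = 1)
  set.seed(5)
  m <- train(build_network(tiny_spec_2d(16)), samples, cfg)
  # epoch 1 sets the best; patience runs out 4 epochs later, well before 50
  expect_equal(nrow(m$history), 5)
})

test_that("a tiny network overfits one easy slice", {
  set.seed(21)
  s <- make_disc_slice(32, 16, 16, 8)
  cfg <- train_config(learning_rate = 3e-3, max_epochs = 120,
                      plateau_patience = 30, early_stop_patience = 300,
                      batch_size = 1, val_fraction = 0, seed = 3)
  set.seed(6)
  m <- train(build_network(tiny_spec_2d(32)), list(s), cfg)
  final <- tail(m$history$train_loss, 1)
  expect_lt(final, 0.1)
})

test_that("train rejects empty sample streams", {
  set.seed(5)
  m <- build_network(tiny_spec_2d(16))
  expect_error(train(m, list(), train_config(seed = 1)),
               class = "raunet_no_samples")
})

test_that("a sample generator is re-invoked each epoch", {
  set.seed(21)
  calls <- 0L
  gen <- function(epoch) {
    calls <<- calls + 1L
    list(make_disc_slice(16))
  }
  cfg <- train_config(learning_rate = 1e-4, max_epochs = 3, batch_size = 1,
                      val_fraction = 0, seed = 2)
  set.seed(5)
  invisible(train(build_network(tiny_spec_2d(16)), gen, cfg))
  expect_identical(calls, 3L)
})

test_that("transfer_init copies weights exactly and checks the spec", {
  set.seed(31)
  base <- build_network(tiny_spec_2d(16))
  set.seed(99)
  fresh <- build_network(tiny_spec_2d(16))
  x <- matrix(runif(256), 16, 16)
  expect_false(identical(predict(fresh, x)$voxels, predict(base, x)$voxels))
  init <- transfer_init(fresh, base)
  expect_identical(predict(init, x)$voxels, predict(base, x)$voxels)

  set.seed(1)
  other <- build_network(network_spec_2d(c(16, 16), levels = 2,
                                         channel_schedule = c(6, 8, 12)))
  expect_error(transfer_init(other, base), class = "raunet_spec_mismatch")
})

test_that("fine-tuning on a second phase does not hurt that phase", {
  set.seed(41)
  # "phase A": bright discs; "phase B": same anatomy, weaker contrast
  phase_a <- lapply(1:4, function(i) make_disc_slice(16, runif(1, 6, 10),
                                                     runif(1, 6, 10), 4))
  phase_b <- lapply(phase_a, function(s) {
    s$input <- 0.25 + 0.5 * s$input
    s
  })
  cfg <- train_config(learning_rate = 3e-3, max_epochs = 25, batch_size = 4,
                      val_fraction = 0, seed = 11)
  set.seed(13)
  base <- train(build_network(tiny_spec_2d(16)), phase_a, cfg)
  loss_on <- function(model, samples) {
    mean(vapply(samples, function(s) {
      dice_loss(s$target, predict(model, s$input)$voxels)
    }, numeric(1)))
  }
  base_loss <- loss_on(base, phase_b)
  tuned <- transfer_init(build_network(tiny_spec_2d(16)), base)
  tuned <- train(tuned, phase_b, cfg)
  expect_lte(loss_on(tuned, phase_b), base_loss + 1e-8)
})
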