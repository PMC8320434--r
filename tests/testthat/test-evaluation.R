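test_that("dsc matches its closed-form values", {
  a <- make_sphere_mask(c(10, 10, 10), c(5, 5, 5), 3)
  expect_equal(dsc(a, a), 1)
  b <- array(0, dim(a)); b[1, 1, 1] <- 1
  a2 <- array(0, dim(a)); a2[10, 10, 10] <- 1
  expect_equal(dsc(a2, b), 0)
  # |RS| = 100, |PS| = 50, overlap 50 -> 2*50/150
  rs <- array(0, c(5, 5, 8)); rs[1:100] <- 1
  ps <- array(0, c(5, 5, 8)); ps[51:100] <- 1
  expect_equal(dsc(rs, ps), 2 * 50 / 150)
  expect_equal(dsc(array(0, c(2, 2, 2)), array(0, c(2, 2, 2))), 1)
  expect_error(dsc(a, array(0, c(2, 2, 2))), class = "raunet_shape_mismatch")
})

test_that("dsc equals 1 - dice_loss on random binary masks", {
  set.seed(6)
  for (i in 1:20) {
    a <- array(as.numeric(runif(4 * 5 * 6) < 0.4), c(4, 5, 6))
    b <- array(as.numeric(runif(4 * 5 * 6) < 0.4), c(4, 5, 6))
    if (sum(a) + sum(b) == 0) next
    expect_equal(dsc(a, b), 1 - dice_loss(a, b))
  }
})

test_that("dsc is symmetric and invariant to axis permutation", {
  set.seed(7)
  a <- array(as.numeric(runif(120) < 0.3), c(4, 5, 6))
  b <- array(as.numeric(runif(120) < 0.3), c(4, 5, 6))
  expect_equal(dsc(a, b), dsc(b, a))
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_equal(dsc(aperm(a, perm), aperm(b, perm)), dsc(a, b))
})

test_that("label_lesions separates components and converts volumes", {
  m <- array(0, c(20, 20, 20))
  m[2:5, 2:5, 2:5] <- 1
  m[12:15, 12:15, 12:15] <- 1
  ls <- label_lesions(binary_mask(m, label = "tumor"))
  expect_identical(nrow(ls$components), 2L)

  cube <- array(0, c(12, 12, 12))
  cube[2:11, 2:11, 2:11] <- 1 # 10^3 voxels at 1 mm iso = 1 cm^3
  ls2 <- label_lesions(binary_mask(cube, label = "tumor"))
  expect_equal(ls2$components$volume_cm3, 1.0)

  # corner-touching voxels: one component under 26-connectivity, two under 6
  diag2 <- array(0, c(4, 4, 4))
  diag2[1, 1, 1] <- 1
  diag2[2, 2, 2] <- 1
  expect_identical(nrow(label_lesions(diag2, 26)$components), 1L)
  expect_identical(nrow(label_lesions(diag2, 6)$components), 2L)

  empty <- label_lesions(array(0, c(3, 3, 3)))
  expect_identical(nrow(empty$components), 0L)
})

test_that("component labelling agrees with a brute-force flood fill", {
  set.seed(12)
  for (trial in 1:8) {
    m <- array(as.numeric(runif(10^3) < 0.25), c(10, 10, 10))
    for (conn in c(6, 26)) {
      got <- label_lesions(m, conn)
      want <- oracle_label(m, conn)
      expect_identical(max(got$labels), max(want))
      # same partition: labels agree up to renaming
      if (max(want) > 0) {
        pairs <- unique(cbind(got$labels[m == 1], want[m == 1]))
        expect_identical(nrow(pairs), max(want))
      }
    }
  }
})

test_that("match_lesions handles the contracted example cases", {
  shape <- c(20, 20, 20)
  two <- array(0, shape)
  two[2:4, 2:4, 2:4] <- 1
  two[10:12, 10:12, 10:12] <- 1
  ref <- label_lesions(two)
  m <- match_lesions(ref, label_lesions(two))
  expect_equal(m[c("TP", "FN", "FP")], list(TP = 2, FN = 0, FP = 0))

  m2 <- match_lesions(ref, label_lesions(array(0, shape)))
  expect_equal(m2[c("TP", "FN", "FP")], list(TP = 0, FN = 2, FP = 0))

  # P1 overlaps lesion A by one voxel, P2 is disjoint from everything
  a <- array(0, shape); a[5:8, 5:8, 5:8] <- 1
  pred <- array(0, shape)
  pred[8:10, 8:10, 8:10] <- 1   # shares the single voxel (8,8,8) with A
  pred[16:18, 16:18, 16:18] <- 1
  m3 <- match_lesions(label_lesions(a), label_lesions(pred))
  expect_equal(m3[c("TP", "FN", "FP")], list(TP = 1, FN = 0, FP = 1))
})

test_that("match_lesions agrees with an exhaustive overlap oracle", {
  set.seed(13)
  for (trial in 1:40) {
    shape <- sample(8:20, 3, replace = TRUE)
    ref_m <- array(as.numeric(runif(prod(shape)) < 0.12), shape)
    pred_m <- array(as.numeric(runif(prod(shape)) < 0.12), shape)
    ref <- label_lesions(ref_m)
    pred <- label_lesions(pred_m)
    got <- match_lesions(ref, pred)

    rl <- oracle_label(ref_m); pl <- oracle_label(pred_m)
    nr <- max(rl); np <- max(pl)
    overlap <- matrix(FALSE, max(nr, 1), max(np, 1))
    if (nr > 0 && np > 0)
      for (r in 1:nr) for (p in 1:np)
        overlap[r, p] <- any(rl == r & pl == p)
    tp <- if (nr > 0) sum(apply(overlap, 1, any)[seq_len(nr)]) else 0
    fp <- if (np > 0) sum(!apply(overlap, 2, any)[seq_len(np)]) else 0
    expect_identical(c(got$TP, got$FN, got$FP),
                     c(tp, nr - tp, fp))
  }
})

test_that("detection_stats reproduces the published F1 arithmetic", {
  # sensitivity/precision pairs printed with their F1 values
  expect_equal(round(f1_score(0.71, 0.46), 2), 0.56)
  expect_equal(round(f1_score(0.90, 0.61), 2), 0.73)
  expect_equal(f1_score(1, 1), 1)

  d <- detection_stats(list(list(TP = 7, FN = 3, FP = 2),
                            list(TP = 1, FN = 1, FP = 4)), n_images = 4)
  expect_equal(d$sensitivity, 8 / 12)
  expect_equal(d$precision, 8 / 14)
  expect_equal(d$fp_per_image, 6 / 4)
  expect_equal(d$f1, 2 * d$sensitivity * d$precision /
                 (d$sensitivity + d$precision))
  expect_error(detection_stats(list(), 0), class = "raunet_invalid_params")
})

test_that("degenerate detection counts follow the stated conventions", {
  none <- detection_stats(list(TP = 0, FN = 0, FP = 0), n_images = 1)
  expect_true(is.na(none$sensitivity))
  expect_equal(none$precision, 1)
  no_pred <- detection_stats(list(TP = 0, FN = 3, FP = 0), n_images = 1)
  expect_true(is.na(no_pred$precision))
  expect_equal(no_pred$sensitivity, 0)
  expect_equal(f1_score(0, 0), 0)
})

test_that("a simulated detector's sensitivity is recovered", {
  set.seed(99)
  p_detect <- 0.8
  n_lesions <- 400
  hits <- rbinom(1, n_lesions, p_detect)
  d <- detection_stats(list(TP = hits, FN = n_lesions - hits, FP = 0),
                       n_images = 50)
  # binomial 3-sigma band around the true detection probability
  expect_lt(abs(d$sensitivity - p_detect),
            3 * sqrt(p_detect * (1 - p_detect) / n_lesions))
})

test_that("volume_agreement computes r, bias and limits of agreement", {
  a <- volume_agreement(c(1, 2, 3), c(2, 4, 6))
  expect_equal(a$r, 1)
  expect_equal(a$bias, 2)
  ident <- volume_agreement(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(ident$r, 1)
  expect_equal(ident$bias, 0)
  expect_equal(ident$loa_high - ident$loa_low, 0)
  shift <- volume_agreement(c(1, 2, 3), c(6, 7, 8))
  expect_equal(shift$r, 1)
  expect_equal(shift$bias, 5)
  expect_error(volume_agreement(1:3, 1:4), class = "raunet_shape_mismatch")
  expect_error(volume_agreement(1:2, 1:2), class = "raunet_invalid_params")
  expect_error(volume_agreement(c(1, 1, 1), c(1, 2, 3)),
               class = "raunet_invalid_params")
})

test_that("filter_by_volume keeps the inclusive bound", {
  m <- array(0, c(30, 15, 15))
  m[1:4, 1:4, 1:4] <- 1          # 64 voxels = 0.064 cm^3
  m[20:29, 5:14, 5:14] <- 1      # 1000 voxels = 1 cm^3
  ls <- label_lesions(binary_mask(m, label = "tumor"))
  kept <- filter_by_volume(ls, 0.5)
  expect_identical(nrow(kept$components), 1L)
  expect_equal(kept$components$volume_cm3, 1.0)
  expect_identical(nrow(filter_by_volume(ls, 0)$components), 2L)

  exact <- array(0, c(10, 10, 10))
  exact[1:10, 1:10, 1:5] <- 1    # exactly 0.5 cm^3
  ls2 <- label_lesions(binary_mask(exact, label = "tumor"))
  expect_identical(nrow(filter_by_volume(ls2, 0.5)$components), 1L)
})
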