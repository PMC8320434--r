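# Shared fixtures: tiny volumes, masks and network specs sized for fast tests.

make_test_volume <- function(shape = c(8, 12, 12), value = 50,
                             spacing = c(1, 1, 1)) {
  ct_volume(array(value, shape), spacing = spacing)
}

make_disc_slice <- function(n = 32, cx = n / 2, cy = n / 2, r = n / 4) {
  g <- expand.grid(y = seq_len(n), x = seq_len(n))
  d <- sqrt((g$y - cy)^2 + (g$x - cx)^2)
  img <- matrix(0.3, n, n)
  msk <- matrix(0, n, n)
  img[d <= r] <- 0.8
  msk[d <= r] <- 1
  list(input = img, target = msk)
}

make_sphere_mask <- function(shape, center, radius) {
  gz <- slice.index(array(0, shape), 1)
  gy <- slice.index(array(0, shape), 2)
  gx <- slice.index(array(0, shape), 3)
  d <- sqrt((gz - center[1])^2 + (gy - center[2])^2 + (gx - center[3])^2)
  array(as.numeric(d <= radius), shape)
}

tiny_spec_2d <- function(n = 32)
  network_spec_2d(c(n, n), levels = 2, channel_schedule = c(4, 8, 12))

tiny_spec_3d <- function(shape = c(8, 8, 8))
  network_spec_3d(shape, levels = 1, channel_schedule = c(4, 8))

# brute-force 3D connected-component labelling (flood fill in plain R),
# independent oracle for label_lesions / match_lesions
oracle_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  nb <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  nb <- nb[!(nb$dz == 0 & nb$dy == 0 & nb$dx == 0), ]
  if (connectivity == 6)
    nb <- nb[abs(nb$dz) + abs(nb$dy) + abs(nb$dx) == 1, ]
  cur <- 0L
  for (p in which(mask != 0)) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    queue <- p
    lab[p] <- cur
    while (length(queue) > 0) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ind <- arrayInd(q, d)
      for (k in seq_len(nrow(nb))) {
        z <- ind[1] + nb$dz[k]; y <- ind[2] + nb$dy[k]; x <- ind[3] + nb$dx[k]
        if (z < 1 || z > d[1] || y < 1 || y > d[2] || x < 1 || x > d[3]) next
        if (mask[z, y, x] != 0 && lab[z, y, x] == 0L) {
          lab[z, y, x] <- cur
          queue <- c(queue, (x - 1) * d[1] * d[2] + (y - 1) * d[1] + z)
        }
      }
    }
  }
  lab
}
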