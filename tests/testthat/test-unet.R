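small_cfg <- unet_config()   # architecture is fixed; inputs vary

test_that("model output is a per-pixel softmax of the right shape", {
  m <- build_unet(small_cfg, seed = 1)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p <- unet_predict(m, x)
  expect_equal(dim(p), c(64L, 64L, 2L))
  expect_lt(max(abs(p[, , 1] + p[, , 2] - 1)), 1e-5)
  # zero input: spatially constant probabilities
  p0 <- unet_predict(m, array(0, c(32, 32, 3)))
  expect_lt(max(abs(p0[, , 2] - p0[1, 1, 2])), 1e-9)
  expect_error(unet_predict(m, array(0, c(48, 48, 3))), "multiples")
})

test_that("trainable parameter count matches the layer-wise closed form", {
  m <- build_unet(small_cfg, seed = 2)
  k2 <- 5^2
  fd <- c(10, 20, 30, 40, 50); fu <- rev(fd)
  d_in <- c(3, fd[-5])
  u_in <- c(fd[5], fu[1] + fd[4], fu[2] + fd[3], fu[3] + fd[2], fu[4] + fd[1])
  n_expected <- sum(k2 * d_in * fd + fd) +     # down convs + biases
    sum(k2 * u_in * fu + fu) +                 # up (transposed) convs + biases
    (1 * 1 * fu[5] * 2 + 2)                    # final 1x1 softmax conv
  expect_identical(unet_n_params(m), as.integer(n_expected))
})

test_that("analytic gradients match finite differences", {
  m <- build_unet(small_cfg, seed = 3)
  set.seed(11)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  y <- matrix(0L, 32, 32); y[10:20, 12:15] <- 1L
  w <- spatial_weight_map(y, weight_params())
  g <- myelinquant:::unet_grad_cpp(m$params, x, y, w, 10)
  th <- unlist(m$params); sk <- m$params; gv <- unlist(g$grads)
  idx <- sort(sample(length(th), 10))
  num <- vapply(idx, function(i) {
    e <- 1e-5
    tp <- th; tp[i] <- tp[i] + e
    lp <- myelinquant:::unet_grad_cpp(utils::relist(tp, sk), x, y, w, 10)$loss
    tm <- th; tm[i] <- tm[i] - e
    lm <- myelinquant:::unet_grad_cpp(utils::relist(tm, sk), x, y, w, 10)$loss
    (lp - lm) / (2 * e)
  }, 0)
  rel <- abs(num - gv[idx]) / pmax(abs(num) + abs(gv[idx]), 1e-8)
  expect_lt(max(rel), 1e-4)
})

test_that("spatial weight map reproduces the edge-decay formula exactly", {
  # brute-force Chebyshev oracle on random small masks
  set.seed(5)
  for (k in 1:100) {
    h <- sample(8:64, 1); w <- sample(8:64, 1)
    tr <- matrix(0L, h, w)
    n_on <- sample(0:6, 1)
    if (n_on > 0) tr[cbind(sample(h, n_on, TRUE), sample(w, n_on, TRUE))] <- 1L
    D <- myelinquant:::chebyshev_dt(tr)
    if (n_on > 0) {
      pts <- which(tr == 1L); pr <- (pts - 1) %% h; pc <- (pts - 1) %/% h
      bf <- matrix(0, h, w)
      for (r in 1:h) for (c in 1:w)
        bf[r, c] <- min(pmax(abs(r - 1 - pr), abs(c - 1 - pc)))
      expect_identical(D, bf)
    } else {
      expect_true(all(D == h + w))
    }
  }
  # plug-in values of the decay formula
  tr <- matrix(0L, 16, 16); tr[8, 8] <- 1L
  wmap <- spatial_weight_map(tr, weight_params(f = 6, b = 0))
  expect_equal(wmap[8, 8], exp(1))                    # D = 0 -> w = e
  expect_equal(wmap[8, 14], 1)                        # D = f -> w = 1
  # strict monotone decay along a ray until the edge
  expect_true(all(diff(wmap[8, 8:16]) < 0))
  # additive-floor mode
  wadd <- spatial_weight_map(tr, weight_params(f = 6, b = 0.5,
                                               spatial_mode = "additive_floor"))
  expect_equal(wadd[8, 8], exp(1) + 0.5)
  expect_gte(min(wadd), 0.5)
})

test_that("weighted loss has its closed-form anchors", {
  # perfect one-hot prediction: loss ~ 0
  y <- matrix(0L, 8, 8); y[3:5, 3:5] <- 1L
  pred <- array(0, c(8, 8, 2))
  pred[, , 1] <- 1 - y; pred[, , 2] <- y
  expect_lt(weighted_loss(pred, y), 1e-6)
  # uniform p = 0.5, all-background truth, unit weights: loss = ln 2
  pred5 <- array(0.5, c(8, 8, 2))
  expect_equal(weighted_loss(pred5, matrix(0L, 8, 8)), log(2))
  # doubling class weight strictly increases loss when truth pixels err
  l1 <- weighted_loss(pred5, y, class_weight = 10)
  l2 <- weighted_loss(pred5, y, class_weight = 20)
  expect_gt(l2, l1)
  # direct recomputation oracle
  w <- spatial_weight_map(y, weight_params())
  cw <- w * ifelse(y == 1, 10, 1)
  expect_equal(weighted_loss(pred5, y, w, 10), mean(cw * log(2)))
  bad <- pred5; bad[1, 1, 1] <- 1.2
  expect_error(weighted_loss(bad, y), "outside")
})

test_that("inference threshold boundaries and monotonicity hold", {
  m <- build_unet(small_cfg, seed = 4)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_true(all(infer_cell(m, x, threshold = 0) == 1L))
  expect_true(all(infer_cell(m, x, threshold = 1 + 1e-9) == 0L))
  counts <- vapply(c(0, 0.25, 0.5, 0.75, 1.01),
                   function(t) sum(infer_cell(m, x, t)), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("short training descends and is seed-reproducible", {
  exs <- phantom_example_set(300, crop_size_px = 64, n_cells = 10)
  train <- exs[1:8]; val <- exs[9:10]
  tc <- train_config(steps = 30, batch_size = 2, learning_rate = 1e-3,
                     seed = 7, val_every = 10)
  r1 <- unet_train(build_unet(seed = 7), train, val, tc, weight_params())
  r2 <- unet_train(build_unet(seed = 7), train, val, tc, weight_params())
  expect_identical(r1$log, r2$log)
  # validation loss (a stable mean over the val set) must descend
  expect_lt(r1$log$val_loss[nrow(r1$log)], r1$log$val_loss[1])
  expect_s3_class(r1$log, "train_log")
  g <- glance(r1$log)
  expect_equal(g$best_val_ji, max(r1$log$val_mean_ji))
})

test_that("a perfect-model stub reproduces the truth through infer_well", {
  ph <- generate_phantom(phantom_spec(height_px = 512, width_px = 512,
                                      n_cells = 8, p_ensheathing = 1,
                                      log10_length_mean = 1.3,
                                      log10_length_sd = 0.08, seed = 12))
  tr <- ph$truth
  nuc_cand <- tibble::tibble(
    cell_id = tr$cells$cell_id,
    centroid_y = tr$cells$centroid_y, centroid_x = tr$cells$centroid_x,
    nucleus_px = lapply(tr$cells$cell_id, function(id) which(tr$nuclei == id)))
  # stub: replace the network by an oracle returning the candidate's truth crop
  stub_infer <- function(cand, crop) {
    yfull <- (tr$sheaths == cand$cell_id) + 0
    myelinquant:::crop_window(yfull, c(round(cand$centroid_y) - crop / 2,
                                       round(cand$centroid_x) - crop / 2), crop)
  }
  d <- c(512L, 512L)
  got <- matrix(0L, d[1], d[2])
  for (i in seq_len(nrow(nuc_cand))) {
    mask <- stub_infer(nuc_cand[i, ], 256)
    off <- as.integer(round(c(nuc_cand$centroid_y[i],
                              nuc_cand$centroid_x[i])) - 128)
    u <- myelinquant:::uncrop_indices(off, 256, d)
    got[u$well_r, u$well_c] <- pmax(got[u$well_r, u$well_c],
                                    (mask[u$crop_r, u$crop_c] > 0) + 0L)
  }
  expect_identical(got > 0, tr$sheaths > 0)
  # infer_well contract: zero candidates give an empty record set
  m <- build_unet(small_cfg, seed = 1)
  empty <- infer_well(m, ph$image, nuc_cand[0, ], crop_size_px = 128)
  expect_equal(nrow(empty), 0L)
})
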