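test_that("training masks are reproducible rectangles in the area range", {
  m1 <- random_training_mask(c(32, 32), seed = 7)
  m2 <- random_training_mask(c(32, 32), seed = 7)
  expect_identical(m1, m2)
  fracs <- sapply(1:100, function(s)
    mean(random_training_mask(c(32, 32), seed = s)))
  expect_true(all(fracs > 0.05 & fracs < 0.45))  # rounding slack on 10-35%
  expect_true(mean(fracs >= 0.10 & fracs <= 0.35) > 0.9)
  # a mask is a single axis-aligned rectangle
  m <- random_training_mask(c(20, 20), seed = 3)
  rows <- range(which(rowSums(m) > 0)); cols <- range(which(colSums(m) > 0))
  expect_equal(sum(m), diff(rows + c(0, 1)) * diff(cols + c(0, 1)))
})

test_that("chebyshev distance matches a brute-force scan", {
  set.seed(13)
  for (i in 1:5) {
    m <- matrix(rbinom(144, 1, 0.4), 12, 12)
    m[1, 1] <- 0
    d <- chebyshev_distance(m)
    known <- which(m == 0, arr.ind = TRUE)
    for (px in seq_len(144)) {
      r <- (px - 1) %% 12 + 1; c <- (px - 1) %/% 12 + 1
      ref <- min(pmax(abs(known[, 1] - r), abs(known[, 2] - c)))
      expect_equal(d[r, c], ref)
    }
  }
})

test_that("gamma = 1 reduces the discounted loss to plain L1", {
  set.seed(2)
  pred <- array(runif(16 * 16 * 3 * 2, -1, 1), c(16, 16, 3, 2))
  targ <- array(runif(16 * 16 * 3 * 2, -1, 1), c(16, 16, 3, 2))
  mask <- array(0, c(16, 16, 2)); mask[4:10, 5:12, ] <- 1
  l <- discounted_l1(pred, targ, mask, gamma = 1)
  expect_equal(l$loss, mean(abs(pred - targ)), tolerance = 1e-12)
  # discounting keeps known pixels at weight 1 and shrinks hole weights
  ld <- discounted_l1(pred, targ, mask, gamma = 0.9)
  expect_lt(ld$loss, l$loss + 1e-12)
})

test_that("the coarse network is deterministic, finite and composites exactly", {
  cfg <- inpaint_config(size = 16, channels = 4)
  m <- build_inpaint_model(cfg, seed = 5)
  m2 <- build_inpaint_model(cfg, seed = 5)
  x <- array(runif(16 * 16 * 3 * 2, -1, 1), c(16, 16, 3, 2))
  msk <- array(0, c(16, 16, 2)); msk[5:9, 5:9, ] <- 1
  r1 <- coarse_forward(m, x, msk)
  r2 <- coarse_forward(m2, x, msk)
  expect_identical(r1$pred, r2$pred)
  expect_true(all(is.finite(r1$pred)))
  # no-hole case: composite equals the input exactly
  r0 <- coarse_forward(m, x, array(0, c(16, 16, 2)))
  expect_identical(r0$composite, x)
})

test_that("the refinement composite never touches pixels outside the mask", {
  cfg <- inpaint_config(size = 16, channels = 4)
  m <- build_inpaint_model(cfg, seed = 5)
  x <- array(runif(16 * 16 * 3 * 2, -1, 1), c(16, 16, 3, 2))
  msk <- array(0, c(16, 16, 2)); msk[3:8, 6:12, ] <- 1
  cf <- coarse_forward(m, x, msk)
  rf <- refine_forward(m, x, cf, msk)
  m3 <- array(0, dim(x))
  for (n in 1:2) m3[, , , n] <- array(rep(msk[, , n], 3), c(16, 16, 3))
  expect_identical(rf$composite[m3 == 0], x[m3 == 0])
  # no-hole case is the bit-exact identity
  rf0 <- refine_forward(m, x, coarse_forward(m, x, array(0, c(16, 16, 2))),
                        array(0, c(16, 16, 2)))
  expect_identical(rf0$composite, x)
})

test_that("the attention branch is live: disabling it changes the output", {
  cfg <- inpaint_config(size = 32, channels = 4)
  m <- build_inpaint_model(cfg, seed = 6)
  set.seed(8)
  x <- array(runif(32 * 32 * 4 * 1, -1, 1), c(32, 32, 4, 1))
  msk <- array(0, c(32, 32, 1)); msk[13:20, 13:20, ] <- 1
  with_attn <- tonguetex:::nn_forward(m$refine, x, ctx = list(mask = msk))
  without <- tonguetex:::nn_forward(m$refine, x, ctx = list(mask = NULL))
  expect_gt(max(abs(with_attn$y - without$y)), 0)
})

test_that("the loss on a fixed batch decreases over the first 50 steps", {
  cfg <- inpaint_config(size = 32, channels = 8, lr = 1e-4)
  model <- build_inpaint_model(cfg, seed = 3)
  p <- default_params(seed = 8)
  tp <- generate_texture_patches(p, 2, patch_size = 32, seed = 14)
  x <- tp$x * 2 - 1
  masks <- array(0, c(32, 32, dim(x)[4]))
  for (i in seq_len(dim(x)[4]))
    masks[, , i] <- random_training_mask(c(32, 32), seed = 20 + i)
  opt <- list(coarse = tonguetex:::adam_init(),
              refine = tonguetex:::adam_init())
  losses <- numeric(50)
  for (s in 1:50) {
    r <- tonguetex:::.inpaint_step(model, opt, x, masks, cfg$gamma, cfg$lr)
    model <- r$model; opt <- r$opt
    losses[s] <- r$loss
  }
  expect_lt(losses[50], losses[1])
  expect_lt(mean(losses[41:50]), mean(losses[1:10]))
})

test_that("overfitting constant patches drives the coarse fill to the constant", {
  const <- 0.3
  corpus <- array_corpus(array(const, c(32, 32, 3, 40)))
  cfg <- inpaint_config(size = 32, channels = 8, epochs = 4, lr = 1e-3)
  m <- train_inpainter(corpus, cfg, seed = 2)
  x <- array(const * 2 - 1, c(32, 32, 3, 1))
  msk <- array(0, c(32, 32, 1)); msk[8:24, 8:24, ] <- 1
  cf <- coarse_forward(m, x, msk)
  pred01 <- (cf$pred + 1) / 2
  m3 <- array(rep(msk[, , 1], 3), c(32, 32, 3))
  expect_lt(abs(mean(pred01[, , , 1][m3 == 1]) - const), 0.05)
})

test_that("training on a tagged 396/48 corpus halves the validation loss", {
  p <- default_params(seed = 8, coating_area_fraction = 0)
  tp <- generate_texture_patches(p, 148, patch_size = 32, seed = 2)
  corpus <- split_corpus(array_corpus(tp$x), c(396, 48), seed = 1)
  cfg <- inpaint_config(size = 32, channels = 16, epochs = 2, lr = 1e-4)
  m <- train_inpainter(corpus, cfg, seed = 1)
  expect_equal(nrow(m$history), 2)
  expect_lt(m$best_val_loss, 0.5 * m$initial_val_loss)
  # checkpoint round-trip preserves behavior
  path <- file.path(tempdir(), "im.rds")
  save_inpaint_model(m, path)
  m2 <- load_inpaint_model(path)
  x <- tp$x[, , , 1:2, drop = FALSE] * 2 - 1
  msk <- array(0, c(32, 32, 2)); msk[10:20, 10:20, ] <- 1
  expect_identical(coarse_forward(m, x, msk)$pred,
                   coarse_forward(m2, x, msk)$pred)
  expect_error(train_inpainter(tonguetex:::.empty_corpus(32L), cfg), "empty")
})

test_that("coating inpainting preserves non-coating pixels bit-exactly", {
  p <- default_params(seed = 8)
  s <- generate_sample(p, "normal", seed = 31)
  cfg <- inpaint_config(size = 32, channels = 4)
  m <- build_inpaint_model(cfg, seed = 1)   # untrained: conservation only
  out <- inpaint_coating(s$image, s$tongue_mask, s$coating_mask, m)
  m3 <- array(rep(s$coating_mask, 3), dim(s$image))
  expect_identical(out[m3 == 0], s$image[m3 == 0])
  expect_true(all(out >= 0 & out <= 1))
  # empty mask is the identity; full coverage has no background to draw from
  expect_identical(inpaint_coating(s$image, s$tongue_mask,
                                   matrix(0, 128, 128), m), s$image)
  expect_error(inpaint_coating(s$image, s$tongue_mask, s$tongue_mask, m),
               "no known background")
  expect_error(inpaint_coating(s$image, s$coating_mask, s$tongue_mask, m),
               "subset")
})

test_that("a trained model repairs corrupted body regions", {
  p <- default_params(seed = 8, coating_area_fraction = 0)
  tp <- generate_texture_patches(p, 120, patch_size = 32, seed = 5)
  cfg <- inpaint_config(size = 32, channels = 16, epochs = 3, lr = 3e-4)
  m <- train_inpainter(array_corpus(tp$x), cfg, seed = 4)
  s <- generate_sample(p, "tough", seed = 99)           # pure body truth
  blob <- generate_sample(default_params(seed = 55), "tough",
                          seed = 55)$coating_mask * s$tongue_mask
  # corrupt the blob with coating-colored pixels, then inpaint it away
  corrupted <- s$image
  pc <- default_params(seed = 8)
  ncor <- sum(blob)
  set.seed(77)
  fakecols <- tonguetex:::.rmvn3(ncor, pc$coating_color_mean,
                                 pc$coating_color_cov)
  for (ch in 1:3) {
    pl <- corrupted[, , ch]; pl[blob == 1] <- fakecols[, ch]
    corrupted[, , ch] <- pl
  }
  out <- inpaint_coating(corrupted, s$tongue_mask, blob, m)
  m3 <- array(rep(blob, 3), dim(s$image))
  l1_inpainted <- mean(abs(out[m3 == 1] - s$image[m3 == 1]))
  l1_corrupted <- mean(abs(corrupted[m3 == 1] - s$image[m3 == 1]))
  expect_lt(l1_inpainted, l1_corrupted)
  # and it approaches the per-image mean-color noise floor
  fill <- s$image
  known <- s$tongue_mask * (1 - blob)
  for (ch in 1:3) {
    pl <- fill[, , ch]
    pl[blob == 1] <- mean(s$image[, , ch][known == 1])
    fill[, , ch] <- pl
  }
  l1_fill <- mean(abs(fill[m3 == 1] - s$image[m3 == 1]))
  expect_lt(l1_inpainted, 2 * l1_fill)
})
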