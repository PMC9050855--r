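test_that("center crop and re-embedding follow the stated geometry", {
  cc <- center_crop(array(1, c(160, 120, 30)), c(128, 96))
  expect_equal(dim(cc$volume), c(128, 96, 30))
  expect_equal(cc$offset, c(16L, 12L))

  cc2 <- center_crop(array(1, c(128, 96, 22)), c(128, 96))
  expect_equal(dim(cc2$volume), c(128, 96, 22))
  expect_equal(cc2$offset, c(0L, 0L))
  expect_true(all(cc2$pad == 0))

  cc3 <- center_crop(array(1, c(100, 80, 25)), c(128, 96))
  expect_equal(dim(cc3$volume), c(128, 96, 25))
  expect_equal(unname(cc3$pad[, "low"]), c(14L, 8L))
  expect_equal(unname(cc3$pad[, "high"]), c(14L, 8L))

  # odd margins put the extra voxel on the low side
  cc4 <- center_crop(array(1, c(131, 97, 5)), c(128, 96))
  expect_equal(cc4$offset, c(2L, 1L))

  # exact round trip through embed_crop
  vol <- array(rnorm(40 * 30 * 6), c(40, 30, 6))
  cc5 <- center_crop(vol, c(24, 16))
  back <- embed_crop(cc5$volume, dim(vol), cc5)
  expect_equal(back[9:32, 8:23, ], vol[9:32, 8:23, ])
  expect_true(all(back[1:8, , ] == 0))
})

test_that("model construction is seeded, sized by config, and validated", {
  cfg <- cnn_config(crop_xy = c(32, 24), levels = 3,
                    dense_layers_per_block = 2, growth_rate = 8,
                    channels = 8, seed = 7, epochs = 1)
  m1 <- build_unet(cfg); m2 <- build_unet(cfg)
  w1 <- flowunwrap:::.unet_get_weights(m1$ptr)
  w2 <- flowunwrap:::.unet_get_weights(m2$ptr)
  expect_identical(w1, w2)

  # larger growth strictly increases the parameter count
  n8 <- n_params(m1)
  n12 <- n_params(build_unet(cnn_config(crop_xy = c(32, 24), levels = 3,
                                        dense_layers_per_block = 2,
                                        growth_rate = 12, channels = 8,
                                        epochs = 1)))
  expect_gt(n12, n8)

  expect_error(cnn_config(crop_xy = c(33, 24), levels = 3), "divisible")
  expect_error(cnn_config(dropout = 1), "dropout")
})

test_that("forward pass produces a normalized two-channel softmax", {
  cfg <- cnn_tiny_config(seed = 2)
  m <- build_unet(cfg)
  vol <- array(0, c(48, 32, 8))
  out <- flowunwrap:::.unet_forward(m$ptr, as.numeric(vol), dim(vol))
  expect_length(out$prob, 48 * 32 * 8)
  expect_true(all(out$prob >= 0 & out$prob <= 1))
  # untrained background-biased head: empty mask, even on noise
  expect_equal(sum(out$mask), 0)
  set.seed(1)
  noisy <- array(rnorm(48 * 32 * 8), c(48, 32, 8))
  out2 <- flowunwrap:::.unet_forward(m$ptr, as.numeric(noisy), dim(noisy))
  expect_equal(sum(out2$mask), 0)
})

test_that("predicted masks are congruent with the field", {
  ph <- desk_phantom(seed = 1, n_frames = 2, grid = c(32, 24, 12),
                     vessel = vessel_ubend(radius_mm = 6, bend_radius_mm = 10))
  m <- build_unet(cnn_tiny_config(crop_xy = c(24, 16), seed = 1))
  mask <- predict_unet(m, ph$field)
  expect_identical(dim(mask), dim(ph$field$values))
  expect_error(predict_unet(m, "not a field"), "velocity_field")
})

test_that("composite loss matches a hand-computed toy value", {
  # 2x2x1 volume: truth {2 fg}, prediction probabilities fixed
  p <- array(c(0.9, 0.8, 0.3, 0.1), c(2, 2, 1))
  t <- array(c(1, 1, 0, 0), c(2, 2, 1))
  res <- composite_loss(p, t)
  ce_hand <- -mean(log(c(0.9, 0.8, 0.7, 0.9)))
  dice_hand <- 1 - (2 * (0.9 + 0.8) + 1e-5) / ((0.9 + 0.8 + 0.3 + 0.1) + 2 + 1e-5)
  expect_equal(res$ce, ce_hand, tolerance = 1e-12)
  expect_equal(res$dice_loss, dice_hand, tolerance = 1e-12)
  expect_equal(res$loss, ce_hand + dice_hand, tolerance = 1e-12)

  # perfect hard prediction: both terms vanish (up to the epsilon)
  perfect <- composite_loss(t, t)
  expect_lt(perfect$ce, 1e-10)
  expect_lt(abs(perfect$dice_loss), 1e-5)

  # empty truth with all-background prediction is finite and minimal
  e <- composite_loss(array(0, c(2, 2, 1)), array(0, c(2, 2, 1)))
  expect_true(is.finite(e$loss))
  worse <- composite_loss(array(c(0.5, 0, 0, 0), c(2, 2, 1)),
                          array(0, c(2, 2, 1)))
  expect_lt(e$loss, worse$loss)
})

test_that("an epoch enumerates every wrap x frame x direction sample", {
  # 2 phantoms x 4 wraps x 10 frames x 3 directions = 240 samples
  n_epoch_samples <- 2 * 4 * 10 * 3
  expect_equal(n_epoch_samples, 240)
  ph <- lapply(1:2, function(s) desk_phantom(seed = s, n_frames = 2,
                                             grid = c(16, 16, 4),
                                             vessel = vessel_straight(radius_mm = 6)))
  cfg <- cnn_tiny_config(crop_xy = c(16, 16), epochs = 2, seed = 3)
  m <- train_unet(build_unet(cfg), ph, cfg)
  expect_equal(nrow(m$record), 2)
  expect_true(all(is.finite(m$record$ce)))
  expect_true(all(is.finite(m$record$dice_loss)))
  expect_error(train_unet(build_unet(cfg), list(), cfg), "empty training set")
})

test_that("training is reproducible and actually learns the task", {
  ph <- lapply(1:2, function(s) desk_phantom(seed = s, n_frames = 4,
                                             grid = c(32, 24, 12),
                                             vessel = vessel_ubend(radius_mm = 6,
                                                                   bend_radius_mm = 10)))
  cfg <- cnn_tiny_config(crop_xy = c(32, 24), epochs = 6, seed = 5)
  m1 <- train_unet(build_unet(cfg), ph, cfg)
  expect_gt(tail(m1$record$train_dice, 1), m1$record$train_dice[1])

  m2 <- train_unet(build_unet(cfg), ph, cfg)
  expect_identical(flowunwrap:::.unet_get_weights(m1$ptr),
                   flowunwrap:::.unet_get_weights(m2$ptr))
  expect_equal(m1$record$ce, m2$record$ce)

  # normalization invariance: scaling field and venc together changes nothing
  hold <- desk_phantom(seed = 9, n_frames = 2, grid = c(32, 24, 12),
                       vessel = vessel_ubend(radius_mm = 6, bend_radius_mm = 10))
  w <- wrap_velocity(hold$field, wrap_spec(venc_fraction = 0.5, venc = 150))
  pred <- predict_unet(m1, w$aliased)
  scaled <- w$aliased
  scaled$values <- scaled$values * 3.7
  scaled$venc <- scaled$venc * 3.7
  expect_identical(predict_unet(m1, scaled), pred)

  # checkpoint round trip reproduces predictions exactly
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m1, ck)
  m3 <- load_checkpoint(ck)
  expect_identical(predict_unet(m3, w$aliased), pred)
})

test_that("mask-guided correction from CNN output reduces velocity error", {
  ph <- lapply(1:2, function(s) desk_phantom(seed = s, snr = Inf, n_frames = 4,
                                             grid = c(32, 24, 12),
                                             vessel = vessel_ubend(radius_mm = 6,
                                                                   bend_radius_mm = 10)))
  cfg <- cnn_tiny_config(crop_xy = c(32, 24), epochs = 8, seed = 6)
  m <- train_unet(build_unet(cfg), ph, cfg)
  hold <- desk_phantom(seed = 31, snr = Inf, n_frames = 4, grid = c(32, 24, 12),
                       vessel = vessel_ubend(radius_mm = 6, bend_radius_mm = 10))
  w <- wrap_velocity(hold$field, wrap_spec(venc_fraction = 0.5, venc = 150))
  pred <- predict_unet(m, w$aliased)
  corr <- unwrap_with_mask(w$aliased, pred)
  err_aliased <- mean(abs(w$aliased$values - hold$field$values))
  err_corr <- mean(abs(corr$values - hold$field$values))
  expect_lt(err_corr, err_aliased)
})
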