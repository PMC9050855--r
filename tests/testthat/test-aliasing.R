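test_that("single-wrap values reproduce the venc-reduction rule", {
  # 1.0 m/s seen at venc_sim 0.6 m/s folds to 1.0 - 2*0.6 = -0.2 m/s
  f <- toy_field(array(c(100, 50), c(2, 1, 1, 1, 3)))
  w <- wrap_velocity(f, wrap_spec(venc_sim = 60, venc = 150))
  expect_equal(w$aliased$values[1, 1, 1, 1, 1], -20)
  expect_true(w$truth[1, 1, 1, 1, 1])
  # below venc_sim: identity, unmasked
  expect_equal(w$aliased$values[2, 1, 1, 1, 1], 50)
  expect_false(w$truth[2, 1, 1, 1, 1])
  # venc metadata moves to venc_sim; the input is untouched
  expect_equal(w$aliased$venc, 60)
  expect_equal(f$venc, 150)
})

test_that("modular wrap agrees with a brute-force fold on a dense grid", {
  v <- 100
  x <- seq(-3 * v, 3 * v - 0.5, by = 0.5)
  oracle <- vapply(x, function(xi) {
    while (xi < -v) xi <- xi + 2 * v
    while (xi >= v) xi <- xi - 2 * v
    xi
  }, numeric(1))
  f <- toy_field(array(x, c(length(x), 1, 1, 1, 3)), venc = 400)
  w <- wrap_velocity(f, wrap_spec(venc_sim = v, venc = 400))
  expect_equal(as.vector(w$aliased$values[, 1, 1, 1, 1]), oracle)
  # half-open boundary: +venc wraps to -venc
  expect_equal(w$aliased$values[x == v, 1, 1, 1, 1], -v)
  expect_true(all(w$aliased$values >= -v & w$aliased$values < v))
})

test_that("mask-driven unwrap inverts the wrap", {
  f <- toy_field(array(-20, c(1, 1, 1, 1, 3)), venc = 60)
  m <- array(TRUE, dim(f$values))
  un <- unwrap_with_mask(f, m, venc = 60)
  expect_equal(un$values[1], 100)
  # empty mask: identity
  un2 <- unwrap_with_mask(f, array(FALSE, dim(f$values)))
  expect_identical(un2$values, f$values)
  # shape mismatch
  expect_error(unwrap_with_mask(f, array(TRUE, c(2, 1, 1, 1, 3))),
               "shape mismatch")
})

test_that("wrap then mask-driven unwrap restores noise-free phantoms bit-exactly", {
  for (seed in 1:5) {
    ph <- desk_phantom(seed = seed, snr = Inf, n_frames = 4,
                       grid = c(32, 24, 12),
                       vessel = vessel_ubend(radius_mm = 6, bend_radius_mm = 10))
    frac <- c(0.5, 0.55, 0.65)[(seed %% 3) + 1]
    sp <- wrap_spec(venc_fraction = frac, venc = ph$field$venc)
    w <- wrap_velocity(ph$field, sp)
    # sign-based single-shift correction is invertible up to 2 * venc_sim
    expect_true(all(abs(ph$field$values) <= 2 * sp$venc_sim))
    un <- unwrap_with_mask(w$aliased, w$truth, venc = sp$venc_sim)
    expect_identical(un$values, ph$field$values)
    # ground truth equals the threshold oracle on noise-free data
    expect_identical(w$truth, abs(ph$field$values) >= sp$venc_sim)
  }
})

test_that("lowering venc_sim only grows the truth mask", {
  ph <- desk_phantom(seed = 3, snr = Inf, n_frames = 4, grid = c(32, 24, 12),
                     vessel = vessel_ubend(radius_mm = 6, bend_radius_mm = 10))
  masks <- lapply(c(0.7, 0.6, 0.5, 0.4), function(fr)
    wrap_velocity(ph$field, wrap_spec(venc_fraction = fr, venc = 150))$truth)
  for (i in 1:3)
    expect_true(all(masks[[i + 1]][masks[[i]]])) # superset
})

test_that("wrap specification is validated", {
  expect_error(wrap_spec(venc_sim = 150, venc = 150), "smaller")
  expect_error(wrap_spec(venc_sim = 200, venc = 150), "smaller")
  expect_error(wrap_spec(venc = 150), "venc_sim")
  f <- toy_field(array(0, c(1, 1, 1, 1, 3)), venc = 100)
  expect_error(wrap_velocity(f, wrap_spec(venc_sim = 120, venc = 150)),
               "smaller")
  # printed worked examples: reduced vencs as fractions of a 1.5 m/s scan
  expect_equal(round(100 * wrap_spec(venc_sim = 62, venc = 150)$fraction), 41)
  expect_equal(round(100 * wrap_spec(venc_sim = 79, venc = 150)$fraction), 53)
})

test_that("training venc fractions are uniform on the configured range", {
  set.seed(42)
  fr <- sample_venc_fraction(2000)
  expect_true(all(fr >= 0.40 & fr <= 0.70))
  expect_equal(mean(fr), 0.55, tolerance = 0.02)
  set.seed(7); a <- sample_venc_fraction(5)
  set.seed(7); b <- sample_venc_fraction(5)
  expect_identical(a, b)
})
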