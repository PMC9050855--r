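test_that("uniform axial flow gives the textbook plane flow numbers", {
  # 100 cm/s through a 4 cm^2 ROI, constant in time over a 1 s cycle:
  # Q = 1000 mm/s * 400 mm^2 = 400 ml/s each frame, net flow 400 ml
  dims <- c(8, 8, 4); sp <- c(5, 5, 5)  # voxel face 25 mm^2
  vessel <- array(FALSE, dims); vessel[3:6, 3:6, ] <- TRUE  # 16 vox = 4 cm^2
  vals <- array(0, c(dims, 4, 3))
  vals[, , , , 3] <- 100
  f <- velocity_field(vals, 150, sp, frame_interval = 250)
  pl <- analysis_plane(c(20, 20, 7.5), c(0, 0, 1))
  fr <- plane_flow(f, pl, vessel)
  expect_equal(fr$series_mls, rep(400, 4))
  expect_equal(fr$net_flow_ml, 400)
  expect_equal(fr$peak_flow_mls, 400)
  expect_equal(fr$peak_velocity_ms, 1.0)
})

test_that("all-zero fields report zero flow", {
  dims <- c(6, 6, 4)
  vessel <- array(TRUE, dims)
  f <- velocity_field(array(0, c(dims, 3, 3)), 150, c(2, 2, 2), 100)
  fr <- plane_flow(f, analysis_plane(c(6, 6, 3), c(0, 0, 1)), vessel)
  expect_equal(fr$net_flow_ml, 0)
  expect_equal(fr$peak_flow_mls, 0)
  expect_equal(fr$peak_velocity_ms, 0)
})

test_that("poiseuille net flow matches the analytic integral within 5%", {
  ph <- tube_phantom(snr = Inf, grid = c(33, 33, 10), spacing = c(1.5, 1.5, 2),
                     radius = 15, n_frames = 6)
  pl <- phantom_planes(ph)$mid
  fr <- plane_flow(ph$field, pl, ph$vessel)
  # Q(t) = pi R^2 vmax w_t / 2; R = 15 mm, vmax = 1500 mm/s
  q_frames <- pi * 15^2 * (150 * 10) * ph$waveform / 2 / 1000  # ml/s
  net_analytic <- sum(q_frames) * ph$field$frame_interval / 1000
  expect_equal(fr$net_flow_ml, net_analytic, tolerance = 0.05)
  expect_equal(fr$peak_flow_mls, max(q_frames), tolerance = 0.05)
})

test_that("flow scales linearly with velocity", {
  ph <- tube_phantom(snr = Inf, grid = c(17, 17, 8), radius = 8,
                     spacing = c(2, 2, 2), n_frames = 4)
  pl <- phantom_planes(ph)$mid
  f1 <- plane_flow(ph$field, pl, ph$vessel)
  f2 <- ph$field; f2$values <- f2$values * 2.5
  fr2 <- plane_flow(f2, pl, ph$vessel)
  expect_equal(fr2$net_flow_ml, 2.5 * f1$net_flow_ml)
  expect_equal(fr2$peak_flow_mls, 2.5 * f1$peak_flow_mls)
})

test_that("degenerate planes are rejected", {
  ph <- tube_phantom(snr = Inf, grid = c(17, 17, 8), radius = 8,
                     spacing = c(2, 2, 2), n_frames = 4)
  expect_error(plane_flow(ph$field, analysis_plane(c(1e4, 0, 0), c(0, 0, 1)),
                          ph$vessel), "intersect|ROI")
  expect_error(analysis_plane(c(0, 0, 0), c(0, 0, 0)), "non-zero")
})

test_that("dual-venc truth thresholds the paired difference", {
  dims <- c(2, 1, 1, 1, 3)
  hi <- toy_field(array(c(150, 10), dims), venc = 175)
  lo <- toy_field(array(c(-50, 10), dims), venc = 100)
  m <- dual_venc_truth(lo, hi)
  expect_true(m[1, 1, 1, 1, 1])    # |150 - (-50)| = 200 > 100
  expect_false(m[2, 1, 1, 1, 1])
  # identical velocity values: empty mask
  expect_false(any(dual_venc_truth(toy_field(hi$values, venc = 100), hi)))
  expect_error(dual_venc_truth(hi, lo), "smaller venc")
})

test_that("dual-venc truth equals the wrap simulator ground truth", {
  for (seed in 1:3) {
    ph <- desk_phantom(seed = seed, snr = Inf, n_frames = 4,
                       grid = c(32, 24, 12),
                       vessel = vessel_ubend(radius_mm = 6, bend_radius_mm = 10))
    w <- wrap_velocity(ph$field, wrap_spec(venc_fraction = 0.55, venc = 150))
    m <- dual_venc_truth(w$aliased, ph$field)
    expect_identical(m, w$truth)
  }
})

test_that("bland-altman reproduces the defining formulas", {
  ba0 <- bland_altman(c(10, 12, 9, 14), c(10, 12, 9, 14))
  expect_equal(ba0$bias, 0); expect_equal(ba0$loa, 0)
  expect_equal(ba0$loa_percent, 0)

  ba1 <- bland_altman(rep(10, 4), rep(11, 4))
  expect_equal(ba1$bias, 1); expect_equal(ba1$loa, 0)
  expect_equal(ba1$loa_percent, 0)

  set.seed(11)
  ref <- rnorm(2000, mean = 100, sd = 3)
  tst <- ref + rnorm(2000, sd = 5)
  ba <- bland_altman(ref, tst)
  expect_equal(ba$loa, 1.96 * sd(tst - ref), tolerance = 1e-12)
  expect_equal(ba$loa_percent, 100 * ba$loa / mean(ref), tolerance = 1e-12)
  expect_equal(ba$loa, 9.8, tolerance = 0.05)

  expect_warning(baz <- bland_altman(c(-1, 1), c(0, 0)), "undefined")
  expect_true(is.na(baz$loa_percent))
  expect_error(bland_altman(1:3, 1:4), "equal-length")
})

test_that("correcting a wrapped field restores the plane flow", {
  ph <- tube_phantom(snr = Inf, grid = c(33, 33, 10), spacing = c(1.5, 1.5, 2),
                     radius = 15, n_frames = 6)
  pl <- phantom_planes(ph)$mid
  truth_net <- plane_flow(ph$field, pl, ph$vessel)$net_flow_ml
  w <- wrap_velocity(ph$field, wrap_spec(venc_fraction = 0.5, venc = 150))
  aliased_net <- plane_flow(w$aliased, pl, ph$vessel)$net_flow_ml
  corr <- unwrap_with_mask(w$aliased, w$truth)
  corr_net <- plane_flow(corr, pl, ph$vessel)$net_flow_ml
  expect_lt(abs(corr_net - truth_net), abs(aliased_net - truth_net))
  expect_equal(corr_net, truth_net)
})
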