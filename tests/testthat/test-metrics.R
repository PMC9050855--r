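test_that("dice matches enumerated toy masks and the epsilon convention", {
  X <- array(FALSE, c(3, 3, 1)); Y <- X
  X[c(1, 2, 3)] <- TRUE; Y[c(2, 3, 4, 5)] <- TRUE  # |X|=3 |Y|=4 |X&Y|=2
  expect_equal(dice_score(X, Y), (4 + 1e-5) / (7 + 1e-5), tolerance = 1e-12)
  expect_equal(dice_score(X, X), 1.0, tolerance = 1e-6)
  # both empty: 1 via the stabilizing constant
  E <- array(FALSE, c(3, 3, 1))
  expect_equal(dice_score(E, E), 1.0)
  # one empty: near 0
  expect_lt(dice_score(E, Y), 1e-4)
  # symmetry
  expect_equal(dice_score(X, Y), dice_score(Y, X))
  expect_error(dice_score(X, array(FALSE, c(4, 3, 1))), "shape mismatch")
})

test_that("dice and counts ignore everything outside the vessel mask", {
  set.seed(1)
  dims <- c(8, 8, 4)
  X <- random_mask(dims, 0.2); Y <- random_mask(dims, 0.2)
  vessel <- array(FALSE, dims); vessel[3:6, 3:6, ] <- TRUE
  base <- dice_score(X, Y, vessel)
  X2 <- X; X2[!vessel] <- !X[!vessel]  # scramble outside
  expect_equal(dice_score(X2, Y, vessel), base)
  # in-vessel count on a toy: 5 inside, 2 outside
  m <- array(FALSE, c(4, 4, 1)); v <- array(FALSE, c(4, 4, 1))
  v[1:3, 1:3, 1] <- TRUE
  m[c(1, 2, 5, 6, 9)] <- TRUE   # all inside vessel columns 1..3
  m[c(13, 16)] <- TRUE          # outside
  expect_equal(count_aliased(m, v), 5)
  expect_equal(count_aliased(array(FALSE, c(4, 4, 1)), v), 0)
  # full mask counts |vessel| x frames x directions
  dims5 <- c(4, 4, 1, 3, 3)
  expect_equal(count_aliased(array(TRUE, dims5), v), sum(v) * 9)
})

test_that("hausdorff equals hand values and the brute-force oracle", {
  dims <- c(10, 9, 8); sp <- c(2, 2, 2)
  X <- array(FALSE, dims); X[2, 3, 4] <- TRUE
  expect_equal(hausdorff_mm(X, X, sp), 0)
  Y <- array(FALSE, dims); Y[5, 3, 4] <- TRUE  # offset (3,0,0) * 2 mm
  expect_equal(hausdorff_mm(X, Y, sp), 6)
  set.seed(33)
  for (rep in 1:25) {
    A <- random_mask(dims, 0.05); B <- random_mask(dims, 0.05)
    if (!any(A) || !any(B)) next
    fast <- hausdorff_mm(A, B, sp)
    expect_equal(fast, brute_hausdorff(A, B, sp), tolerance = 1e-10)
    expect_equal(hausdorff_mm(A, B, sp, method = "brute"), fast,
                 tolerance = 1e-10)
  }
})

test_that("vessel restriction shields hausdorff from outside modifications", {
  set.seed(9)
  dims <- c(10, 10, 4); sp <- c(1.5, 1.5, 3)
  vessel <- array(FALSE, dims); vessel[3:8, 3:8, ] <- TRUE
  A <- random_mask(dims, 0.08) & vessel
  B <- random_mask(dims, 0.08) & vessel
  expect_true(any(A) && any(B))
  d0 <- hausdorff_mm(A, B, sp, restrict = vessel)
  A2 <- A; A2[1, 1, 1] <- TRUE; A2[10, 10, 4] <- TRUE
  expect_equal(hausdorff_mm(A2, B, sp, restrict = vessel), d0)
})

test_that("empty masks make the hausdorff distance an explicit error", {
  dims <- c(6, 6, 2)
  E <- array(FALSE, dims); Y <- array(FALSE, dims); Y[8] <- TRUE
  expect_error(hausdorff_mm(E, Y, c(1, 1, 1)), "undefined")
  expect_error(hausdorff_mm(E, E, c(1, 1, 1)), "undefined")
})

test_that("5-D masks aggregate hausdorff per volume with the max reported", {
  dims <- c(8, 8, 4, 2, 3)
  X <- array(FALSE, dims); Y <- array(FALSE, dims)
  X[2, 2, 1, 1, 1] <- TRUE; Y[2, 2, 1, 1, 1] <- TRUE        # identical -> 0
  X[2, 2, 1, 2, 2] <- TRUE; Y[6, 2, 1, 2, 2] <- TRUE        # 4 voxels in x
  res <- hausdorff_mm(X, Y, c(2, 1, 1))
  expect_equal(res$max_mm, 8)
  expect_equal(sum(!is.na(res$per_volume$hausdorff_mm)), 2)
  # a half-empty volume is NA with a warning, not silently 0
  X[2, 2, 1, 1, 3] <- TRUE
  expect_warning(res2 <- hausdorff_mm(X, Y, c(2, 1, 1)), "undefined")
  expect_equal(res2$max_mm, 8)
})
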