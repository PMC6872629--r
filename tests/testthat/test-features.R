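test_that("downsample_field computes exact block means", {
  # 6x6 field, left half (1,0), right half (0,1), cell 3 -> hand-computed 2x2
  ur <- cbind(matrix(1, 6, 3), matrix(0, 6, 3))
  uc <- cbind(matrix(0, 6, 3), matrix(1, 6, 3))
  f <- deformation_field(ur, uc)
  d <- downsample_field(f, 3)
  expect_equal(dim(d), c(2L, 2L))
  expect_equal(d$u_row, matrix(c(1, 1, 0, 0), 2, 2))
  expect_equal(d$u_col, matrix(c(0, 0, 1, 1), 2, 2))
  expect_equal(d$cell_size, 3)
  # constant field stays constant at any rate, including fractional
  cf <- deformation_field(matrix(0.7, 9, 9), matrix(-0.2, 9, 9))
  for (cell in c(2, 3.75, 5)) {
    dc <- downsample_field(cf, cell)
    expect_true(all(abs(dc$u_row - 0.7) < 1e-12))
    expect_true(all(abs(dc$u_col + 0.2) < 1e-12))
  }
  # cell 1 is the identity
  expect_identical(downsample_field(f, 1), f)
  expect_error(downsample_field(f, 0.5), "cell")
})

test_that("downsampling conserves the area-weighted mean vector", {
  for (seed in 1:5) {
    f <- toy_field(25, amp = 2, seed = seed)
    for (cell in c(2, 3.75, 5)) {
      d <- downsample_field(f, cell)
      ar <- dbmorph:::.cell_overlap_weights(25, cell, ceiling(25 / cell))$area
      w <- outer(ar, ar)
      expect_equal(sum(d$u_row * w) / sum(w), mean(f$u_row), tolerance = 1e-9)
      expect_equal(sum(d$u_col * w) / sum(w), mean(f$u_col), tolerance = 1e-9)
    }
  }
})

test_that("polar conversion follows the stated conventions", {
  f <- deformation_field(matrix(c(3, 0, -1), 1, 3), matrix(c(4, 0, 0), 1, 3))
  p <- field_to_polar(f)
  expect_equal(p$magnitude[1, 1], 5)
  expect_equal(p$direction[1, 1], atan2(3, 4))
  expect_equal(p$magnitude[1, 2], 0)
  expect_equal(p$direction[1, 2], 0)          # zero vector -> (0, 0)
  expect_equal(p$direction[1, 3], atan2(-1, 0))
  # round trip on non-zero vectors
  set.seed(3)
  ur <- matrix(rnorm(64), 8, 8); uc <- matrix(rnorm(64), 8, 8)
  p2 <- field_to_polar(deformation_field(ur, uc))
  expect_equal(p2$magnitude * sin(p2$direction), ur, tolerance = 1e-12)
  expect_equal(p2$magnitude * cos(p2$direction), uc, tolerance = 1e-12)
})

test_that("jacobian determinant matches analytic fields", {
  n <- 12
  z <- zero_field(c(n, n))
  expect_true(all(abs(jacobian_determinant(z) - 1) < 1e-12))
  r0 <- matrix(rep(0:(n - 1), n), n, n)
  c0 <- matrix(rep(0:(n - 1), each = n), n, n)
  # uniform 1.1x expansion: detJ = 1.21 in the interior
  f <- deformation_field(0.1 * r0, 0.1 * c0)
  dj <- jacobian_determinant(f)
  expect_true(all(abs(dj[2:(n - 1), 2:(n - 1)] - 1.21) < 1e-9))
  # axis shrinkage: detJ = 0.5 < 1
  f2 <- deformation_field(-0.5 * r0, 0 * c0)
  dj2 <- jacobian_determinant(f2)
  expect_true(all(abs(dj2[2:(n - 1), 2:(n - 1)] - 0.5) < 1e-9))
  expect_error(jacobian_determinant(zero_field(c(2, 5))), "3x3")
})

test_that("jacobian of random affine fields equals det(A)", {
  n <- 10
  r0 <- matrix(rep(0:(n - 1), n), n, n)
  c0 <- matrix(rep(0:(n - 1), each = n), n, n)
  set.seed(42)
  for (i in 1:20) {
    A <- diag(2) + matrix(runif(4, -0.3, 0.3), 2, 2)
    f <- deformation_field((A[1, 1] - 1) * r0 + A[1, 2] * c0,
                           A[2, 1] * r0 + (A[2, 2] - 1) * c0)
    dj <- jacobian_determinant(f)
    expect_true(all(abs(dj[2:(n - 1), 2:(n - 1)] - det(A)) < 1e-6))
  }
})

test_that("feature matrices have the documented layout", {
  set.seed(1)
  fields <- lapply(1:10, function(i) toy_field(12, amp = 1, seed = i))
  labels <- rep(c("control", "diseased"), 5)
  fms <- build_feature_matrix(fields, labels, rates = 3,
                              channels = c("magnitude", "direction"))
  fm <- fms[["3"]]
  expect_equal(dim(fm$values), c(10L, 32L))      # 4x4 cells x 2 channels
  expect_equal(fm$descriptors$grid_row[1], 0)
  expect_equal(fm$descriptors$grid_col[1], 0)
  expect_equal(fm$descriptors$channel[1], "magnitude")
  expect_equal(fm$descriptors$channel[2], "direction")
  expect_equal(fm$descriptors$cell_size[1], 3)
  expect_equal(colnames(fm$values)[1], "r0c0_magnitude_s3")
  # adding the jacobian channel adds one column per cell
  fm3 <- build_feature_matrix(fields, labels, rates = 3,
                              channels = c("magnitude", "direction", "jacobian"))[["3"]]
  expect_equal(ncol(fm3$values), 48L)
  # descriptor values match direct per-field computation
  d5 <- downsample_field(fields[[5]], 3)
  p5 <- field_to_polar(d5)
  expect_equal(fm$values[5, "r1c2_magnitude_s3"], p5$magnitude[2, 3],
               ignore_attr = TRUE)
  expect_equal(fm$values[5, "r1c2_direction_s3"], p5$direction[2, 3],
               ignore_attr = TRUE)
  # grid mismatch rejected
  expect_error(build_feature_matrix(c(fields, list(toy_field(10))),
                                    c(labels, "control"), rates = 3),
               "share")
})

test_that("feature matrices round-trip through CSV + JSON", {
  fields <- lapply(1:4, function(i) toy_field(12, amp = 1, seed = i))
  fm <- build_feature_matrix(fields, rep(c("a", "b"), 2), rates = 3)[["3"]]
  base <- file.path(withr::local_tempdir(), "fm")
  write_feature_matrix(fm, base)
  fm2 <- read_feature_matrix(base)
  expect_equal(fm2$values, fm$values, ignore_attr = TRUE)
  expect_equal(fm2$labels, fm$labels)
  expect_equal(fm2$descriptors$channel, fm$descriptors$channel)
})
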