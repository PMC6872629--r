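test_that("warp_image honours the pull convention and edge clamping", {
  img <- toy_image(16)
  z <- zero_field(c(16, 16))
  expect_identical(warp_image(img, z)$pixels, img$pixels)
  # constant field (0, 1): content sampled one column to the right
  shift <- deformation_field(matrix(0, 16, 16), matrix(1, 16, 16))
  w <- warp_image(img, shift)$pixels
  expect_equal(w[, 1:15], img$pixels[, 2:16], tolerance = 1e-12)
  expect_equal(w[, 16], img$pixels[, 16], tolerance = 1e-12)  # clamped edge
  # grid mismatch rejected
  expect_error(warp_image(img, zero_field(c(8, 8))), "grid")
})

test_that("small smooth warps are approximately invertible", {
  img <- toy_image(48)
  f <- toy_field(48, amp = 1.5)
  neg <- deformation_field(-f$u_row, -f$u_col)
  back <- warp_image(warp_image(img, f), neg)
  expect_lt(mean(abs(back$pixels - img$pixels)), 0.02)
})

test_that("invert_field produces the inverse displacement", {
  f <- toy_field(32, amp = 1.2)
  fi <- invert_field(f)
  # x + v(x) + u(x + v(x)) == 0 at the fixed point
  res_r <- fi$u_row + dbmorph:::.warp_pull_cpp(f$u_row, fi$u_row, fi$u_col)
  res_c <- fi$u_col + dbmorph:::.warp_pull_cpp(f$u_col, fi$u_row, fi$u_col)
  expect_lt(max(abs(c(res_r, res_c))), 1e-6)
})

test_that("affine registration recovers translations and rotations", {
  spec <- phantom_spec(image_size = 96, n_control = 1, n_diseased = 1,
                       lesion_centers = c(40, 56), seed = 3)
  ref <- make_reference(spec)
  # identity
  res0 <- register_affine(ref, ref)
  expect_lt(max(abs(res0$transform$linear - diag(2))), 1e-3)
  expect_lt(max(abs(res0$transform$translation)), 1e-3)
  expect_lt(res0$mse_after, 1e-8)
  # content translated by (3, -2): recovered forward map ~ (-3, 2)
  q <- gray_image(dbmorph:::apply_affine(ref$pixels,
                                         affine_transform(diag(2), c(3, -2))))
  res <- register_affine(q, ref)
  expect_lt(max(abs(res$transform$translation - c(-3, 2))), 0.5)
  # content rotated 5 degrees: recovered rotation ~ -5 degrees
  th <- 5 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  q2 <- gray_image(dbmorph:::apply_affine(ref$pixels, affine_transform(R)))
  res2 <- register_affine(q2, ref)
  ang <- atan2(res2$transform$linear[2, 1], res2$transform$linear[1, 1]) * 180 / pi
  expect_lt(abs(ang - (-5)), 1)
  # never increases dissimilarity
  expect_lte(res$mse_after, res$mse_before)
  # degenerate input rejected
  flat <- gray_image(matrix(0.5, 32, 32))
  expect_error(register_affine(flat, flat), "zero-variance")
})

test_that("demons self-registration is near-identity and constant images give zero fields", {
  spec <- tiny_spec(seed = 5)
  ref <- make_reference(spec)
  f <- register_demons(ref, ref)
  expect_lt(max(field_magnitude(f)), 0.1)
  # flat images at different levels: gradient is zero everywhere -> zero field
  a <- gray_image(matrix(0.2, 32, 32))
  b <- gray_image(matrix(0.8, 32, 32))
  f2 <- register_demons(a, b)
  expect_true(all(f2$u_row == 0) && all(f2$u_col == 0))
  expect_error(register_demons(gray_image(matrix(0.5, 8, 8)),
                               gray_image(matrix(0.5, 9, 9))), "grid")
})

test_that("demons recovers known smooth warps within tolerance", {
  spec <- phantom_spec(image_size = 128, n_control = 2, n_diseased = 1,
                       global_jitter = c(0, 0), smooth_field_amplitude = 4,
                       lesion_amplitude = 0, lesion_centers = c(54, 74),
                       seed = 7)
  co <- generate_cohort(spec)
  mask <- co$reference$pixels > 0
  for (s in co$subjects[1:2]) {
    rec <- register_demons(s$image, co$reference)
    truth <- invert_field(s$field)
    epe <- sqrt((rec$u_row - truth$u_row)^2 + (rec$u_col - truth$u_col)^2)
    expect_lt(mean(epe[mask]), 0.25 * 4)
    expect_lte(attr(rec, "ssd_final"), attr(rec, "ssd_initial"))
  }
})

test_that("registration is deterministic", {
  spec <- tiny_spec(seed = 8)
  co <- generate_cohort(spec)
  s <- co$subjects[[4]]
  f1 <- register_demons(s$image, co$reference)
  f2 <- register_demons(s$image, co$reference)
  expect_identical(f1$u_row, f2$u_row)
  expect_identical(f1$u_col, f2$u_col)
})
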