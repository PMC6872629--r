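test_that("phantom spec validates its invariants", {
  expect_error(phantom_spec(image_size = 16), "image_size")
  expect_error(phantom_spec(n_control = 0), "counts")
  expect_error(phantom_spec(lesion_amplitude = -1), "non-negative")
  expect_error(phantom_spec(lesion_centers = c(5, 200)), "inside the image")
})

test_that("reference image is deterministic, bounded and textured", {
  spec <- phantom_spec(image_size = 128, seed = 5)
  ref1 <- make_reference(spec)
  ref2 <- make_reference(spec)
  expect_identical(ref1$pixels, ref2$pixels)
  expect_true(all(ref1$pixels >= 0 & ref1$pixels <= 1))
  obj_frac <- mean(ref1$pixels > 0)
  expect_gt(obj_frac, 0.2)
  expect_lt(obj_frac, 0.8)
  # background exactly zero outside the object mask
  expect_true(all(ref1$pixels[ref1$pixels <= 0] == 0))
  # non-trivial gradient over most of the object, so registration is well-posed
  gr <- abs(diff(ref1$pixels))
  inside <- ref1$pixels[-1, ] > 0 & ref1$pixels[-nrow(ref1$pixels), ] > 0
  expect_gt(mean(gr[inside] > 1e-3), 0.3)
})

test_that("identity-parameter subject reproduces the reference exactly", {
  spec <- phantom_spec(image_size = 64, n_control = 1, n_diseased = 1,
                       global_jitter = c(0, 0), smooth_field_amplitude = 0,
                       noise_sd = 0, lesion_amplitude = 0,
                       lesion_centers = c(27, 37), seed = 2)
  ref <- make_reference(spec)
  s <- make_subject(ref, "control", spec, 123)
  expect_equal(s$image$pixels, ref$pixels, tolerance = 1e-12)
  expect_true(all(s$field$u_row == 0) && all(s$field$u_col == 0))
})

test_that("lesion bump has the stated displacement profile", {
  spec <- phantom_spec(image_size = 96, n_control = 1, n_diseased = 1,
                       global_jitter = c(0, 0), smooth_field_amplitude = 0,
                       noise_sd = 0, lesion_amplitude = 3, lesion_radius = 8,
                       lesion_centers = c(48, 48), seed = 3)
  ref <- make_reference(spec)
  s <- make_subject(ref, "diseased", spec, 77)
  mag <- sqrt(s$field$u_row^2 + s$field$u_col^2)
  expect_gte(mag[49, 49], 2.5)           # peak at the center (0-based (48,48))
  far <- mag[49, 49 + 3 * 8 + 1]         # beyond three radii
  expect_lt(far, 0.5)
})

test_that("cohorts are reproducible and seed-sensitive", {
  spec <- tiny_spec(seed = 9)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  c3 <- generate_cohort(tiny_spec(seed = 10))
  labs <- vapply(c1$subjects, `[[`, "", "label")
  expect_equal(sum(labs == "control"), 3)
  expect_equal(sum(labs == "diseased"), 3)
  expect_identical(c1$subjects[[2]]$image$pixels, c2$subjects[[2]]$image$pixels)
  expect_false(identical(c1$subjects[[2]]$image$pixels,
                         c3$subjects[[2]]$image$pixels))
})

test_that("ground-truth field and warped image are consistent", {
  spec <- tiny_spec(seed = 4, noise_sd = 0.02)
  co <- generate_cohort(spec)
  for (s in co$subjects[c(1, 4)]) {
    w <- warp_image(co$reference, s$field)
    mae <- mean(abs(w$pixels - s$image$pixels))
    expect_lte(mae, spec$noise_sd + 0.02)
  }
})

test_that("lesion-free cohorts are label-blind", {
  fails <- 0
  for (seed in 1:5) {
    spec <- phantom_spec(image_size = 64, n_control = 20, n_diseased = 20,
                         lesion_amplitude = 0, lesion_centers = c(27, 37),
                         seed = seed)
    co <- generate_cohort(spec)
    d <- vapply(co$subjects, function(s)
      mean(abs(s$image$pixels - co$reference$pixels)), numeric(1))
    labs <- vapply(co$subjects, `[[`, "", "label")
    p <- wilcox.test(d[labs == "control"], d[labs == "diseased"])$p.value
    if (p <= 0.01) fails <- fails + 1
  }
  expect_lte(fails, 1)
})

test_that("cohort round-trips through the on-disk layout", {
  spec <- tiny_spec(seed = 6)
  co <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  man <- write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  man2 <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(man2$label, vapply(co$subjects, `[[`, "", "label"))
  img <- load_image(man2$path[1])
  expect_equal(dim(img$pixels), c(64L, 64L))
  # 16-bit TIFF quantization error only
  expect_lt(max(abs(img$pixels - co$subjects[[1]]$image$pixels)), 1 / 65535)
  f <- read_field(file.path(dir, "fields", co$subjects[[1]]$subject_id))
  expect_equal(f$u_row, co$subjects[[1]]$field$u_row, tolerance = 1e-9)
  expect_equal(f$convention, "generative")
})
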