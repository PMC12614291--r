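test_that("phantom slices are piecewise constant at the configured HU levels", {
  spec <- anatomy_spec()
  for (seed in c(1, 17, 303)) {
    ph <- generate_phantom_ct(c(32, 32), spec, seed = seed)
    expect_true(all(as.vector(ph$ct) %in%
                      c(spec$air_hu, spec$tissue_hu, spec$bone_hu)))
    expect_identical(attr(ph$ct, "units"), "HU")
  }
})

test_that("body area fraction stays in a plausible range across seeds", {
  fr <- vapply(1:60, function(s) {
    mean(generate_phantom_ct(c(32, 32), seed = s)$body_mask)
  }, numeric(1))
  expect_true(all(fr > 0.2 & fr < 0.8))
})

test_that("phantom generation is deterministic by seed and validates shape", {
  a <- generate_phantom_ct(c(32, 32), seed = 5)
  b <- generate_phantom_ct(c(32, 32), seed = 5)
  expect_identical(a, b)
  expect_error(generate_phantom_ct(c(16, 16)), "32 x 32")
})

test_that("an all-identity degradation spec returns the input unchanged", {
  ph <- generate_phantom_ct(c(32, 32), seed = 2)
  spec <- degradation_spec(bias_amplitude = 0, streak_count = 0,
                           streak_intensity = 0, noise_sd = 0,
                           fov_radius_frac = 1, shift_px = c(0, 0),
                           contour_scale = 1)
  out <- degrade_to_cbct(ph$ct, spec, seed = 1)
  expect_equal(unclass(out), unclass(ph$ct), ignore_attr = TRUE)
})

test_that("bias-only degradation shifts the body by the known radial field", {
  ph <- generate_phantom_ct(c(32, 32), seed = 9)
  spec <- degradation_spec(bias_amplitude = 80, streak_count = 0,
                           streak_intensity = 0, noise_sd = 0,
                           fov_radius_frac = 1, shift_px = c(0, 0),
                           contour_scale = 1)
  cbct <- degrade_to_cbct(ph$ct, spec, seed = 1)
  nonair <- ph$body_mask & ph$ct > -999
  field <- radial_bias_field(c(32, 32), 80)
  expect_lt(abs(mean((cbct - ph$ct)[nonair]) - mean(field[nonair])), 1)
  # exact invertibility of the noise-free bias
  expect_equal(unclass(cbct)[nonair] - field[nonair],
               unclass(ph$ct)[nonair], ignore_attr = TRUE)
})

test_that("noise-only degradation has the configured in-body HU spread", {
  ph <- generate_phantom_ct(c(64, 64), seed = 12)
  spec <- degradation_spec(bias_amplitude = 0, streak_count = 0,
                           streak_intensity = 0, noise_sd = 30,
                           fov_radius_frac = 1, shift_px = c(0, 0),
                           contour_scale = 1)
  cbct <- degrade_to_cbct(ph$ct, spec, seed = 3)
  # away from the clip boundary the residual is exactly the Gaussian field
  inner <- ph$body_mask & ph$ct == 40
  resid <- (cbct - ph$ct)[inner]
  expect_gt(sum(inner), 500)
  expect_lt(abs(sd(resid) - 30), 30 * 3 / sqrt(2 * sum(inner) - 2) + 1)
  expect_lt(abs(mean(resid)), 5 * 30 / sqrt(sum(inner)))
})

test_that("degradations respect the FOV: outside pixels become air", {
  ph <- generate_phantom_ct(c(32, 32), seed = 21)
  spec <- degradation_spec(fov_radius_frac = 0.6)
  cbct <- degrade_to_cbct(ph$ct, spec, seed = 2)
  expect_true(all(cbct[!fov_mask(c(32, 32), 0.6)] == -1000))
  expect_true(all(cbct >= -1000 & cbct <= 3000))
})

test_that("paired datasets are reproducible and carry their invariants", {
  ds1 <- make_pair_dataset(5, seed = 100)
  ds2 <- make_pair_dataset(5, seed = 100)
  expect_identical(ds1, ds2)
  expect_length(ds1, 5)
  for (p in ds1) {
    expect_identical(dim(p$pct), dim(p$cbct))
    expect_true(all(p$pct >= -1000 & p$pct <= 3000))
    expect_true(all(p$cbct >= -1000 & p$cbct <= 3000))
    expect_identical(p$unit_tag, "HU")
    expect_type(p$seed_anatomy, "integer")
  }
  # distinct anatomy seeds -> distinct pairs
  expect_gt(length(unique(vapply(ds1, function(p) p$seed_anatomy,
                                 integer(1)))), 1)
})

test_that("preprocessing maps the clip window affinely onto [-1, 1]", {
  expect_equal(as.numeric(preprocess(-1000)), -1)
  expect_equal(as.numeric(preprocess(3000)), 1)
  expect_equal(as.numeric(preprocess(1000)), 0)
  expect_equal(as.numeric(preprocess(5000)), 1) # clipped first
  expect_equal(as.numeric(preprocess(-2000)), -1)
  img <- matrix(c(-1500, 0, 40, 4000), 2, 2)
  expect_identical(attr(preprocess(img), "units"), "normalized")
})

test_that("to_hu inverts preprocess on the clip window and guards its domain", {
  expect_equal(as.numeric(to_hu(0)), 1000)
  expect_equal(as.numeric(to_hu(-1)), -1000)
  x <- matrix(seq(-1500, 3500, length.out = 64), 8, 8)
  expect_equal(unclass(to_hu(preprocess(x))), pmin(pmax(x, -1000), 3000),
               ignore_attr = TRUE)
  expect_error(to_hu(1.5), "\\[-1, 1\\]")
})

test_that("preprocess on a paired sample converts both images and the unit tag", {
  p <- make_pair_dataset(1, seed = 4)[[1]]
  pn <- preprocess(p)
  expect_identical(pn$unit_tag, "normalized")
  expect_true(all(pn$pct >= -1 & pn$pct <= 1))
  expect_true(all(pn$cbct >= -1 & pn$cbct <= 1))
})

test_that("fov_mask geometry: edge contact, area convergence, validation", {
  m <- fov_mask(c(33, 33), 1)
  expect_true(m[17, 1] && m[17, 33] && m[1, 17] && m[33, 17]) # edge midpoints
  expect_false(m[1, 1]) # corners excluded
  big <- fov_mask(c(256, 256), 1)
  expect_lt(abs(sum(big) / (pi * 128^2) - 1), 0.02)
  expect_error(fov_mask(c(32, 32), 0), "radius_frac")
  expect_error(fov_mask(c(32, 32), 1.2), "radius_frac")
  # small-FOV mask sits inside the default phantom body
  ph <- generate_phantom_ct(c(64, 64), seed = 30)
  expect_true(all(ph$body_mask[fov_mask(c(64, 64), 0.4)]))
})

test_that("resample_and_crop handles identity, constants and center cropping", {
  vol <- array(stats::rnorm(20 * 20 * 3), c(20, 20, 3))
  out <- resample_and_crop(vol, c(1, 1, 3), c(1, 1, 3), crop_size = c(20, 20))
  expect_equal(out$volume, vol)

  const <- array(40, c(16, 16, 2))
  up <- resample_and_crop(const, c(2, 2, 3), c(1, 1, 3), crop_size = c(31, 31))
  expect_true(all(abs(up$volume - 40) < 1e-12))

  big <- array(seq_len(30 * 30), c(30, 30, 1))
  crop <- resample_and_crop(big, c(1, 1, 3), c(1, 1, 3), crop_size = c(26, 26))
  expect_equal(crop$volume[, , 1], big[3:28, 3:28, 1])

  small <- array(0, c(10, 10, 1))
  pad <- resample_and_crop(small, c(1, 1, 3), c(1, 1, 3), crop_size = c(16, 16))
  expect_equal(pad$volume[1, 1, 1], -1000) # padded with air
  expect_error(resample_and_crop(vol, NULL), "spacing")
  expect_error(resample_and_crop(matrix(0, 3, 3), c(1, 1, 1)), "3D")
})
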