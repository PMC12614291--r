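hu <- function(m) {
  attr(m, "units") <- "HU"
  m
}

test_that("masked MAE matches hand-computed values", {
  full <- matrix(TRUE, 1, 2)
  a <- hu(matrix(c(0, 100), 1, 2))
  b <- hu(matrix(c(10, 80), 1, 2))
  expect_equal(masked_mae(a, b, full), 15)
  expect_equal(masked_mae(a, a, full), 0)
  c50 <- hu(matrix(50, 4, 4))
  z <- hu(matrix(0, 4, 4))
  expect_equal(masked_mae(c50, z, matrix(TRUE, 4, 4)), 50)
})

test_that("masked PSNR follows its closed form with the fixed 4000 HU range", {
  m <- matrix(TRUE, 4, 4)
  a <- hu(matrix(40, 4, 4)); z <- hu(matrix(0, 4, 4))
  expect_equal(masked_psnr(a, z, m), 20 * log10(4000 / 40))
  expect_equal(masked_psnr(a, z, m), 40)
  # halving a constant error adds 20*log10(2) dB
  a2 <- hu(matrix(20, 4, 4))
  expect_equal(masked_psnr(a2, z, m) - masked_psnr(a, z, m), 20 * log10(2))
  expect_equal(masked_psnr(z, z, m), 100) # zero-MSE cap
})

test_that("masked NCC is affine invariant and bounded", {
  m <- matrix(TRUE, 5, 5)
  set.seed(8)
  a <- matrix(rnorm(25), 5, 5)
  expect_equal(masked_ncc(a, a, m), 1)
  expect_equal(masked_ncc(a, -a, m), -1)
  expect_equal(masked_ncc(a, 3.7 * a + 12, m), 1)
  b <- matrix(rnorm(25), 5, 5)
  expect_true(abs(masked_ncc(a, b, m)) <= 1)
  expect_error(masked_ncc(a, matrix(1, 5, 5), m), "constant")
})

test_that("metrics are symmetric and strictly mask-local", {
  set.seed(9)
  a <- hu(matrix(rnorm(64, 0, 100), 8, 8))
  b <- hu(matrix(rnorm(64, 0, 100), 8, 8))
  m <- fov_mask(c(8, 8), 0.8)
  expect_equal(masked_mae(a, b, m), masked_mae(b, a, m))
  expect_equal(masked_psnr(a, b, m), masked_psnr(b, a, m))
  expect_equal(masked_ncc(a, b, m), masked_ncc(b, a, m))
  # changing out-of-mask pixels changes nothing
  a2 <- a
  a2[!m] <- a2[!m] + 5000
  a2 <- hu(pmin(a2, 3000))
  expect_equal(masked_mae(a2, b, m), masked_mae(a, b, m))
  expect_equal(masked_psnr(a2, b, m), masked_psnr(a, b, m))
  expect_equal(masked_ncc(a2, b, m), masked_ncc(a, b, m))
})

test_that("HU metrics refuse normalized inputs and empty masks", {
  a <- norm_img(matrix(0.5, 4, 4))
  b <- hu(matrix(0, 4, 4))
  m <- matrix(TRUE, 4, 4)
  expect_error(masked_mae(a, b, m), "normalized")
  expect_error(masked_psnr(b, a, m), "normalized")
  expect_error(masked_mae(b, b, matrix(FALSE, 4, 4)), "empty")
  expect_error(masked_mae(b, hu(matrix(0, 2, 2)), m), "shape")
})

test_that("difference maps are antisymmetric and unmasked", {
  a <- hu(matrix(1:9, 3, 3)); b <- hu(matrix(9:1, 3, 3))
  expect_equal(unclass(hu_difference_map(a, b)),
               -unclass(hu_difference_map(b, a)), ignore_attr = TRUE)
  expect_true(all(hu_difference_map(a, a) == 0))
  expect_true(all(hu_difference_map(a + 7, a) == 7))
})

test_that("truncated HU histograms exclude air and conserve counts", {
  air <- hu(matrix(-1000, 8, 8))
  h <- hu_histogram(air, bin_width = 50, lower_trunc = -950)
  expect_equal(sum(h$count), 0)
  tissue <- hu(matrix(40, 8, 8))
  h2 <- hu_histogram(tissue, bin_width = 50)
  expect_equal(sum(h2$count), 64)
  expect_equal(sum(h2$count > 0), 1)
  mix <- hu(matrix(c(rep(-1000, 10), rep(40, 30), rep(1000, 24)), 8, 8))
  h3 <- hu_histogram(mix, bin_width = 10)
  expect_equal(sum(h3$count), 54) # air excluded
  expect_error(hu_histogram(tissue, bin_width = 0), "bin_width")
})

test_that("shared-noise latent convergence follows the sqrt(alpha_bar) law", {
  x0 <- rand_norm_image(c(16, 16), 1)
  y0 <- rand_norm_image(c(16, 16), 2)
  for (kind in c("linear", "cosine", "sigmoid")) {
    s <- make_schedule(kind, 1000)
    curve <- latent_convergence_curve(x0, y0, s, timesteps = c(0, 250, 500,
                                                               750, 1000),
                                      seed = 3)
    d0 <- sqrt(sum((x0 - y0)^2))
    expect_equal(curve$euclidean_distance,
                 sqrt(curve$alpha_bar) * d0, tolerance = 1e-6)
  }
  # identical inputs: similarity 1, distance 0 everywhere
  same <- latent_convergence_curve(x0, x0, make_schedule("linear", 100),
                                   timesteps = c(0, 50, 100), seed = 4)
  expect_equal(same$cosine_similarity, rep(1, 3))
  expect_equal(same$euclidean_distance, rep(0, 3))
})

test_that("evaluate_pairs aggregates per-slice metrics faithfully", {
  ds <- make_pair_dataset(4, seed = 55)
  mask <- fov_mask(c(32, 32), 0.9)
  pct <- lapply(ds, function(p) p$pct)
  cbct <- lapply(ds, function(p) p$cbct)
  ev <- evaluate_pairs(pct, pct, cbct, mask) # sCT == pCT
  sct_rows <- ev$per_slice[ev$per_slice$image == "sCT", ]
  expect_true(all(sct_rows$mae_hu == 0))
  expect_true(all(sct_rows$psnr_db == 100))
  expect_true(all(sct_rows$ncc == 1))
  cb <- ev$summary[ev$summary$image == "CBCT", ]
  cb_rows <- ev$per_slice[ev$per_slice$image == "CBCT", ]
  expect_equal(cb$mae_hu, mean(cb_rows$mae_hu))
  expect_equal(cb$mae_hu_sd, sd(cb_rows$mae_hu))
  expect_error(evaluate_pairs(pct[1:2], pct, cbct, mask), "equal length")
})
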