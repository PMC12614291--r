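test_that("one-shot forward diffusion honours its boundary cases", {
  s <- make_schedule("linear", 100)
  x0 <- rand_norm_image(c(8, 8), 1)
  eps <- matrix(stats::rnorm(64), 8, 8)
  expect_equal(unclass(forward_diffuse(x0, 0, eps, s)), unclass(x0),
               ignore_attr = TRUE)
  expect_equal(unclass(forward_diffuse(x0, 40, 0 * eps, s)),
               sqrt(alpha_bar_at(s, 40)) * unclass(x0), ignore_attr = TRUE)
  expect_equal(unclass(forward_diffuse(0 * x0, 40, eps, s)),
               sqrt(1 - alpha_bar_at(s, 40)) * eps, ignore_attr = TRUE)
  expect_error(forward_diffuse(x0, 5, matrix(0, 4, 4), s), "shape")
})

test_that("a single Markov step has the prescribed mean and variance", {
  s <- make_schedule("linear", 10, beta_min = 0.05, beta_max = 0.3)
  x_prev <- matrix(0.8, 1, 1)
  draws <- vapply(1:10000, function(i) {
    as.numeric(forward_step(x_prev, 5, s))
  }, numeric(1))
  b <- s$beta[5]
  se_mean <- sqrt(b / 10000)
  expect_lt(abs(mean(draws) - sqrt(1 - b) * 0.8), 3 * se_mean)
  expect_lt(abs(sd(draws) - sqrt(b)), 3 * sqrt(b / (2 * 10000)))
  # tiny beta: output is essentially the input
  s2 <- make_schedule("linear", 10, beta_min = 1e-10, beta_max = 1e-9)
  expect_lt(max(abs(forward_step(x_prev, 1, s2, seed = 1) - x_prev)), 1e-4)
})

test_that("iterated Markov steps match one-shot diffusion in distribution", {
  # Monte-Carlo equivalence of the step-by-step process and its closed form,
  # checked on an 8x8 image via per-pixel means and variances
  s <- make_schedule("linear", 15, beta_min = 0.02, beta_max = 0.2)
  x0 <- rand_norm_image(c(8, 8), 3)
  n <- 1e4
  withr::with_seed(11, {
    iter_sum <- matrix(0, 8, 8); iter_sq <- matrix(0, 8, 8)
    for (i in seq_len(n)) {
      x <- x0
      for (t in 1:15) x <- forward_step(x, t, s)
      iter_sum <- iter_sum + x
      iter_sq <- iter_sq + x^2
    }
  })
  m_iter <- iter_sum / n
  v_iter <- iter_sq / n - m_iter^2
  ab <- alpha_bar_at(s, 15)
  m_theory <- sqrt(ab) * unclass(x0)
  v_theory <- 1 - ab
  se_m <- sqrt(v_theory / n)
  expect_true(all(abs(m_iter - m_theory) < 3.5 * se_m))
  se_v <- v_theory * sqrt(2 / (n - 1))
  expect_true(all(abs(v_iter - v_theory) < 3.5 * se_v))
})

test_that("reverse_step implements the DDPM update and its contracts", {
  s <- make_schedule("linear", 100)
  x_t <- rand_norm_image(c(6, 6), 4)
  # plug-in: zero predicted noise, zero z
  out <- reverse_step(0 * x_t, x_t, 10, s)
  expect_equal(unclass(out), unclass(x_t) / sqrt(s$alpha[10]),
               ignore_attr = TRUE)
  # tiny beta limit: identity
  s2 <- make_schedule("linear", 10, beta_min = 1e-12, beta_max = 1e-11)
  expect_lt(max(abs(reverse_step(0 * x_t, x_t, 5, s2) - x_t)), 1e-5)
  # z must be zero at t = 1
  expect_error(reverse_step(0 * x_t, x_t, 1, s, z = matrix(1, 6, 6)),
               "z = 0")
  expect_error(reverse_step(0 * x_t, x_t, 0, s), "1..100")
  expect_error(reverse_step(matrix(0, 2, 2), x_t, 5, s), "shape")
})

test_that("with the exact-noise oracle the reverse residual contracts as predicted", {
  s <- make_schedule("cosine", 200)
  x0 <- rand_norm_image(c(8, 8), 5)
  den <- oracle_denoiser(unclass(x0), s)
  withr::with_seed(6, {
    eps <- matrix(stats::rnorm(64), 8, 8)
    x <- forward_diffuse(x0, 120, eps, s)
    for (t in seq(120, 1)) {
      resid_before <- unclass(x) - sqrt(alpha_bar_at(s, t)) * unclass(x0)
      eps_hat <- predict_noise(den, x, 0 * x, t)
      x <- reverse_step(eps_hat, x, t, s)
      resid_after <- unclass(x) - sqrt(alpha_bar_at(s, t - 1)) * unclass(x0)
      shrink <- sqrt(s$alpha[t]) * (1 - alpha_bar_at(s, t - 1)) /
        (1 - alpha_bar_at(s, t))
      expect_equal(resid_after, resid_before * shrink, tolerance = 1e-9)
    }
  })
  # the t = 1 step lands exactly on the target
  expect_equal(unclass(x), unclass(x0), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("both samplers recover the oracle target and are seed-deterministic", {
  s <- make_schedule("linear", 300)
  x0 <- rand_norm_image(c(8, 8), 7)
  den <- oracle_denoiser(unclass(x0), s)
  so <- sample_original(den, s, c(8, 8), stochastic_z = FALSE,
                        clip_x0 = FALSE, seed = 8)
  expect_lt(max(abs(so - unclass(x0))), 1e-3)
  expect_identical(dim(so), c(8L, 8L))
  so2 <- sample_original(den, s, c(8, 8), stochastic_z = FALSE,
                         clip_x0 = FALSE, seed = 8)
  expect_identical(so, so2)

  y0 <- rand_norm_image(c(8, 8), 9)
  for (tc in c(300L, 150L, 1L)) {
    sc <- sample_noised_conditioned(den, y0, s, tc, stochastic_z = FALSE,
                                    clip_x0 = FALSE, seed = 10)
    expect_lt(max(abs(sc - unclass(x0))), 1e-3)
  }
  # t_con = 0 returns the conditioning image untouched
  expect_identical(sample_noised_conditioned(den, y0, s, 0L, seed = 1), y0)
  # stochastic sampling is reproducible by seed
  a <- sample_noised_conditioned(den, y0, s, 50L, seed = 12)
  b <- sample_noised_conditioned(den, y0, s, 50L, seed = 12)
  expect_identical(a, b)
})

test_that("training loss is exact for oracle and zero predictors", {
  s <- make_schedule("linear", 100)
  x0 <- rand_norm_image(c(8, 8), 13)
  y0 <- rand_norm_image(c(8, 8), 14)
  den <- oracle_denoiser(unclass(x0), s)
  withr::with_seed(15, {
    eps <- matrix(stats::rnorm(64), 8, 8)
    expect_lt(training_loss(den, x0, y0, 30, eps, s), 1e-20)
    # an all-zeros predictor scores the mean squared noise
    zero_den <- structure(list(), class = "zero_denoiser")
    registerS3method("predict_noise", "zero_denoiser",
                     function(denoiser, x_t, y0, t) 0 * x_t)
    losses <- vapply(1:200, function(i) {
      e <- matrix(stats::rnorm(64), 8, 8)
      training_loss(zero_den, x0, y0, 30, e, s)
    }, numeric(1))
    expect_lt(abs(mean(losses) - 1), 3 * sd(losses) / sqrt(200))
  })
  # consistent pixel permutation leaves the loss unchanged
  perm <- withr::with_seed(16, sample(64))
  pmat <- function(m) matrix(as.vector(m)[perm], 8, 8)
  withr::with_seed(17, {
    eps <- matrix(stats::rnorm(64), 8, 8)
    l1 <- training_loss(den, x0, y0, 40, eps, s)
    den_p <- oracle_denoiser(pmat(unclass(x0)), s)
    l2 <- training_loss(den_p, norm_img(pmat(x0)), norm_img(pmat(y0)),
                        40, pmat(eps), s)
    expect_equal(l1, l2)
  })
})

test_that("timestep bands bin the schedule into deciles", {
  expect_equal(timestep_band(950, 1000), 10)
  expect_equal(timestep_band(1, 1000), 1)
  expect_equal(timestep_band(c(100, 101, 1000), 1000), c(1, 2, 10))
  expect_error(timestep_band(0, 1000), "1..1000")
})

test_that("a short overfitting run reduces high-timestep losses", {
  ds <- make_pair_dataset(1, seed = 20)
  dn <- lapply(ds, preprocess)
  s <- make_schedule("cosine", 50)
  den <- build_denoiser(denoiser_config(), seed = 21)
  fit <- train_diffusion(den, dn, s, steps = 120, batch_size = 2, seed = 22)
  lh <- fit$loss_history
  hi <- lh[lh$band >= 9, ]
  early <- mean(hi$loss[hi$step <= 20])
  late <- mean(hi$loss[hi$step > 100])
  expect_lt(late, 0.1 * early)
  expect_error(train_diffusion(den, list(), s), "empty")
  expect_error(train_diffusion(den, ds, s), "normalized")
})
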