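# Forward diffusion, the epsilon-prediction training objective, and the two
# sampling algorithms: original (pure-noise start) and channel- plus
# noised-conditioned (reverse diffusion started from the guiding CBCT noised
# to timestep t_con).

#' One-shot forward diffusion to timestep t
#'
#' Computes \eqn{x_t = \sqrt{\bar\alpha_t}\,x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon},
#' the closed form of `t` iterated Markov noising steps. At `t = 0` the input
#' is returned unchanged.
#'
#' @param x0 clean normalized image (any array shape).
#' @param t integer timestep in `0:n_steps`.
#' @param eps standard-normal noise of the same shape as `x0` (supplied
#'   explicitly so callers control determinism and noise sharing).
#' @param schedule a [make_schedule()] object.
#' @return Noised image of the same shape.
#' @export
forward_diffuse <- function(x0, t, eps, schedule) {
  stopifnot(inherits(schedule, "noise_schedule"))
  assert_same_shape(x0, eps, c("x0", "eps"))
  ab <- alpha_bar_at(schedule, t)
  out <- sqrt(ab) * unclass_img(x0) + sqrt(1 - ab) * unclass_img(eps)
  set_units(out, "normalized")
}

#' Single Markov forward-diffusion step
#'
#' Draws from \eqn{q(x_t | x_{t-1}) = N(\sqrt{1-\beta_t}\,x_{t-1}, \beta_t I)}.
#'
#' @param x_prev image at timestep `t - 1`.
#' @param t integer timestep in `1:n_steps`.
#' @param schedule a [make_schedule()] object.
#' @param seed optional integer seed.
#' @return Image at timestep `t`.
#' @export
forward_step <- function(x_prev, t, schedule, seed = NULL) {
  stopifnot(inherits(schedule, "noise_schedule"))
  t <- as.integer(t)
  if (t < 1L || t > schedule$n_steps) {
    stop_param("t must lie in 1..", schedule$n_steps)
  }
  b <- schedule$beta[t]
  z <- with_seed_opt(seed, stats::rnorm(length(x_prev)))
  out <- sqrt(1 - b) * unclass_img(x_prev) +
    sqrt(b) * array(z, dim(x_prev) %||% length(x_prev))
  set_units(out, "normalized")
}

#' Denoising training loss for one sample
#'
#' The epsilon-prediction objective: mean squared error between the true noise
#' and the denoiser's prediction on the noised sample,
#' \eqn{\|\epsilon - \epsilon_\theta(x_t, y_0, t)\|^2 / N}.
#'
#' @param denoiser a denoiser usable with [predict_noise()].
#' @param x0 clean normalized CT image.
#' @param y0 conditioning normalized CBCT image of the same shape.
#' @param t integer timestep in `1:n_steps`.
#' @param eps noise image of the same shape.
#' @param schedule a [make_schedule()] object.
#' @return Non-negative scalar loss.
#' @export
training_loss <- function(denoiser, x0, y0, t, eps, schedule) {
  assert_same_shape(x0, y0, c("x0", "y0"))
  x_t <- forward_diffuse(x0, t, eps, schedule)
  pred <- predict_noise(denoiser, x_t, y0, t)
  mean((unclass_img(eps) - pred)^2)
}

#' One reverse diffusion step
#'
#' The DDPM update
#' \eqn{x_{t-1} = \frac{1}{\sqrt{\alpha_t}}\big(x_t -
#' \frac{1-\alpha_t}{\sqrt{1-\bar\alpha_t}}\,\hat\epsilon\big) + \sigma_t z}.
#' With `clip_x0 = TRUE` the implied clean image
#' \eqn{\hat x_0 = (x_t - \sqrt{1-\bar\alpha_t}\,\hat\epsilon)/\sqrt{\bar\alpha_t}}
#' is clamped to `[-1, 1]` before the (algebraically equivalent)
#' posterior-mean form of the same update is applied — a standard numerical
#' safeguard against drift in long sampling chains.
#'
#' @param eps_hat predicted noise image.
#' @param x_t current noisy image.
#' @param t integer timestep in `1:n_steps`.
#' @param schedule a [make_schedule()] object.
#' @param z standard-normal noise image, or `NULL` for zero; must be zero at
#'   `t = 1`.
#' @param clip_x0 clamp the implied clean image to `[-1, 1]`.
#' @return The image at timestep `t - 1`.
#' @export
reverse_step <- function(eps_hat, x_t, t, schedule, z = NULL,
                         clip_x0 = FALSE) {
  stopifnot(inherits(schedule, "noise_schedule"))
  assert_same_shape(eps_hat, x_t, c("eps_hat", "x_t"))
  t <- as.integer(t)
  if (t < 1L || t > schedule$n_steps) {
    stop_param("t must lie in 1..", schedule$n_steps)
  }
  if (t == 1L && !is.null(z) && any(z != 0)) {
    stop_param("the final reverse step (t = 1) must use z = 0")
  }
  x_t <- unclass_img(x_t); eps_hat <- unclass_img(eps_hat)
  a <- schedule$alpha[t]
  b <- schedule$beta[t]
  ab <- schedule$alpha_bar[t + 1L]
  ab_prev <- schedule$alpha_bar[t]
  mu <- if (clip_x0) {
    x0h <- (x_t - sqrt(1 - ab) * eps_hat) / sqrt(ab)
    x0h <- pmin(pmax(x0h, -1), 1)
    (sqrt(ab_prev) * b * x0h + sqrt(a) * (1 - ab_prev) * x_t) / (1 - ab)
  } else {
    (x_t - (b / sqrt(1 - ab)) * eps_hat) / sqrt(a)
  }
  out <- if (is.null(z)) mu else mu + schedule$sigma[t] * unclass_img(z)
  set_units(array(out, dim(x_t) %||% length(x_t)), "normalized")
}

#' Sample from pure noise (original DDPM sampling)
#'
#' Starts from \eqn{x_T \sim N(0, I)} and applies the full chain of reverse
#' steps. The two-channel denoiser contract is kept by passing an all-zeros
#' neutral conditioning channel.
#'
#' @param denoiser a denoiser usable with [predict_noise()].
#' @param schedule a [make_schedule()] object.
#' @param shape output spatial shape `c(rows, cols)`.
#' @param n number of images to sample (batched through the network).
#' @param stochastic_z inject \eqn{\sigma_t z} noise during sampling (`z = 0`
#'   at `t = 1` always).
#' @param clip_x0 see [reverse_step()].
#' @param seed optional integer seed; fixed seeds give bit-identical samples.
#' @return Normalized image, `H x W` (or `H x W x n` when `n > 1`).
#' @export
sample_original <- function(denoiser, schedule, shape, n = 1L,
                            stochastic_z = TRUE, clip_x0 = TRUE,
                            seed = NULL) {
  dims <- if (n > 1L) c(shape, n) else shape
  y0 <- array(0, dims)
  with_seed_opt(seed, {
    x <- array(stats::rnorm(prod(dims)), dims)
    run_reverse_chain(denoiser, x, y0, schedule, schedule$n_steps,
                      stochastic_z, clip_x0)
  })
}

#' Channel- and noised-conditioned sampling
#'
#' The conditional sampling algorithm: the guiding CBCT `y0` is noised to
#' timestep `t_con` with the forward process,
#' \eqn{x_{t_{con}} = \sqrt{\bar\alpha_{t_{con}}}\,y_0 +
#' \sqrt{1-\bar\alpha_{t_{con}}}\,\epsilon}, and reverse diffusion then runs
#' from \eqn{t = t_{con}} down to 1 with `y0` concatenated as the conditioning
#' channel at every step. `t_con` trades off how much CBCT content is
#' destroyed (large `t_con`: more denoising iterations but less anatomical
#' guidance; `t_con = n_steps` is equivalent to channel-conditioned sampling
#' from essentially pure noise) against how much CBCT degradation survives
#' (small `t_con`). `t_con = 0` returns the conditioning image unchanged.
#'
#' @param denoiser a denoiser usable with [predict_noise()].
#' @param y0 conditioning normalized CBCT: `H x W` matrix or `H x W x B`
#'   array.
#' @param schedule a [make_schedule()] object.
#' @param t_con starting timestep in `0:n_steps`.
#' @inheritParams sample_original
#' @return Normalized synthetic-CT estimate of the same shape as `y0`.
#' @export
sample_noised_conditioned <- function(denoiser, y0, schedule, t_con,
                                      stochastic_z = TRUE, clip_x0 = TRUE,
                                      seed = NULL) {
  stopifnot(inherits(schedule, "noise_schedule"))
  t_con <- as.integer(t_con)
  if (t_con < 0L || t_con > schedule$n_steps) {
    stop_param("t_con must lie in 0..", schedule$n_steps)
  }
  u <- get_units(y0)
  if (!is.null(u) && u != "normalized") {
    stop_param("y0 must be in normalized units; apply preprocess() first")
  }
  if (t_con == 0L) return(y0)
  with_seed_opt(seed, {
    eps <- array(stats::rnorm(length(y0)), dim(y0) %||% length(y0))
    x <- forward_diffuse(y0, t_con, eps, schedule)
    run_reverse_chain(denoiser, x, unclass_img(y0), schedule, t_con,
                      stochastic_z, clip_x0)
  })
}

# shared reverse loop; consumes the ambient RNG stream for z draws
run_reverse_chain <- function(denoiser, x, y0, schedule, t_start,
                              stochastic_z, clip_x0) {
  dims <- dim(x) %||% length(x)
  for (t in seq(t_start, 1L)) {
    eps_hat <- predict_noise(denoiser, x, y0, t)
    z <- if (stochastic_z && t > 1L) {
      array(stats::rnorm(prod(dims)), dims)
    } else {
      NULL
    }
    x <- reverse_step(eps_hat, x, t, schedule, z = z, clip_x0 = clip_x0)
  }
  x
}

#' Timestep band index
#'
#' Assigns a timestep to one of `n_bands` equal bands of `1:n_steps`; used for
#' the per-band loss bookkeeping that reveals how much slower the denoising
#' loss converges at low timesteps (fine detail) than at high timesteps
#' (coarse structure).
#'
#' @param t integer timestep(s) in `1:n_steps`.
#' @param n_steps total timesteps.
#' @param n_bands number of bands (default deciles).
#' @return Integer band index in `1:n_bands` (band `n_bands` holds the highest
#'   timesteps).
#' @export
timestep_band <- function(t, n_steps, n_bands = 10L) {
  t <- as.integer(t)
  if (any(t < 1L | t > n_steps)) stop_param("t must lie in 1..", n_steps)
  pmin(ceiling(t * n_bands / n_steps), n_bands)
}

#' Train the conditional denoiser
#'
#' Runs the channel-conditioned training loop: per step, draw a batch of
#' pCT/CBCT pairs, a timestep per sample from the timestep distribution and a
#' noise realization; noise the CT one-shot to its timestep; take an Adam step
#' on the mean squared error between the true and predicted noise. The loss of
#' every sample is recorded together with its timestep band (default deciles),
#' so the band-convergence behaviour can be inspected afterwards.
#'
#' @param denoiser a [build_denoiser()] object.
#' @param dataset a [make_pair_dataset()] already converted to normalized
#'   units (see [preprocess()]), or any list of `paired_sample`s.
#' @param schedule a [make_schedule()] object.
#' @param sampler a [timestep_distribution()]; defaults to uniform.
#' @param steps number of gradient steps.
#' @param batch_size pairs per gradient step.
#' @param lr Adam learning rate.
#' @param n_bands number of loss-history timestep bands.
#' @param seed optional integer seed controlling batch, timestep and noise
#'   draws.
#' @param verbose print progress every 100 steps.
#' @return A list with `denoiser` (trained weights) and `loss_history`, a data
#'   frame with one row per training sample: `step`, `t`, `band`, `loss`.
#' @export
train_diffusion <- function(denoiser, dataset, schedule,
                            sampler = timestep_distribution("uniform",
                                                            schedule$n_steps),
                            steps = 1000L, batch_size = 4L, lr = 1e-3,
                            n_bands = 10L, seed = NULL, verbose = FALSE) {
  stopifnot(inherits(denoiser, "cbct_denoiser"),
            inherits(schedule, "noise_schedule"),
            inherits(sampler, "timestep_distribution"))
  if (length(dataset) == 0L) stop_param("dataset is empty")
  if (sampler$n_steps != schedule$n_steps) {
    stop_param("sampler and schedule disagree on the number of timesteps")
  }
  bad <- vapply(dataset, function(p) !identical(p$unit_tag, "normalized"),
                logical(1))
  if (any(bad)) {
    stop_param("all pairs must be preprocessed to normalized units first")
  }
  cfg <- denoiser$config
  H <- cfg$input_shape[1]; W <- cfg$input_shape[2]
  hw <- H * W
  B <- as.integer(batch_size)
  params <- denoiser$params
  opt <- adam_state(params)
  hist_step <- integer(0); hist_t <- integer(0); hist_loss <- numeric(0)

  with_seed_opt(seed, {
    for (s in seq_len(steps)) {
      idx <- sample.int(length(dataset), B, replace = TRUE)
      x0 <- vapply(idx, function(i) unclass_img(dataset[[i]]$pct),
                   matrix(0, H, W))
      y0 <- vapply(idx, function(i) unclass_img(dataset[[i]]$cbct),
                   matrix(0, H, W))
      t_b <- sample_timesteps(sampler, B)
      eps <- array(stats::rnorm(hw * B), c(H, W, B))
      ab <- rep(schedule$alpha_bar[t_b + 1L], each = hw)
      xt_stack <- sqrt(ab) * as.vector(x0) + sqrt(1 - ab) * as.vector(eps)

      tp <- ad_tape()
      pids <- lapply(params, function(p) ad_leaf(tp, p))
      out <- unet_forward(cfg, tp, pids, cbind(xt_stack, as.vector(y0)),
                          t_b, B)
      target <- matrix(as.vector(eps), ncol = 1)
      loss_id <- op_mse(tp, out, target)
      grads_by_node <- ad_backward(tp, loss_id)
      grads <- lapply(pids, function(id) grads_by_node[[id]])

      upd <- adam_update(params, grads, opt, lr = lr)
      params <- upd$params; opt <- upd$state

      resid2 <- (ad_value(tp, out) - target)^2
      per_sample <- colMeans(matrix(resid2, hw, B))
      hist_step <- c(hist_step, rep(s, B))
      hist_t <- c(hist_t, t_b)
      hist_loss <- c(hist_loss, per_sample)
      if (verbose && s %% 100L == 0L) {
        message(sprintf("step %d/%d loss %.4f", s, steps,
                        ad_value(tp, loss_id)))
      }
    }
  })

  denoiser$params <- params
  list(denoiser = denoiser,
       loss_history = data.frame(
         step = hist_step, t = hist_t,
         band = timestep_band(hist_t, schedule$n_steps, n_bands),
         loss = hist_loss))
}
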