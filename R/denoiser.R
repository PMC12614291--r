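# The conditional noise-prediction network: a 2-channel-input (noisy CT +
# guiding CBCT), 1-channel-output U-Net with sinusoidal timestep embeddings,
# ResNet blocks, group normalization, and single-head spatial self-attention
# at configurable resolution levels.

#' Configuration of the conditional U-Net denoiser
#'
#' Describes a U-Net \eqn{\epsilon_\theta(x_t, y_0, t)} that takes the noisy
#' CT sample concatenated with the conditioning CBCT as two input channels and
#' predicts the added noise as a single output channel. The default is a toy
#' scale (depth 3, base width 16, 32 x 32 inputs) that trains on a CPU in
#' minutes; paper-scale dimensions (depth 6, two ResNet blocks per level,
#' 256 x 256 inputs, ~1e8 parameters) are reachable through the same fields.
#'
#' @param input_shape spatial input size `c(rows, cols)`; must be divisible by
#'   `2^depth`.
#' @param depth number of resolution levels (downsampling happens `depth - 1`
#'   times).
#' @param base_width channels at the finest level.
#' @param channel_mult per-level width multipliers; default doubles each level
#'   capped at 8x.
#' @param blocks_per_level ResNet blocks per level.
#' @param attention_levels levels (1 = finest) that get spatial self-attention
#'   after their ResNet blocks, on both the down and up paths; default the
#'   bottleneck only.
#' @param time_embedding_dim dimension of the sinusoidal timestep embedding
#'   (even).
#' @param groups preferred group count for group normalization (reduced per
#'   layer to the largest divisor of the channel count).
#' @param in_channels,out_channels fixed at 2 (noisy CT + CBCT) and 1
#'   (predicted noise) for this model family but exposed for completeness.
#' @return A list of class `denoiser_config`.
#' @export
denoiser_config <- function(input_shape = c(32L, 32L),
                            depth = 3L,
                            base_width = 16L,
                            channel_mult = NULL,
                            blocks_per_level = 1L,
                            attention_levels = depth,
                            time_embedding_dim = 32L,
                            groups = 8L,
                            in_channels = 2L,
                            out_channels = 1L) {
  depth <- as.integer(depth)
  input_shape <- as.integer(input_shape)
  if (depth < 1L) stop_param("depth must be >= 1")
  if (any(input_shape %% (2L^depth) != 0L)) {
    stop_param("input_shape must be divisible by 2^depth (",
               2L^depth, ")")
  }
  if (time_embedding_dim %% 2L != 0L) {
    stop_param("time_embedding_dim must be even")
  }
  channel_mult <- channel_mult %||% pmin(2^(seq_len(depth) - 1L), 8L)
  if (length(channel_mult) != depth) {
    stop_param("channel_mult must have one entry per level")
  }
  structure(list(input_shape = input_shape, depth = depth,
                 base_width = as.integer(base_width),
                 channel_mult = as.integer(channel_mult),
                 blocks_per_level = as.integer(blocks_per_level),
                 attention_levels = as.integer(attention_levels),
                 time_embedding_dim = as.integer(time_embedding_dim),
                 groups = as.integer(groups),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels)),
            class = "denoiser_config")
}

gn_groups <- function(C, pref) {
  g <- min(pref, C)
  while (C %% g != 0L) g <- g - 1L
  g
}

# Enumerate every parameter of the network: name -> list(dim, init), where
# init selects the initialization family. Walked in the same order as the
# forward pass.
denoiser_param_shapes <- function(cfg) {
  stopifnot(inherits(cfg, "denoiser_config"))
  d_t <- cfg$time_embedding_dim
  h_t <- 2L * d_t
  w <- cfg$base_width * cfg$channel_mult
  shapes <- list()
  put <- function(name, dim, init) {
    shapes[[name]] <<- list(dim = dim, init = init)
  }
  put_resblock <- function(prefix, cin, cout) {
    put(paste0(prefix, ".gn1.g"), cin, "ones")
    put(paste0(prefix, ".gn1.b"), cin, "zeros")
    put(paste0(prefix, ".conv1.w"), c(9L * cin, cout), "conv")
    put(paste0(prefix, ".conv1.b"), cout, "zeros")
    put(paste0(prefix, ".temb.w"), c(h_t, cout), "dense")
    put(paste0(prefix, ".temb.b"), cout, "zeros")
    put(paste0(prefix, ".gn2.g"), cout, "ones")
    put(paste0(prefix, ".gn2.b"), cout, "zeros")
    put(paste0(prefix, ".conv2.w"), c(9L * cout, cout), "conv")
    put(paste0(prefix, ".conv2.b"), cout, "zeros")
    if (cin != cout) {
      put(paste0(prefix, ".skip.w"), c(cin, cout), "dense")
      put(paste0(prefix, ".skip.b"), cout, "zeros")
    }
  }
  put_attention <- function(prefix, C) {
    put(paste0(prefix, ".gn.g"), C, "ones")
    put(paste0(prefix, ".gn.b"), C, "zeros")
    for (nm in c("wq", "wk", "wv")) {
      put(paste0(prefix, ".", nm), c(C, C), "dense")
    }
    put(paste0(prefix, ".wo"), c(C, C), "zeros")
  }

  put("temb.w1", c(d_t, h_t), "dense")
  put("temb.b1", h_t, "zeros")
  put("temb.w2", c(h_t, h_t), "dense")
  put("temb.b2", h_t, "zeros")
  put("stem.w", c(9L * cfg$in_channels, w[1]), "conv")
  put("stem.b", w[1], "zeros")

  cur <- w[1]
  for (l in seq_len(cfg$depth)) {
    for (k in seq_len(cfg$blocks_per_level)) {
      put_resblock(sprintf("d%d.b%d", l, k), cur, w[l])
      cur <- w[l]
    }
    if (l %in% cfg$attention_levels) put_attention(sprintf("d%d.attn", l), cur)
  }
  if (cfg$depth > 1L) {
    for (l in seq(cfg$depth - 1L, 1L)) {
      cin <- cur + w[l] # upsampled channels + skip concat
      for (k in seq_len(cfg$blocks_per_level)) {
        put_resblock(sprintf("u%d.b%d", l, k), cin, w[l])
        cin <- w[l]
      }
      cur <- w[l]
      if (l %in% cfg$attention_levels) {
        put_attention(sprintf("u%d.attn", l), cur)
      }
    }
  }
  put("head.gn.g", cur, "ones")
  put("head.gn.b", cur, "zeros")
  # small (not zero) head so a fresh network is already sensitive to its
  # timestep and conditioning inputs, while starting near the neutral
  # zero-noise prediction
  put("head.w", c(9L * cur, cfg$out_channels), "head")
  put("head.b", cfg$out_channels, "zeros")
  shapes
}

#' Number of parameters of a denoiser configuration
#'
#' Computed analytically from the layer shapes, so paper-scale configurations
#' can be sized without allocating their weights.
#'
#' @param x a [denoiser_config()] or a built denoiser.
#' @return Integer parameter count.
#' @export
count_denoiser_params <- function(x) {
  cfg <- if (inherits(x, "cbct_denoiser")) x$config else x
  sum(vapply(denoiser_param_shapes(cfg),
             function(s) prod(s$dim), numeric(1)))
}

#' Build an initialized conditional U-Net denoiser
#'
#' Allocates and initializes the network weights: He-scaled normal draws for
#' convolutions, scaled normal draws for dense layers and attention
#' projections, unit/zero affine normalization parameters, and zero-initialized
#' attention output projections and prediction head (the freshly built network
#' therefore predicts zero noise, a neutral starting point).
#'
#' @param cfg a [denoiser_config()].
#' @param seed optional integer seed; the same seed reproduces identical
#'   weights.
#' @return An object of class `cbct_denoiser` with fields `config`, `params`
#'   and `n_params`.
#' @export
build_denoiser <- function(cfg = denoiser_config(), seed = NULL) {
  shapes <- denoiser_param_shapes(cfg)
  params <- with_seed_opt(seed, {
    lapply(shapes, function(s) {
      n <- prod(s$dim)
      v <- switch(s$init,
        zeros = rep(0, n),
        ones = rep(1, n),
        conv = stats::rnorm(n, 0, sqrt(2 / s$dim[1])),
        dense = stats::rnorm(n, 0, sqrt(1 / s$dim[1])),
        head = stats::rnorm(n, 0, 0.01 * sqrt(2 / s$dim[1]))
      )
      if (length(s$dim) > 1L) matrix(v, s$dim[1], s$dim[2]) else v
    })
  })
  structure(list(config = cfg, params = params,
                 n_params = sum(vapply(params, length, numeric(1)))),
            class = "cbct_denoiser")
}

#' @export
print.cbct_denoiser <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<cbct_denoiser> %dx%d, depth %d, widths %s, %s parameters\n",
              cfg$input_shape[1], cfg$input_shape[2], cfg$depth,
              paste(cfg$base_width * cfg$channel_mult, collapse = "/"),
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

# sinusoidal timestep embedding, one row per sample
sinusoidal_embedding <- function(t, dim) {
  half <- dim %/% 2L
  freqs <- exp(-log(10000) * (seq_len(half) - 1) / max(half - 1, 1))
  ang <- outer(as.numeric(t), freqs)
  cbind(sin(ang), cos(ang))
}

# Build the U-Net forward graph on a tape. x_stack is the (B*H*W) x 2 input
# (noisy CT, conditioning CBCT); t_vec has one timestep per sample. pids maps
# parameter names to leaf node ids. Returns the output node id.
unet_forward <- function(cfg, tp, pids, x_stack, t_vec, B) {
  H <- cfg$input_shape[1]; W <- cfg$input_shape[2]
  w <- cfg$base_width * cfg$channel_mult
  P <- function(nm) {
    id <- pids[[nm]]
    if (is.null(id)) stop_param("internal: unknown parameter ", nm)
    id
  }

  temb0 <- ad_leaf(tp, sinusoidal_embedding(t_vec, cfg$time_embedding_dim))
  temb <- op_bias(tp, op_mm(tp, op_silu(tp, op_bias(tp,
            op_mm(tp, temb0, P("temb.w1")), P("temb.b1"))),
            P("temb.w2")), P("temb.b2"))

  res_block <- function(h, prefix, cin, cout, hh, ww) {
    hw <- hh * ww
    a <- op_silu(tp, op_groupnorm(tp, h, P(paste0(prefix, ".gn1.g")),
                                  P(paste0(prefix, ".gn1.b")),
                                  gn_groups(cin, cfg$groups), hw))
    a <- op_conv3x3(tp, a, P(paste0(prefix, ".conv1.w")),
                    P(paste0(prefix, ".conv1.b")), hh, ww, B)
    tb <- op_bias(tp, op_mm(tp, op_silu(tp, temb),
                            P(paste0(prefix, ".temb.w"))),
                  P(paste0(prefix, ".temb.b")))
    a <- op_add(tp, a, op_broadcast_rows(tp, tb, hw))
    a <- op_silu(tp, op_groupnorm(tp, a, P(paste0(prefix, ".gn2.g")),
                                  P(paste0(prefix, ".gn2.b")),
                                  gn_groups(cout, cfg$groups), hw))
    a <- op_conv3x3(tp, a, P(paste0(prefix, ".conv2.w")),
                    P(paste0(prefix, ".conv2.b")), hh, ww, B)
    skip <- if (cin == cout) h else {
      op_conv1x1(tp, h, P(paste0(prefix, ".skip.w")),
                 P(paste0(prefix, ".skip.b")))
    }
    op_add(tp, a, skip)
  }
  attn_block <- function(h, prefix, C, hw) {
    a <- op_groupnorm(tp, h, P(paste0(prefix, ".gn.g")),
                      P(paste0(prefix, ".gn.b")),
                      gn_groups(C, cfg$groups), hw)
    a <- op_attention(tp, a, P(paste0(prefix, ".wq")),
                      P(paste0(prefix, ".wk")), P(paste0(prefix, ".wv")),
                      P(paste0(prefix, ".wo")), hw)
    op_add(tp, h, a)
  }

  x <- ad_leaf(tp, x_stack)
  h <- op_conv3x3(tp, x, P("stem.w"), P("stem.b"), H, W, B)
  cur <- w[1]
  hh <- H; ww <- W
  skips <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    for (k in seq_len(cfg$blocks_per_level)) {
      h <- res_block(h, sprintf("d%d.b%d", l, k), cur, w[l], hh, ww)
      cur <- w[l]
    }
    if (l %in% cfg$attention_levels) {
      h <- attn_block(h, sprintf("d%d.attn", l), cur, hh * ww)
    }
    skips[[l]] <- h
    if (l < cfg$depth) {
      h <- op_avgpool2(tp, h, hh, ww, B)
      hh <- hh %/% 2L; ww <- ww %/% 2L
    }
  }
  if (cfg$depth > 1L) {
    for (l in seq(cfg$depth - 1L, 1L)) {
      h <- op_upsample2(tp, h, hh, ww, B)
      hh <- hh * 2L; ww <- ww * 2L
      h <- op_concat_cols(tp, h, skips[[l]])
      cin <- cur + w[l]
      for (k in seq_len(cfg$blocks_per_level)) {
        h <- res_block(h, sprintf("u%d.b%d", l, k), cin, w[l], hh, ww)
        cin <- w[l]
      }
      cur <- w[l]
      if (l %in% cfg$attention_levels) {
        h <- attn_block(h, sprintf("u%d.attn", l), cur, hh * ww)
      }
    }
  }
  a <- op_silu(tp, op_groupnorm(tp, h, P("head.gn.g"), P("head.gn.b"),
                                gn_groups(cur, cfg$groups), hh * ww))
  op_conv3x3(tp, a, P("head.w"), P("head.b"), hh, ww, B)
}

# stack images (H x W matrix or H x W x B array) into a (B*H*W) column
stack_images <- function(x) {
  if (is.matrix(x)) return(matrix(as.vector(x), ncol = 1))
  matrix(as.vector(x), ncol = 1)
}

unstack_images <- function(v, H, W, B) {
  if (B == 1L) matrix(v, H, W) else array(v, c(H, W, B))
}

#' Predict the noise component of a noisy CT sample
#'
#' Runs the denoiser \eqn{\epsilon_\theta(x_t, y_0, t)} on the noisy sample
#' and its conditioning CBCT. Deterministic given the weights.
#'
#' @param denoiser a [build_denoiser()] object (or an
#'   [oracle_denoiser()] for testing).
#' @param x_t noisy normalized image: `H x W` matrix or `H x W x B` array.
#' @param y0 conditioning normalized CBCT of the same shape.
#' @param t integer timestep, scalar or one per batch sample.
#' @return Predicted noise with the same shape as `x_t`.
#' @export
predict_noise <- function(denoiser, x_t, y0, t) UseMethod("predict_noise")

#' @export
predict_noise.cbct_denoiser <- function(denoiser, x_t, y0, t) {
  assert_same_shape(x_t, y0, c("x_t", "y0"))
  cfg <- denoiser$config
  dims <- dim(x_t) %||% length(x_t)
  H <- dims[1]; W <- dims[2]
  B <- if (length(dims) == 3L) dims[3] else 1L
  if (H != cfg$input_shape[1] || W != cfg$input_shape[2]) {
    stop_param("input is ", H, "x", W, " but the denoiser expects ",
               cfg$input_shape[1], "x", cfg$input_shape[2])
  }
  t <- as.integer(t)
  if (length(t) == 1L) t <- rep(t, B)
  if (length(t) != B) stop_param("t must be scalar or one per batch sample")
  tp <- ad_tape()
  pids <- lapply(denoiser$params, function(p) ad_leaf(tp, p))
  out <- unet_forward(cfg, tp, pids,
                      cbind(as.vector(x_t), as.vector(y0)), t, B)
  unstack_images(ad_value(tp, out), H, W, B)
}

#' Exact-noise oracle denoiser
#'
#' A reference denoiser for validating the samplers independently of any
#' trained network: given the target clean image \eqn{x_0^*}, it returns the
#' exact noise consistent with the forward process,
#' \eqn{\hat\epsilon = (x_t - \sqrt{\bar\alpha_t}\,x_0^*) / \sqrt{1 - \bar\alpha_t}}.
#' Substituted into the reverse update with `z = 0`, sampling recovers
#' \eqn{x_0^*} up to accumulated floating-point error.
#'
#' @param x0_target the clean normalized image the oracle aims at.
#' @param schedule the [make_schedule()] the sampler will use.
#' @return An object of class `oracle_denoiser` usable with
#'   [predict_noise()] and the sampling functions.
#' @export
oracle_denoiser <- function(x0_target, schedule) {
  stopifnot(inherits(schedule, "noise_schedule"))
  structure(list(x0 = x0_target, schedule = schedule),
            class = "oracle_denoiser")
}

#' @export
predict_noise.oracle_denoiser <- function(denoiser, x_t, y0, t) {
  ab <- alpha_bar_at(denoiser$schedule, t[1])
  x0 <- denoiser$x0
  if (!is.null(dim(x_t)) && length(dim(x_t)) == 3L && is.matrix(x0)) {
    x0 <- array(rep(as.vector(x0), dim(x_t)[3]), dim(x_t))
  }
  (x_t - sqrt(ab) * x0) / sqrt(1 - ab)
}
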