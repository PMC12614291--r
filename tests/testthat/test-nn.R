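# Gradient correctness of the autodiff layers, checked against central finite
# differences on tiny geometries.

ns <- asNamespace("cbctdiff")
ad_tape <- ns$ad_tape; ad_leaf <- ns$ad_leaf; ad_value <- ns$ad_value
ad_backward <- ns$ad_backward; op_mse <- ns$op_mse

grad_check <- function(build, inputs, h = 1e-6, tol = 1e-4) {
  # build(tp, ids) must return the id of a scalar loss node
  run <- function(vals) {
    tp <- ad_tape()
    ids <- lapply(vals, function(v) ad_leaf(tp, v))
    list(tp = tp, loss = build(tp, ids), ids = ids)
  }
  base <- run(inputs)
  grads <- ad_backward(base$tp, base$loss)
  for (nm in names(inputs)) {
    g_ad <- grads[[base$ids[[nm]]]]
    for (i in sample(length(inputs[[nm]]), min(3, length(inputs[[nm]])))) {
      vp <- inputs; vp[[nm]][i] <- vp[[nm]][i] + h
      vm <- inputs; vm[[nm]][i] <- vm[[nm]][i] - h
      lp <- local({ r <- run(vp); ad_value(r$tp, r$loss) })
      lm <- local({ r <- run(vm); ad_value(r$tp, r$loss) })
      fd <- (lp - lm) / (2 * h)
      ad <- if (is.null(g_ad)) 0 else g_ad[i]
      expect_lt(abs(fd - ad) / max(abs(fd), abs(ad), 1e-6), tol,
                label = sprintf("grad of %s[%d] (fd=%g ad=%g)", nm, i, fd, ad))
    }
  }
}

test_that("group normalization gradients match finite differences", {
  set.seed(1)
  hw <- 4L # 2x2 spatial, B = 2, C = 4, 2 groups
  inputs <- list(x = matrix(rnorm(8 * 4), 8, 4),
                 gamma = runif(4, 0.5, 1.5), beta = rnorm(4),
                 target = matrix(rnorm(8 * 4), 8, 4))
  grad_check(function(tp, ids) {
    y <- ns$op_groupnorm(tp, ids$x, ids$gamma, ids$beta, 2L, hw)
    op_mse(tp, y, inputs$target)
  }, inputs[c("x", "gamma", "beta")])
})

test_that("self-attention gradients match finite differences", {
  set.seed(2)
  hw <- 4L; C <- 3L # B = 2 samples of 4 tokens
  inputs <- list(x = matrix(rnorm(8 * C), 8, C),
                 wq = matrix(rnorm(C * C, 0, 0.5), C, C),
                 wk = matrix(rnorm(C * C, 0, 0.5), C, C),
                 wv = matrix(rnorm(C * C, 0, 0.5), C, C),
                 wo = matrix(rnorm(C * C, 0, 0.5), C, C))
  target <- matrix(rnorm(8 * C), 8, C)
  grad_check(function(tp, ids) {
    y <- ns$op_attention(tp, ids$x, ids$wq, ids$wk, ids$wv, ids$wo, hw)
    op_mse(tp, y, target)
  }, inputs)
})

test_that("3x3 convolution gradients match finite differences", {
  set.seed(3)
  H <- 4L; W <- 4L; B <- 2L; cin <- 2L; cout <- 3L
  inputs <- list(x = matrix(rnorm(B * H * W * cin), B * H * W, cin),
                 w = matrix(rnorm(9 * cin * cout, 0, 0.3), 9 * cin, cout),
                 b = rnorm(cout))
  target <- matrix(rnorm(B * H * W * cout), B * H * W, cout)
  grad_check(function(tp, ids) {
    y <- ns$op_conv3x3(tp, ids$x, ids$w, ids$b, H, W, B)
    op_mse(tp, y, target)
  }, inputs)
})

test_that("pooling, upsampling, SiLU and broadcast gradients match finite differences", {
  set.seed(4)
  H <- 4L; W <- 4L; B <- 2L; C <- 2L
  x <- matrix(rnorm(B * H * W * C), B * H * W, C)
  tgt_pool <- matrix(rnorm(B * 4 * C), B * 4, C)
  grad_check(function(tp, ids) {
    op_mse(tp, ns$op_avgpool2(tp, ns$op_silu(tp, ids$x), H, W, B), tgt_pool)
  }, list(x = x))

  x2 <- matrix(rnorm(B * 4 * C), B * 4, C)
  tgt_up <- matrix(rnorm(B * 16 * C), B * 16, C)
  grad_check(function(tp, ids) {
    op_mse(tp, ns$op_upsample2(tp, ids$x2, 2L, 2L, B), tgt_up)
  }, list(x2 = x2))

  emb <- matrix(rnorm(B * C), B, C)
  tgt_bc <- matrix(rnorm(B * H * W * C), B * H * W, C)
  grad_check(function(tp, ids) {
    op_mse(tp, ns$op_broadcast_rows(tp, ids$emb, H * W), tgt_bc)
  }, list(emb = emb))
})

test_that("whole-network gradients match finite differences", {
  set.seed(5)
  cfg <- tiny_denoiser_config()
  den <- build_denoiser(cfg, seed = 10)
  B <- 2L
  xs <- cbind(rnorm(64 * B), rnorm(64 * B))
  tv <- c(2L, 6L)
  target <- matrix(rnorm(64 * B), ncol = 1)
  loss_fn <- function(params) {
    tp <- ad_tape()
    pids <- lapply(params, function(p) ad_leaf(tp, p))
    ad_value(tp, op_mse(tp, ns$unet_forward(cfg, tp, pids, xs, tv, B),
                        target))
  }
  tp <- ad_tape()
  pids <- lapply(den$params, function(p) ad_leaf(tp, p))
  lid <- op_mse(tp, ns$unet_forward(cfg, tp, pids, xs, tv, B), target)
  grads_by_node <- ad_backward(tp, lid)
  h <- 1e-5
  for (nm in c("stem.w", "d1.b1.conv1.w", "d1.b1.temb.w", "d2.attn.wq",
               "u1.b1.gn1.g", "head.w", "temb.w1")) {
    i <- sample(length(den$params[[nm]]), 1)
    pp <- den$params; pp[[nm]][i] <- pp[[nm]][i] + h
    pm <- den$params; pm[[nm]][i] <- pm[[nm]][i] - h
    fd <- (loss_fn(pp) - loss_fn(pm)) / (2 * h)
    ad <- grads_by_node[[pids[[nm]]]][i]
    expect_lt(abs(fd - ad) / max(abs(fd), abs(ad), 1e-8), 1e-3, label = nm)
  }
})
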