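# Minimal reverse-mode automatic differentiation over matrices, with the
# fused layer operations the conditional U-Net denoiser needs: 3x3 and 1x1
# convolutions (im2col + BLAS matmul), group normalization, SiLU, nearest
# upsampling, 2x2 average pooling, single-head spatial self-attention, and a
# mean-squared-error head.
#
# Activations are stored channels-last as (B*H*W) x C matrices with rows in
# sample-major order: row (b-1)*H*W + p, where p = (col-1)*H + row indexes the
# pixel in R's column-major matrix layout. This makes a stacked batch of
# images exactly `as.vector(array(H, W, B))`.

# ---- tape -------------------------------------------------------------------

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_push <- function(tp, value, parents = integer(0), backward = NULL) {
  # force promises before reserving a slot: evaluating `value` or `parents`
  # may push nested nodes onto the tape
  force(value); force(parents); force(backward)
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) {
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  }
  tp$nodes[[tp$n]] <- list(value = value, parents = parents,
                           backward = backward)
  tp$n
}

ad_value <- function(tp, id) {
  # force id before touching tp$nodes: evaluating a promised op call can push
  # nodes, and tp$nodes must be re-read afterwards
  force(id)
  tp$nodes[[id]]$value
}

ad_leaf <- function(tp, value) ad_push(tp, value)

# Backpropagate from the (scalar) node `from`; returns a list of gradients
# indexed by node id (NULL where no gradient flows).
ad_backward <- function(tp, from) {
  grads <- vector("list", tp$n)
  grads[[from]] <- 1
  for (i in seq(tp$n, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- tp$nodes[[i]]
    if (is.null(nd$backward)) next
    pg <- nd$backward(g)
    for (j in seq_along(nd$parents)) {
      if (is.null(pg[[j]])) next
      p <- nd$parents[[j]]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  grads
}

# ---- primitive ops ----------------------------------------------------------

op_mm <- function(tp, a, b) {
  A <- ad_value(tp, a); B <- ad_value(tp, b)
  ad_push(tp, A %*% B, c(a, b), function(g) {
    list(g %*% t(B), crossprod(A, g))
  })
}

op_add <- function(tp, a, b) {
  ad_push(tp, ad_value(tp, a) + ad_value(tp, b), c(a, b),
          function(g) list(g, g))
}

# add a row vector (bias, one value per column/channel) to every row
op_bias <- function(tp, a, b) {
  bv <- ad_value(tp, b)
  ad_push(tp, add_bias(ad_value(tp, a), bv), c(a, b),
          function(g) list(g, colSums(g)))
}

op_silu <- function(tp, a) {
  x <- ad_value(tp, a)
  f <- silu_fwd(x)
  ad_push(tp, f$y, a, function(g) list(silu_bwd(g, x, f$s)))
}

op_scale <- function(tp, a, k) {
  ad_push(tp, k * ad_value(tp, a), a, function(g) list(k * g))
}

op_concat_cols <- function(tp, a, b) {
  A <- ad_value(tp, a); B <- ad_value(tp, b)
  na <- ncol(A)
  ad_push(tp, cbind(A, B), c(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE],
         g[, -seq_len(na), drop = FALSE])
  })
}

op_mse <- function(tp, a, target) {
  A <- ad_value(tp, a)
  d <- A - target
  ad_push(tp, mean(d^2), a, function(g) list(g * 2 * d / length(d)))
}

# ---- spatial index maps (cached per geometry) -------------------------------

.idx_cache <- new.env(parent = emptyenv())

cached_idx <- function(key, builder) {
  if (is.null(.idx_cache[[key]])) .idx_cache[[key]] <- builder()
  .idx_cache[[key]]
}

# (B*H*W) x 9 map of 3x3 neighbour rows (0 = zero padding)
conv3x3_rowmap <- function(H, W, B) {
  cached_idx(sprintf("c3_%d_%d_%d", H, W, B), function() {
    hw <- H * W
    p <- seq_len(hw)
    r <- (p - 1L) %% H + 1L
    cc <- (p - 1L) %/% H + 1L
    offs <- expand.grid(dr = -1:1, dc = -1:1)
    base <- matrix(0L, hw, 9L)
    for (k in 1:9) {
      rr <- r + offs$dr[k]; c2 <- cc + offs$dc[k]
      ok <- rr >= 1L & rr <= H & c2 >= 1L & c2 <= W
      base[ok, k] <- (c2[ok] - 1L) * H + rr[ok]
    }
    full <- base[rep(p, B), , drop = FALSE]
    pad <- full == 0L
    full <- full + rep((seq_len(B) - 1L) * hw, each = hw) # recycled per column
    full[pad] <- 0L
    storage.mode(full) <- "integer"
    full
  })
}

# four (B*H/2*W/2) row maps into the parent resolution for 2x2 average pooling
pool_rowmaps <- function(H, W, B) {
  cached_idx(sprintf("pool_%d_%d_%d", H, W, B), function() {
    H2 <- H %/% 2L; W2 <- W %/% 2L
    p2 <- seq_len(H2 * W2)
    r2 <- (p2 - 1L) %% H2 + 1L
    c2 <- (p2 - 1L) %/% H2 + 1L
    maps <- lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)),
                   function(o) {
      rr <- 2L * r2 - 1L + o[1]; cc <- 2L * c2 - 1L + o[2]
      base <- (cc - 1L) * H + rr
      as.integer(rep(base, B) + rep((seq_len(B) - 1L) * H * W,
                                    each = H2 * W2))
    })
    maps
  })
}

# (B*2H*2W) row map into the parent resolution for nearest upsampling
upsample_rowmap <- function(H, W, B) {
  cached_idx(sprintf("up_%d_%d_%d", H, W, B), function() {
    H2 <- 2L * H; W2 <- 2L * W
    p2 <- seq_len(H2 * W2)
    r2 <- (p2 - 1L) %% H2 + 1L
    c2 <- (p2 - 1L) %/% H2 + 1L
    rr <- (r2 + 1L) %/% 2L; cc <- (c2 + 1L) %/% 2L
    base <- (cc - 1L) * H + rr
    as.integer(rep(base, B) + rep((seq_len(B) - 1L) * H * W, each = H2 * W2))
  })
}

# ---- fused layer ops --------------------------------------------------------

op_conv3x3 <- function(tp, x, w, b, H, W, B) {
  X <- ad_value(tp, x); Wm <- ad_value(tp, w)
  rowmap <- conv3x3_rowmap(H, W, B)
  P <- im2col0(X, rowmap)
  Y <- add_bias(P %*% Wm, ad_value(tp, b))
  Cin <- ncol(X)
  ad_push(tp, Y, c(x, w, b), function(g) {
    list(col2im0(g %*% t(Wm), rowmap, Cin),
         crossprod(P, g),
         colSums(g))
  })
}

op_conv1x1 <- function(tp, x, w, b) {
  op_bias(tp, op_mm(tp, x, w), b)
}

op_avgpool2 <- function(tp, x, H, W, B) {
  X <- ad_value(tp, x)
  maps <- pool_rowmaps(H, W, B)
  v <- 0.25 * (gather_rows(X, maps[[1]]) + gather_rows(X, maps[[2]]) +
               gather_rows(X, maps[[3]]) + gather_rows(X, maps[[4]]))
  n_in <- nrow(X)
  ad_push(tp, v, x, function(g) {
    g4 <- 0.25 * g
    list(scatter_rows_add(g4, maps[[1]], n_in) +
         scatter_rows_add(g4, maps[[2]], n_in) +
         scatter_rows_add(g4, maps[[3]], n_in) +
         scatter_rows_add(g4, maps[[4]], n_in))
  })
}

op_upsample2 <- function(tp, x, H, W, B) {
  X <- ad_value(tp, x)
  rows <- upsample_rowmap(H, W, B)
  n_in <- nrow(X)
  ad_push(tp, gather_rows(X, rows), x, function(g) {
    list(scatter_rows_add(g, rows, n_in))
  })
}

# broadcast a per-sample row (B x C) to all hw pixels of each sample
op_broadcast_rows <- function(tp, x, hw) {
  X <- ad_value(tp, x)
  B <- nrow(X)
  grp <- rep(seq_len(B), each = hw)
  ad_push(tp, X[grp, , drop = FALSE], x, function(g) {
    list(rowsum(g, grp, reorder = TRUE))
  })
}

# group normalization with per-channel affine parameters (fused kernels)
op_groupnorm <- function(tp, x, gamma, beta, groups, hw, eps = 1e-5) {
  X <- ad_value(tp, x)
  C <- ncol(X)
  grp <- rep(seq_len(groups), each = C %/% groups)
  gm <- ad_value(tp, gamma); bt <- ad_value(tp, beta)
  f <- gn_fwd(X, hw, grp, groups, gm, bt, eps)
  ad_push(tp, f$y, c(x, gamma, beta), function(g) {
    bw <- gn_bwd(g, f$xhat, f$sinv, hw, grp, groups, gm)
    list(bw$dx, bw$dgamma, bw$dbeta)
  })
}

# single-head spatial self-attention, per sample (no residual: callers add the
# output back onto the un-normalized activation themselves)
op_attention <- function(tp, x, wq, wk, wv, wo, hw) {
  X <- ad_value(tp, x)
  Wq <- ad_value(tp, wq); Wk <- ad_value(tp, wk)
  Wv <- ad_value(tp, wv); Wo <- ad_value(tp, wo)
  C <- ncol(X); B <- nrow(X) %/% hw
  sc <- 1 / sqrt(C)
  cache <- vector("list", B)
  Y <- X
  for (b in seq_len(B)) {
    rb <- ((b - 1L) * hw + 1L):(b * hw)
    Xb <- X[rb, , drop = FALSE]
    Q <- Xb %*% Wq; K <- Xb %*% Wk; V <- Xb %*% Wv
    S <- (Q %*% t(K)) * sc
    A <- exp(S - apply(S, 1, max))
    A <- A / rowSums(A)
    Hd <- A %*% V
    Y[rb, ] <- Hd %*% Wo
    cache[[b]] <- list(Xb = Xb, Q = Q, K = K, V = V, A = A, Hd = Hd)
  }
  ad_push(tp, Y, c(x, wq, wk, wv, wo), function(g) {
    dX <- matrix(0, nrow(X), C)
    dWq <- matrix(0, C, C); dWk <- matrix(0, C, C)
    dWv <- matrix(0, C, C); dWo <- matrix(0, C, C)
    for (b in seq_len(B)) {
      rb <- ((b - 1L) * hw + 1L):(b * hw)
      cb <- cache[[b]]
      Gb <- g[rb, , drop = FALSE]
      dWo <- dWo + crossprod(cb$Hd, Gb)
      dHd <- Gb %*% t(Wo)
      dA <- dHd %*% t(cb$V)
      dV <- crossprod(cb$A, dHd)
      dS <- cb$A * (dA - rowSums(dA * cb$A)) * sc
      dQ <- dS %*% cb$K
      dK <- crossprod(dS, cb$Q)
      dX[rb, ] <- dX[rb, ] + dQ %*% t(Wq) + dK %*% t(Wk) + dV %*% t(Wv)
      dWq <- dWq + crossprod(cb$Xb, dQ)
      dWk <- dWk + crossprod(cb$Xb, dK)
      dWv <- dWv + crossprod(cb$Xb, dV)
    }
    list(dX, dWq, dWk, dWv, dWo)
  })
}

# ---- optimizer --------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       step = 0L)
}

adam_update <- function(params, grads, state, lr = 1e-3,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$step <- state$step + 1L
  bc1 <- 1 - beta1^state$step
  bc2 <- 1 - beta2^state$step
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}
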