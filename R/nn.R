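# Internal neural-network engine.
#
# Implements the forward pass, exact backpropagation and Adam updates for the
# conv + multi-head self-attention pair classifier in plain matrix algebra.
# Batches are stored as 3-d arrays X[b, t, c] (sample, position, channel);
# reshapes below rely on R's column-major layout, so the sample index is
# always the fastest-varying one.

# ---- shape bookkeeping -------------------------------------------------

nn_dims <- function(config) {
  L <- config$input_len
  k <- config$kernel_size
  p <- config$pool_size
  chans <- 4L
  convs <- vector("list", config$conv_layers)
  for (i in seq_len(config$conv_layers)) {
    if (L < k) stop("conv layer ", i, ": kernel (", k,
                    ") wider than its input (", L, ")", call. = FALSE)
    Lc <- L - k + 1L
    Lp <- Lc %/% p
    if (Lp < 1L) stop("conv layer ", i, ": pooling leaves no positions",
                      call. = FALSE)
    convs[[i]] <- list(in_len = L, in_ch = chans, conv_len = Lc, out_len = Lp)
    L <- Lp
    chans <- config$conv_filters
  }
  list(convs = convs, n_tokens = L, d_model = config$conv_filters)
}

# ---- parameter init ----------------------------------------------------

nn_init <- function(config) {
  dims <- nn_dims(config)
  d <- dims$d_model
  use_bn <- isTRUE(config$batchnorm)
  conv <- lapply(dims$convs, function(cd) {
    fan_in <- config$kernel_size * cd$in_ch
    p <- list(W = matrix(stats::rnorm(fan_in * d, sd = sqrt(2 / fan_in)),
                         fan_in, d),
              b = numeric(d))
    if (use_bn) {
      p$gamma <- rep(1, d)
      p$beta <- numeric(d)
    }
    p
  })
  bn_run <- if (use_bn)
    lapply(dims$convs, function(cd) list(mean = numeric(d), var = rep(1, d)))
  xav <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(1 / nr)), nr, nc)
  attn <- replicate(config$transformer_blocks, list(
    Wq = xav(d, d), Wk = xav(d, d), Wv = xav(d, d), Wo = xav(d, d)
  ), simplify = FALSE)
  n_flat <- if (identical(config$head_pooling, "global")) 2L * d
            else dims$n_tokens * d
  H <- config$head_hidden
  if (H > 0) {
    dense <- list(
      W1 = matrix(stats::rnorm(n_flat * H, sd = sqrt(2 / n_flat)), n_flat, H),
      b1 = numeric(H),
      w = matrix(stats::rnorm(H, sd = sqrt(1 / H)), H, 1),
      b = 0)
  } else {
    dense <- list(
      w = matrix(stats::rnorm(n_flat, sd = sqrt(1 / n_flat)), n_flat, 1),
      b = 0)
  }
  list(conv = conv, attn = attn, dense = dense, bn_run = bn_run,
       dims = dims)
}

# ---- primitive layers --------------------------------------------------
# Convolution (im2col + GEMM), max pooling and batched attention run in
# compiled code (src/nn_kernels.cpp); these wrappers keep the engine's
# array contracts in one place.

# Cross-correlation of a C-channel sequence batch with a filter bank,
# i.e. the double sum S_ij = sum_u sum_v W_uv X_{i-u+1, j-v+1} evaluated at
# every valid offset, one output channel per filter.
nn_conv_fwd <- function(X, W, b, k, want_cache = TRUE) {
  cpp_conv_fwd(X, W, as.numeric(b), as.integer(k), isTRUE(want_cache))
}

nn_conv_bwd <- function(dY, cache, W, k, B, L, C, want_dx = TRUE) {
  cpp_conv_bwd(dY, cache$Xc, W, as.integer(k), as.integer(B),
               as.integer(L), as.integer(C), isTRUE(want_dx))
}

nn_relu_fwd <- function(Y) {
  mask <- Y > 0
  Y[!mask] <- 0
  list(Y = Y, mask = mask)
}

# Non-overlapping max pooling over the position axis; trailing remainder
# positions are dropped (floor semantics).
nn_pool_fwd <- function(Y, p) {
  cpp_pool_fwd(Y, as.integer(p))
}

nn_pool_bwd <- function(dM, cache, p) {
  cpp_pool_bwd(dM, cache$which_j, as.integer(p), as.integer(cache$in_len))
}

# Sinusoidal positional encoding, n tokens x d dims.
nn_pos_encoding <- function(n, d) {
  pos <- matrix(seq_len(n) - 1, n, d)
  i2 <- matrix(rep(floor((seq_len(d) - 1) / 2) * 2, each = n), n, d)
  ang <- pos / (10000^(i2 / d))
  out <- ang
  even <- rep(seq_len(d) %% 2 == 1, each = n)  # dims 1,3,... (0-based even)
  out[even] <- sin(ang[even])
  out[!even] <- cos(ang[!even])
  out
}

nn_softmax_rows <- function(Z) {
  Z <- Z - Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  E <- exp(Z)
  E / rowSums(E)
}

# Batch normalisation (fused with ReLU in compiled code): training mode
# normalises with batch statistics and updates running moments; inference
# mode applies the stored affine map, keeping prediction deterministic.

# Multi-head scaled dot-product self-attention on one sample (Tn x d),
# heads carved out of contiguous column blocks, with residual connection.
nn_attn_fwd_one <- function(S, pars, n_heads) {
  d <- ncol(S); dk <- d / n_heads
  Q <- S %*% pars$Wq; K <- S %*% pars$Wk; V <- S %*% pars$Wv
  O <- matrix(0, nrow(S), d)
  A <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    Ah <- nn_softmax_rows(Q[, idx, drop = FALSE] %*%
                            t(K[, idx, drop = FALSE]) / sqrt(dk))
    A[[h]] <- Ah
    O[, idx] <- Ah %*% V[, idx, drop = FALSE]
  }
  list(out = O %*% pars$Wo + S, S = S, Q = Q, K = K, V = V, O = O, A = A)
}

nn_attn_bwd_one <- function(dOut, cache, pars, n_heads, grads) {
  d <- ncol(cache$S); dk <- d / n_heads
  dS <- dOut                       # residual path
  grads$Wo <- grads$Wo + crossprod(cache$O, dOut)
  dO <- dOut %*% t(pars$Wo)
  dQ <- matrix(0, nrow(cache$S), d)
  dK <- dQ; dV <- dQ
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    Ah <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    dAh <- dOh %*% t(Vh)
    dV[, idx] <- crossprod(Ah, dOh)
    dZ <- (dAh - rowSums(dAh * Ah)) * Ah
    dQ[, idx] <- dZ %*% cache$K[, idx, drop = FALSE] / sqrt(dk)
    dK[, idx] <- crossprod(dZ, cache$Q[, idx, drop = FALSE]) / sqrt(dk)
  }
  grads$Wq <- grads$Wq + crossprod(cache$S, dQ)
  grads$Wk <- grads$Wk + crossprod(cache$S, dK)
  grads$Wv <- grads$Wv + crossprod(cache$S, dV)
  dS <- dS + dQ %*% t(pars$Wq) + dK %*% t(pars$Wk) + dV %*% t(pars$Wv)
  list(dS = dS, grads = grads)
}

# ---- full network ------------------------------------------------------

# Forward pass. X: (B, L, 4). Returns probabilities and, if keep_cache,
# everything needed for the backward pass.  Dropout (inverted scaling on the
# flattened representation) is applied only when training = TRUE, drawing
# from the current RNG stream.
nn_forward <- function(params, X, config, training = FALSE, keep_cache = FALSE) {
  B <- dim(X)[1]
  dims <- params$dims
  cache <- list(X = X, conv = vector("list", length(params$conv)))
  use_bn <- isTRUE(config$batchnorm)
  bn_run <- params$bn_run
  A <- X
  for (i in seq_along(params$conv)) {
    cf <- nn_conv_fwd(A, params$conv[[i]]$W, params$conv[[i]]$b,
                      config$kernel_size, want_cache = keep_cache)
    bn_cache <- NULL
    if (use_bn) {
      bnf <- cpp_bn_relu_fwd(cf$Y, params$conv[[i]]$gamma,
                             params$conv[[i]]$beta, bn_run[[i]]$mean,
                             bn_run[[i]]$var, training, 0.9, 1e-5)
      act <- bnf$Y
      bn_run[[i]] <- list(mean = as.numeric(bnf$run_mean),
                          var = as.numeric(bnf$run_var))
      bn_cache <- list(Xhat = bnf$Xhat, istd = as.numeric(bnf$istd),
                       training = training)
    } else {
      act <- cf$Y
      act[act < 0] <- 0
    }
    pl <- nn_pool_fwd(act, config$pool_size)
    cache$conv[[i]] <- list(Xc = cf$Xc, act = act, pool = pl,
                            in_dim = dim(A), bn_cache = bn_cache)
    A <- pl$Y
  }
  pe <- nn_pos_encoding(dims$n_tokens, dims$d_model) *
    (config$pe_scale %||% 1)
  cache$attn <- vector("list", length(params$attn))
  for (bl in seq_along(params$attn)) {
    if (bl == 1L && config$pe_scale > 0)
      A <- A + rep(pe, each = B)  # broadcast over samples
    pp <- params$attn[[bl]]
    fw <- cpp_attn_fwd(A, pp$Wq, pp$Wk, pp$Wv, pp$Wo, config$n_heads,
                       keep_cache)
    fw$A_in <- A
    cache$attn[[bl]] <- fw
    A <- fw$out
  }
  if (identical(config$head_pooling, "global")) {
    # per-channel max + mean over tokens: a position-tolerant readout
    d <- dims$d_model
    flat <- matrix(0, B, 2L * d)
    amax <- matrix(0L, B, d)
    for (f in seq_len(d)) {
      Af <- A[, , f, drop = TRUE]
      if (is.null(dim(Af))) Af <- matrix(Af, B, dims$n_tokens)
      mi <- max.col(Af, ties.method = "first")
      amax[, f] <- mi
      flat[, f] <- Af[cbind(seq_len(B), mi)]
      flat[, d + f] <- rowMeans(Af)
    }
    cache$pool_argmax <- amax
  } else {
    flat <- A
    dim(flat) <- c(B, dims$n_tokens * dims$d_model)
  }
  if (training && config$dropout > 0) {
    keep <- 1 - config$dropout
    mask <- matrix(stats::runif(length(flat)) < keep, nrow(flat), ncol(flat))
    flat_d <- flat * mask / keep
    cache$drop_mask <- mask
  } else {
    flat_d <- flat
  }
  cache$flat <- flat
  cache$flat_d <- flat_d
  if (!is.null(params$dense$W1)) {
    H1 <- flat_d %*% params$dense$W1
    H1 <- sweep(H1, 2, params$dense$b1, "+")
    hmask <- H1 > 0
    H1[!hmask] <- 0
    cache$head <- list(H1 = H1, mask = hmask)
    logit <- drop(H1 %*% params$dense$w) + params$dense$b
  } else {
    logit <- drop(flat_d %*% params$dense$w) + params$dense$b
  }
  prob <- 1 / (1 + exp(-logit))
  out <- list(prob = prob, logit = logit, bn_run = bn_run)
  if (keep_cache) out$cache <- cache
  out
}

nn_zero_grads <- function(params) {
  list(
    conv = lapply(params$conv, function(p) lapply(p, function(x) x * 0)),
    attn = lapply(params$attn, function(p) lapply(p, function(x) x * 0)),
    dense = lapply(params$dense, function(p) p * 0)
  )
}

# Backward pass from d(loss)/d(logit).  Returns parameter gradients and,
# when want_dx, the gradient with respect to the one-hot input (used by the
# attribution module).
nn_backward <- function(params, cache, dlogit, config, want_dx = FALSE) {
  dims <- params$dims
  B <- dim(cache$X)[1]
  g <- nn_zero_grads(params)
  if (!is.null(params$dense$W1)) {
    g$dense$w <- crossprod(cache$head$H1, matrix(dlogit, B, 1))
    g$dense$b <- sum(dlogit)
    dH1 <- matrix(dlogit, B, 1) %*% t(params$dense$w)
    dH1[!cache$head$mask] <- 0
    g$dense$W1 <- crossprod(cache$flat_d, dH1)
    g$dense$b1 <- colSums(dH1)
    dflat <- dH1 %*% t(params$dense$W1)
  } else {
    g$dense$w <- crossprod(cache$flat_d, matrix(dlogit, B, 1))
    g$dense$b <- sum(dlogit)
    dflat <- matrix(dlogit, B, 1) %*% t(params$dense$w)
  }
  if (!is.null(cache$drop_mask)) {
    keep <- 1 - config$dropout
    dflat <- dflat * cache$drop_mask / keep
  }
  if (identical(config$head_pooling, "global")) {
    d <- dims$d_model
    Tn <- dims$n_tokens
    dA <- array(0, c(B, Tn, d))
    for (f in seq_len(d)) {
      dA[cbind(seq_len(B), cache$pool_argmax[, f], f)] <- dflat[, f]
      dA[, , f] <- dA[, , f] + dflat[, d + f] / Tn
    }
  } else {
    dA <- dflat
    dim(dA) <- c(B, dims$n_tokens, dims$d_model)
  }
  for (bl in rev(seq_along(params$attn))) {
    cc <- cache$attn[[bl]]
    pp <- params$attn[[bl]]
    bw <- cpp_attn_bwd(dA, cc$A_in, cc$Q, cc$K, cc$V, cc$O, cc$Attn,
                       pp$Wq, pp$Wk, pp$Wv, pp$Wo, config$n_heads)
    g$attn[[bl]] <- list(Wq = bw$dWq, Wk = bw$dWk, Wv = bw$dWv,
                         Wo = bw$dWo)
    dA <- bw$dA
  }
  for (i in rev(seq_along(params$conv))) {
    cc <- cache$conv[[i]]
    dY <- nn_pool_bwd(dA, cc$pool, config$pool_size)
    if (!is.null(cc$bn_cache)) {
      bnb <- cpp_bn_relu_bwd(dY, cc$bn_cache$Xhat, cc$bn_cache$istd,
                             cc$act, params$conv[[i]]$gamma,
                             cc$bn_cache$training)
      g$conv[[i]]$gamma <- as.numeric(bnb$dgamma)
      g$conv[[i]]$beta <- as.numeric(bnb$dbeta)
      dY <- bnb$dX
    } else {
      dY[cc$act <= 0] <- 0
    }
    # dX of the first layer is only needed for attribution
    dx_here <- i > 1L || want_dx
    bw <- nn_conv_bwd(dY, cc, params$conv[[i]]$W, config$kernel_size,
                      cc$in_dim[1], cc$in_dim[2], cc$in_dim[3],
                      want_dx = dx_here)
    g$conv[[i]]$W <- bw$dW
    g$conv[[i]]$b <- as.numeric(bw$db)
    dA <- if (dx_here) bw$dX else NULL
  }
  if (want_dx) g$dX <- dA
  g
}

# Gradient of the output (probability or logit) w.r.t. the one-hot input.
nn_input_grad <- function(params, X, config, wrt = c("prob", "logit")) {
  wrt <- match.arg(wrt)
  fw <- nn_forward(params, X, config, training = FALSE, keep_cache = TRUE)
  dlogit <- if (wrt == "prob") fw$prob * (1 - fw$prob) else rep(1, dim(X)[1])
  g <- nn_backward(params, fw$cache, dlogit, config, want_dx = TRUE)
  list(dX = g$dX, prob = fw$prob)
}

# ---- optimizer ---------------------------------------------------------

nn_adam_init <- function(params) {
  zero <- nn_zero_grads(params)
  list(m = zero, v = zero, t = 0)
}

nn_adam_step <- function(params, grads, state, lr, weight_decay = 0,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         freeze = character()) {
  state$t <- state$t + 1
  t <- state$t
  # decoupled weight decay, applied to weight matrices only (nm %in% decayed)
  decayed <- c("W", "Wq", "Wk", "Wv", "Wo", "W1", "w")
  nm <- ""
  upd <- function(p, g, m, v) {
    m2 <- beta1 * m + (1 - beta1) * g
    v2 <- beta2 * v + (1 - beta2) * g * g
    mh <- m2 / (1 - beta1^t)
    vh <- v2 / (1 - beta2^t)
    p2 <- p - lr * mh / (sqrt(vh) + eps)
    if (weight_decay > 0 && nm %in% decayed) p2 <- p2 - lr * weight_decay * p
    list(p = p2, m = m2, v = v2)
  }
  if (!("conv" %in% freeze)) for (i in seq_along(params$conv)) {
    for (nm in names(params$conv[[i]])) {
      u <- upd(params$conv[[i]][[nm]], grads$conv[[i]][[nm]],
               state$m$conv[[i]][[nm]], state$v$conv[[i]][[nm]])
      params$conv[[i]][[nm]] <- u$p
      state$m$conv[[i]][[nm]] <- u$m
      state$v$conv[[i]][[nm]] <- u$v
    }
  }
  if (!("attn" %in% freeze)) for (i in seq_along(params$attn)) {
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      u <- upd(params$attn[[i]][[nm]], grads$attn[[i]][[nm]],
               state$m$attn[[i]][[nm]], state$v$attn[[i]][[nm]])
      params$attn[[i]][[nm]] <- u$p
      state$m$attn[[i]][[nm]] <- u$m
      state$v$attn[[i]][[nm]] <- u$v
    }
  }
  if (!("dense" %in% freeze)) for (nm in names(params$dense)) {
    u <- upd(params$dense[[nm]], grads$dense[[nm]],
             state$m$dense[[nm]], state$v$dense[[nm]])
    params$dense[[nm]] <- u$p
    state$m$dense[[nm]] <- u$m
    state$v$dense[[nm]] <- u$v
  }
  list(params = params, state = state)
}
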