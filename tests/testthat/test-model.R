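test_that("conv_block equals the literal double-sum on random inputs", {
  # brute-force evaluation of S_ij = sum_u sum_v W_uv X_{i,j+v-1} over all
  # valid offsets, one output row per filter
  brute_conv <- function(x, filters) {
    k <- ncol(filters[[1]])
    out <- matrix(0, length(filters), ncol(x) - k + 1)
    for (f in seq_along(filters))
      for (j in seq_len(ncol(out))) {
        acc <- 0
        for (u in seq_len(nrow(x)))
          for (v in seq_len(k))
            acc <- acc + filters[[f]][u, v] * x[u, j + v - 1]
        out[f, j] <- acc
      }
    out
  }
  set.seed(5)
  for (rep in 1:5) {
    x <- matrix(rnorm(4 * 16), 4, 16)
    filters <- replicate(3, matrix(rnorm(12), 4, 3), simplify = FALSE)
    expect_equal(conv_block(x, filters), brute_conv(x, filters),
                 tolerance = 1e-6)
  }
})

test_that("conv_block: all-ones filter sums windows; zero input; ramp pooling", {
  set.seed(6)
  x <- matrix(rnorm(40), 4, 10)
  ones <- list(matrix(1, 4, 3))
  out <- conv_block(x, ones)
  expect_equal(dim(out), c(1, 8))
  for (j in 1:8) expect_equal(out[1, j], sum(x[, j:(j + 2)]))
  expect_equal(conv_block(matrix(0, 4, 10), ones),
               matrix(0, 1, 8))
  # pooling a monotone ramp keeps the right-most element of each window
  ramp <- matrix(0, 4, 11)
  ramp[1, ] <- 1:11
  pooled <- conv_block(ramp, list(rbind(c(1), c(0), c(0), c(0))),
                       pool_size = 2)
  expect_equal(pooled[1, ], c(2, 4, 6, 8, 10))
  expect_error(conv_block(matrix(0, 4, 2), ones), "kernel width")
})

test_that("attention weights are row-stochastic and match hand-computed softmax", {
  set.seed(7)
  S <- matrix(rnorm(6 * 4), 6, 4)
  Wq <- matrix(rnorm(16), 4, 4)
  Wk <- matrix(rnorm(16), 4, 4)
  A <- attention_weights(S, Wq, Wk)
  expect_true(all(A >= 0))
  expect_equal(rowSums(A), rep(1, 6), tolerance = 1e-6)
  # identical keys -> uniform rows
  Au <- attention_weights(S, Wq, matrix(0, 4, 4))
  expect_equal(Au, matrix(1 / 6, 6, 6), tolerance = 1e-12)
  # 2-token closed form
  S2 <- rbind(c(1, 0), c(0, 1))
  Wq2 <- diag(2); Wk2 <- diag(2)
  Z <- S2 %*% t(S2) / sqrt(2)
  expect_equal(attention_weights(S2, Wq2, Wk2),
               exp(Z) / rowSums(exp(Z)), tolerance = 1e-12)
})

test_that("multi-head attention matches the per-element weighted-sum oracle", {
  set.seed(8)
  d <- 8; n <- 5; h <- 2; dk <- d / h
  S <- matrix(rnorm(n * d), n, d)
  Wq <- matrix(rnorm(d * d), d, d); Wk <- matrix(rnorm(d * d), d, d)
  Wv <- matrix(rnorm(d * d), d, d); Wo <- matrix(rnorm(d * d), d, d)
  # loop oracle: S'_i = sum_j alpha'_ij V_j per head, then concat + Wo
  O <- matrix(0, n, d)
  for (hh in 1:h) {
    idx <- ((hh - 1) * dk + 1):(hh * dk)
    Q <- S %*% Wq[, idx]; K <- S %*% Wk[, idx]; V <- S %*% Wv[, idx]
    for (i in 1:n) {
      z <- sapply(1:n, function(j) sum(Q[i, ] * K[j, ])) / sqrt(dk)
      a <- exp(z - max(z)); a <- a / sum(a)
      acc <- rep(0, dk)
      for (j in 1:n) acc <- acc + a[j] * V[j, ]
      O[i, idx] <- acc
    }
  }
  expect_equal(multi_head_attention(S, Wq, Wk, Wv, Wo, n_heads = h),
               O %*% Wo, tolerance = 1e-5)
  # h = 1 with identity projections reduces to softmax(QK^T/sqrt(d)) V
  I <- diag(d)
  Z <- S %*% t(S) / sqrt(d)
  A <- exp(Z - apply(Z, 1, max)); A <- A / rowSums(A)
  expect_equal(multi_head_attention(S, I, I, I, I, n_heads = 1),
               A %*% S, tolerance = 1e-10)
  # positionless attention is permutation-equivariant
  perm <- c(3, 1, 5, 2, 4)
  out <- multi_head_attention(S, Wq, Wk, Wv, Wo, n_heads = h)
  out_p <- multi_head_attention(S[perm, ], Wq, Wk, Wv, Wo, n_heads = h)
  expect_equal(out_p, out[perm, ], tolerance = 1e-10)
  expect_error(multi_head_attention(S, Wq, Wk, Wv, Wo, n_heads = 3),
               "divisible")
})

test_that("forward pass respects the sigmoid head contracts", {
  cfg <- ctci_config(input_len = 80, conv_filters = 8, kernel_size = 5,
                     pool_size = 2, n_heads = 2, head_hidden = 6,
                     dropout = 0, seed = 3)
  set.seed(3)
  params <- chromint:::nn_init(cfg)
  X <- array(0, c(10, 80, 4))
  for (b in 1:10) X[cbind(b, 1:80, sample(4, 80, TRUE))] <- 1
  # zeroed final layer -> sigmoid(0) = 0.5 exactly
  p0 <- params
  p0$dense$w[] <- 0; p0$dense$b <- 0
  expect_identical(chromint:::nn_forward(p0, X, cfg)$prob, rep(0.5, 10))
  # codomain and bitwise determinism at inference
  pr1 <- chromint:::nn_forward(params, X, cfg)$prob
  pr2 <- chromint:::nn_forward(params, X, cfg)$prob
  expect_true(all(pr1 >= 0 & pr1 <= 1))
  expect_identical(pr1, pr2)
})

test_that("whole-network analytic gradients match finite differences", {
  cfg <- ctci_config(input_len = 40, conv_filters = 8, kernel_size = 5,
                     pool_size = 2, n_heads = 2, head_hidden = 6,
                     dropout = 0, seed = 1)
  set.seed(1)
  params <- chromint:::nn_init(cfg)
  B <- 4
  X <- array(0, c(B, 40, 4))
  for (b in 1:B) X[cbind(b, 1:40, sample(4, 40, TRUE))] <- 1
  y <- c(1, 0, 1, 0)
  loss <- function(par) {
    p <- chromint:::nn_forward(par, X, cfg, training = TRUE)$prob
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  fw <- chromint:::nn_forward(params, X, cfg, training = TRUE,
                              keep_cache = TRUE)
  g <- chromint:::nn_backward(params, fw$cache, (fw$prob - y) / B, cfg,
                              want_dx = TRUE)
  eps <- 1e-6
  set.seed(99)
  paths <- list(
    list(get = function(p) p$conv[[1]]$W,
         set = function(p, v) { p$conv[[1]]$W[] <- v; p },
         grad = g$conv[[1]]$W),
    list(get = function(p) p$conv[[2]]$gamma,
         set = function(p, v) { p$conv[[2]]$gamma[] <- v; p },
         grad = g$conv[[2]]$gamma),
    list(get = function(p) p$attn[[1]]$Wk,
         set = function(p, v) { p$attn[[1]]$Wk[] <- v; p },
         grad = g$attn[[1]]$Wk),
    list(get = function(p) p$dense$W1,
         set = function(p, v) { p$dense$W1[] <- v; p },
         grad = g$dense$W1))
  for (pp in paths) {
    v <- pp$get(params)
    for (i in sample(length(v), 4)) {
      num <- (loss(pp$set(params, replace(v, i, v[i] + eps))) -
                loss(pp$set(params, replace(v, i, v[i] - eps)))) / (2 * eps)
      expect_equal(num, pp$grad[i], tolerance = 1e-4)
    }
  }
  # gradient w.r.t. the input (used by the attribution module)
  for (r in 1:3) {
    ijk <- c(sample(B, 1), sample(40, 1), sample(4, 1))
    Xp <- X; Xp[ijk[1], ijk[2], ijk[3]] <- Xp[ijk[1], ijk[2], ijk[3]] + eps
    Xm <- X; Xm[ijk[1], ijk[2], ijk[3]] <- Xm[ijk[1], ijk[2], ijk[3]] - eps
    lf <- function(Xa) {
      p <- chromint:::nn_forward(params, Xa, cfg, training = TRUE)$prob
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -mean(y * log(p) + (1 - y) * log(1 - p))
    }
    num <- (lf(Xp) - lf(Xm)) / (2 * eps)
    expect_equal(num, g$dX[ijk[1], ijk[2], ijk[3]], tolerance = 1e-4)
  }
})

test_that("AUC equals the brute-force concordance count", {
  # all-pairs concordance oracle
  brute_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    acc <- 0
    for (a in pos) for (b in neg)
      acc <- acc + (a > b) + 0.5 * (a == b)
    acc / (length(pos) * length(neg))
  }
  expect_equal(auc_score(c(.9, .8, .7, .6, .4, .3, .2, .1),
                         c(1, 1, 1, 1, 0, 0, 0, 0)), 1)
  s <- c(0.9, 0.8, 0.4, 0.2); y <- c(1, 0, 1, 0)
  expect_equal(auc_score(s, y), 0.75)
  expect_equal(brute_auc(s, y), 0.75)
  set.seed(12)
  for (rep in 1:5) {
    s <- round(runif(30), 2)           # rounding creates ties
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc_score(s, y), brute_auc(s, y))
    expect_equal(auc_score(-s, y), 1 - auc_score(s, y))
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(13)
    s <- runif(60); y <- rbinom(60, 1, 0.4)
    expect_equal(auc_score(s, y),
                 as.numeric(suppressMessages(
                   pROC::auc(y, s, direction = "<", levels = c(0, 1)))))
  }
  expect_error(auc_score(runif(5), rep(1, 5)), "one class")
})

test_that("training is reproducible, separates a separable task, errors on one class", {
  sc <- synth_config(n_pairs = 200L, anchor_len = 80L,
                     motif_pairs = list(c("TGACGTCATC", "CACGTGGCTA")),
                     positional_sd = 8, label_noise = 0,
                     neg_mix = c(1, 0, 0),   # background-only negatives
                     seed = 5L)
  d <- generate_pairs(sc)
  cfg <- ctci_config(input_len = 160L, kernel_size = 8L,
                     pool_size = 4L, n_heads = 2L, dropout = 0.1,
                     augment_shift = 20L, batch_size = 16L,
                     epochs = 30L, seed = 11L)
  fit1 <- ctci_fit(d$x, d$labels, cfg, validation = 0.15, patience = 30L)
  ev <- ctci_evaluate(fit1, d$x, d$labels)
  expect_gt(ev$auc, 0.95)     # linearly separable grammar -> near-perfect
  fit2 <- ctci_fit(d$x, d$labels, cfg, validation = 0.15, patience = 30L)
  expect_identical(fit1$history, fit2$history)
  expect_error(ctci_fit(d$x, rep(1, dim(d$x)[1]), cfg), "both classes")
  expect_error(ctci_fit(d$x, d$labels,
                        ctci_config(input_len = 100L)),
               "does not match")
})

test_that("shuffled labels destroy generalisation (permutation null)", {
  d <- cached_fit_data()
  set.seed(31)
  n <- dim(d$x)[1]
  y_perm <- sample(d$labels)
  tr <- 1:450; ho <- 451:n
  cfg <- ctci_config(input_len = 240L, augment_shift = 30L,
                     epochs = 15L, seed = 13L)
  fit <- ctci_fit(d$x[tr, , , drop = FALSE], y_perm[tr], cfg,
                  validation = 0)
  ev <- ctci_evaluate(fit, d$x[ho, , , drop = FALSE], y_perm[ho])
  expect_lt(abs(ev$auc - 0.5), 0.12)
})

test_that("a warm start beats a random initialisation before any training", {
  fit <- cached_fit()
  d <- cached_fit_data()
  ho <- 501:dim(d$x)[1]
  warm <- ctci_evaluate(fit, d$x[ho, , , drop = FALSE], d$labels[ho])
  cfg <- fit$config
  cfg$seed <- 99L
  set.seed(99)
  rnd <- fit
  rnd$params <- chromint:::nn_init(cfg)
  cold <- ctci_evaluate(rnd, d$x[ho, , , drop = FALSE], d$labels[ho])
  expect_gt(warm$auc, cold$auc)
  expect_gt(warm$auc, 0.8)
  expect_lt(abs(cold$auc - 0.5), 0.2)
})

test_that("fine-tuning warm-starts and freezing everything is the identity", {
  fit <- cached_fit()
  d <- cached_fit_data()
  frozen <- ctci_finetune(fit, d$x, d$labels, epochs = 0, freeze = "all")
  expect_identical(frozen$params, fit$params)
  expect_equal(nrow(frozen$history), 0)
  expect_true(frozen$warm_start)
  # one frozen-feature epoch keeps conv weights bitwise identical
  ft <- ctci_finetune(fit, d$x, d$labels, epochs = 1, freeze = "conv",
                      validation = 0.2, seed = 9L)
  expect_identical(ft$params$conv, fit$params$conv)
  expect_error(ctci_finetune(fit, array(0, c(4, 100, 4)), c(0, 1, 0, 1)),
               "width")
})

test_that("classification rule and S3 methods behave", {
  fit <- cached_fit()
  d <- cached_fit_data()
  res <- predict(fit, d$x[1:20, , , drop = FALSE], type = "both")
  expect_identical(res$label, as.integer(res$probability > 0.5))
  expect_identical(predict(fit, d$x[1:5, , , drop = FALSE]),
                   predict(fit, d$x[1:5, , , drop = FALSE]))
  expect_output(print(fit), "pair classifier")
  s <- summary(fit)
  expect_gt(s$n_parameters, 1000)
  expect_length(coef(fit)$conv, 2)
  r <- residuals(fit)
  expect_equal(length(r), fit$n_train)
  sim <- simulate(fit, nsim = 2, seed = 4,
                  newdata = d$x[1:10, , , drop = FALSE])
  expect_equal(dim(sim), c(10, 2))
  expect_true(all(unlist(sim) %in% 0:1))
  f <- tempfile(fileext = ".rds")
  ctci_save(fit, f)
  expect_identical(ctci_load(f)$params, fit$params)
})
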