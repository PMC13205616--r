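#' Model configuration for the sequence pair classifier
#'
#' Builds the hyperparameter set of the conv + transformer classifier.  Two
#' presets are provided: `"simple"`, a small configuration sized for
#' desk-scale experiments and used throughout the test suite (2 conv+pool
#' blocks of 16 filters, one transformer block of 4 heads), and
#' `"reported"`, which mirrors the published genome-scale settings (64
#' filters of width 8, learning rate 1e-4, dropout 0.3, batch size 64).
#' Every field can be overridden individually.
#'
#' @param input_len width of the one-hot input: 6000 for promoter-promoter
#'   (PPI) pairs, 3000 for promoter-distal (PDI) pairs, or any custom width
#'   for synthetic data.
#' @param preset `"simple"` or `"reported"`.
#' @param conv_filters number of convolutional filters per layer; also the
#'   token dimension entering the transformer block.
#' @param kernel_size convolution filter width (bp).
#' @param pool_size non-overlapping max-pool window after each conv layer.
#' @param conv_layers number of conv+pool blocks.
#' @param transformer_blocks number of self-attention blocks.
#' @param n_heads attention heads; must divide `conv_filters`.
#' @param head_hidden width of the hidden layer in the fully connected
#'   classification head (0 = a single linear layer straight to the sigmoid
#'   output).
#' @param head_pooling how the transformer output feeds the head:
#'   `"global"` (per-channel max + mean over tokens, the `"simple"` preset
#'   default -- position-tolerant and far less prone to memorisation at
#'   small sample sizes) or `"flatten"` (the full token x channel vector,
#'   the `"reported"` preset default).
#' @param batchnorm apply batch normalisation after each convolution
#'   (batch statistics during training, stored running moments at
#'   inference).
#' @param augment_shift training-time augmentation: each anchor half of
#'   every minibatch sample is circularly shifted by an independent
#'   uniform offset in `[-augment_shift, augment_shift]` bp (0 disables).
#'   Shift augmentation is standard practice for sequence CNNs at small
#'   sample sizes; it suppresses position-specific memorisation.
#' @param pe_scale amplitude of the sinusoidal positional encoding added
#'   before the transformer block, relative to the (batch-normalised)
#'   feature scale; 0 disables it.  Kept well below 1 so position
#'   information does not swamp sequence content.
#' @param dropout dropout rate on the flattened representation (training
#'   only).
#' @param learning_rate Adam learning rate.
#' @param weight_decay decoupled weight decay applied to weight matrices
#'   (not biases or batch-norm parameters).
#' @param batch_size minibatch size (`"simple"` 16 -- small batches give
#'   the many SGD steps that desk-scale sample sizes need; `"reported"`
#'   64, the published value).
#' @param epochs maximum training epochs.
#' @param seed integer seed controlling weight init, shuffling and dropout.
#' @param threshold probability cutoff for calling an interaction (label 1
#'   iff probability > threshold).
#' @param stage_depths,channel_dims metadata describing the published
#'   stage-wise depth configuration \{4,4,8,6\} and channel dimensions;
#'   retained for provenance but the executable stack is driven by
#'   `conv_layers`/`conv_filters` (see the methods vignette for why the
#'   printed channel table cannot be mapped onto a 4-channel one-hot input
#'   unambiguously).
#' @return object of class `ctci_config` (a named list).
#' @export
ctci_config <- function(input_len = 3000L,
                        preset = c("simple", "reported"),
                        conv_filters = NULL, kernel_size = 8L,
                        pool_size = NULL, conv_layers = 2L,
                        transformer_blocks = 1L, n_heads = 4L,
                        head_hidden = 32L, head_pooling = NULL,
                        batchnorm = TRUE, pe_scale = 0.1,
                        augment_shift = NULL,
                        dropout = 0.3, learning_rate = NULL,
                        weight_decay = 1e-3,
                        batch_size = NULL, epochs = NULL, seed = 1L,
                        threshold = 0.5,
                        stage_depths = c(4L, 4L, 8L, 6L),
                        channel_dims = c(1L, 64L, 128L, 256L, 128L, 64L, 4L)) {
  preset <- match.arg(preset)
  if (is.null(conv_filters))
    conv_filters <- if (preset == "simple") 16L else 64L
  if (is.null(pool_size))
    pool_size <- if (preset == "simple") 4L else 2L
  if (is.null(learning_rate))
    learning_rate <- if (preset == "simple") 3e-3 else 1e-4
  if (is.null(head_pooling))
    head_pooling <- if (preset == "simple") "global" else "flatten"
  head_pooling <- match.arg(head_pooling, c("global", "flatten"))
  if (is.null(batch_size))
    batch_size <- if (preset == "simple") 16L else 64L
  if (is.null(epochs))
    epochs <- if (preset == "simple") 60L else 20L
  if (is.null(augment_shift))
    augment_shift <- if (preset == "simple") 100L else 0L
  cfg <- list(input_len = as.integer(input_len), preset = preset,
              conv_filters = as.integer(conv_filters),
              kernel_size = as.integer(kernel_size),
              pool_size = as.integer(pool_size),
              conv_layers = as.integer(conv_layers),
              transformer_blocks = as.integer(transformer_blocks),
              n_heads = as.integer(n_heads),
              head_hidden = as.integer(head_hidden),
              head_pooling = head_pooling,
              batchnorm = isTRUE(batchnorm), pe_scale = pe_scale,
              augment_shift = as.integer(augment_shift),
              dropout = dropout,
              learning_rate = learning_rate,
              weight_decay = weight_decay,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), seed = as.integer(seed),
              threshold = threshold, stage_depths = stage_depths,
              channel_dims = channel_dims)
  if (cfg$conv_filters %% cfg$n_heads != 0)
    stop("conv_filters (token dimension) must be divisible by n_heads",
         call. = FALSE)
  if (cfg$dropout < 0 || cfg$dropout >= 1)
    stop("dropout must be in [0, 1)", call. = FALSE)
  if (cfg$threshold <= 0 || cfg$threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  class(cfg) <- "ctci_config"
  cfg
}

#' @export
print.ctci_config <- function(x, ...) {
  cat("Pair-classifier configuration (preset: ", x$preset, ")\n", sep = "")
  cat("  input width      ", x$input_len, "bp\n")
  cat("  conv             ", x$conv_layers, "x [", x$conv_filters,
      "filters, kernel", x$kernel_size, ", pool", x$pool_size, "]\n")
  cat("  transformer      ", x$transformer_blocks, "block(s),",
      x$n_heads, "heads\n")
  cat("  training         lr", x$learning_rate, ", batch", x$batch_size,
      ", dropout", x$dropout, ", epochs", x$epochs, "\n")
  cat("  decision rule    interaction iff p >", x$threshold, "\n")
  invisible(x)
}

# ---- input coercion ----------------------------------------------------

# Accepts: a 3-d array (B, L, 4); a list of 4xL matrices (rows A,T,G,C) or
# of encoded-pair objects.  Returns (B, L, 4) with channels in A,T,G,C
# order.
as_input_array <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) return(x)
  if (is.list(x)) {
    mats <- lapply(x, function(el) {
      if (inherits(el, "ctci_encoded")) el$matrix else el
    })
    L <- unique(vapply(mats, ncol, 1L))
    if (length(L) != 1)
      stop("encoded pairs have differing widths: ",
           paste(L, collapse = ", "), call. = FALSE)
    X <- array(0, c(length(mats), L, 4L))
    for (i in seq_along(mats)) X[i, , ] <- t(mats[[i]])
    return(X)
  }
  stop("cannot interpret input as a batch of encoded pairs", call. = FALSE)
}

# ---- exported architectural primitives ---------------------------------

#' Convolution + max-pooling block on a one-hot matrix
#'
#' Cross-correlates a 4 x L one-hot (or feature) matrix with a bank of
#' filters -- the double sum \eqn{S_{ij} = \sum_u \sum_v W_{uv}
#' X_{i-u+1,j-v+1}} evaluated at every valid offset -- then optionally
#' applies an activation and non-overlapping max-pooling along positions.
#' Output width is `floor((L - kernel + 1) / pool_size)`.
#'
#' @param x channels x L numeric matrix (rows are input channels).
#' @param filters list of channels x kernel matrices, one per filter.
#' @param pool_size max-pool window (1 = no pooling).
#' @param bias numeric vector, one per filter (default 0).
#' @param activation `"linear"` or `"relu"`.
#' @return filters x output-width matrix.
#' @export
conv_block <- function(x, filters, pool_size = 1L, bias = NULL,
                       activation = c("linear", "relu")) {
  activation <- match.arg(activation)
  stopifnot(is.matrix(x), is.list(filters), length(filters) >= 1)
  C <- nrow(x); L <- ncol(x)
  k <- ncol(filters[[1]])
  if (k > L)
    stop("kernel width ", k, " exceeds input width ", L, call. = FALSE)
  if (any(vapply(filters, function(f) !all(dim(f) == c(C, k)), TRUE)))
    stop("all filters must be ", C, " x ", k, " matrices", call. = FALSE)
  if (is.null(bias)) bias <- numeric(length(filters))
  W <- matrix(0, k * C, length(filters))
  for (f in seq_along(filters))
    for (j in seq_len(k))
      W[((j - 1) * C + 1):(j * C), f] <- filters[[f]][, j]
  X <- array(0, c(1L, L, C)); X[1, , ] <- t(x)
  out <- nn_conv_fwd(X, W, bias, k)$Y
  if (activation == "relu") out[out < 0] <- 0
  if (pool_size > 1L) out <- nn_pool_fwd(out, as.integer(pool_size))$Y
  Y <- matrix(0, length(filters), dim(out)[2])
  for (f in seq_along(filters)) Y[f, ] <- out[1, , f]
  Y
}

#' Self-attention weight matrix
#'
#' Computes the row-normalised attention weights
#' \eqn{\alpha'_{ij} = \exp(\alpha_{ij}) / \sum_j \exp(\alpha_{ij})} with
#' scores \eqn{\alpha = Q K^\top / \sqrt{d_k}}, \eqn{Q = S W^Q},
#' \eqn{K = S W^K}.  Every row is non-negative and sums to one.
#'
#' @param S tokens x d feature matrix.
#' @param Wq,Wk d x d_k projection matrices.
#' @return tokens x tokens weight matrix.
#' @export
attention_weights <- function(S, Wq, Wk) {
  stopifnot(is.matrix(S), nrow(S) >= 1)
  Q <- S %*% Wq; K <- S %*% Wk
  nn_softmax_rows(Q %*% t(K) / sqrt(ncol(Q)))
}

#' Multi-head self-attention
#'
#' Applies scaled dot-product attention head-wise (heads are contiguous
#' column blocks of the projections), concatenates the head outputs and
#' projects with `Wo`.  With one head and identity projections this reduces
#' to `softmax(Q K^T / sqrt(d_k)) V`.
#'
#' @param S tokens x d feature matrix.
#' @param Wq,Wk,Wv,Wo d x d projection matrices.
#' @param n_heads number of heads; must divide d.
#' @param residual add the input back to the output (as in the full model).
#' @return tokens x d output matrix.
#' @export
multi_head_attention <- function(S, Wq, Wk, Wv, Wo, n_heads = 1L,
                                 residual = FALSE) {
  d <- ncol(S)
  if (d %% n_heads != 0)
    stop("token dimension ", d, " not divisible by n_heads ", n_heads,
         call. = FALSE)
  pars <- list(Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo)
  out <- nn_attn_fwd_one(S, pars, n_heads)$out
  if (!residual) out <- out - S
  out
}

# ---- metrics -----------------------------------------------------------

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney formulation with midranks for ties; equals the proportion of
#' concordant positive/negative score pairs (ties counted 1/2).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: only one class present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

aupr_score <- function(scores, labels) {
  labels <- as.integer(labels)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  prec <- cumsum(y) / seq_along(y)
  sum(prec[y == 1]) / sum(y)
}

# ---- training ----------------------------------------------------------

#' Fit the sequence pair classifier
#'
#' Trains the conv + multi-head self-attention classifier on labelled
#' encoded pairs by minimising binary cross-entropy with Adam.  All
#' randomness (weight initialisation, the stratified validation split,
#' epoch shuffling, dropout) derives from `config$seed`, so a fixed seed and
#' fixed data reproduce the run exactly.  Training stops early when the
#' validation AUC has not improved for `patience` epochs; the weights of the
#' best validation epoch are kept.
#'
#' @param x encoded pairs: a `(B, L, 4)` array, or a list of 4 x L one-hot
#'   matrices (rows A,T,G,C) or of [encode_pair()] results.
#' @param y 0/1 labels, one per pair.
#' @param config a [ctci_config()]; `input_len` must match the pair width.
#' @param validation fraction held out (stratified) for early stopping;
#'   0 disables validation and early stopping.
#' @param patience epochs without validation-AUC improvement before
#'   stopping; default `Inf` (run all epochs, keep the best-validation
#'   weights).  Learning on planted-motif tasks often only takes off
#'   after a dozen epochs, so small patience values stop too early.
#' @param verbose print one line per epoch.
#' @param init optional parameter list to warm-start from (used by
#'   [ctci_finetune()]).
#' @param freeze character vector among `"conv"`, `"attn"`, `"dense"` whose
#'   parameters are held fixed.
#' @return object of class `ctci_fit` with elements `params` (weights),
#'   `config`, `history` (per-epoch loss and validation AUC), `best_epoch`,
#'   and provenance (`seed`, `n_train`, `data_fingerprint`).
#' @seealso [predict.ctci_fit()], [ctci_evaluate()], [ctci_finetune()]
#' @export
ctci_fit <- function(x, y, config = ctci_config(), validation = 0.1,
                     patience = Inf, verbose = FALSE, init = NULL,
                     freeze = character()) {
  X <- as_input_array(x)
  y <- as.numeric(y)
  B <- dim(X)[1]
  stopifnot(length(y) == B)
  if (dim(X)[2] != config$input_len)
    stop("input width ", dim(X)[2], " does not match config$input_len ",
         config$input_len, call. = FALSE)
  if (length(unique(y)) < 2)
    stop("training requires both classes to be present", call. = FALSE)

  set.seed(config$seed)
  params <- if (is.null(init)) nn_init(config) else init

  # stratified validation split
  if (validation > 0) {
    idx1 <- which(y == 1); idx0 <- which(y == 0)
    v1 <- sample(idx1, max(1, round(validation * length(idx1))))
    v0 <- sample(idx0, max(1, round(validation * length(idx0))))
    val_idx <- sort(c(v1, v0))
    tr_idx <- setdiff(seq_len(B), val_idx)
  } else {
    tr_idx <- seq_len(B); val_idx <- integer()
  }
  Xtr <- X[tr_idx, , , drop = FALSE]; ytr <- y[tr_idx]
  Xval <- X[val_idx, , , drop = FALSE]; yval <- y[val_idx]

  state <- nn_adam_init(params)
  ntr <- length(tr_idx)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_auc = numeric())
  best_auc <- -Inf; best_params <- params; best_epoch <- 0L; stall <- 0L

  for (ep in seq_len(config$epochs)) {
    ord <- sample(ntr)
    tot_loss <- 0; nb <- 0
    for (st in seq(1, ntr, by = config$batch_size)) {
      bi <- ord[st:min(st + config$batch_size - 1, ntr)]
      Xb <- Xtr[bi, , , drop = FALSE]; yb <- ytr[bi]
      if (config$augment_shift > 0)
        Xb <- shift_augment(Xb, config$augment_shift)
      fw <- nn_forward(params, Xb, config, training = TRUE,
                       keep_cache = TRUE)
      params$bn_run <- fw$bn_run
      p <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
      tot_loss <- tot_loss - mean(yb * log(p) + (1 - yb) * log(1 - p))
      nb <- nb + 1
      dlogit <- (fw$prob - yb) / length(yb)
      g <- nn_backward(params, fw$cache, dlogit, config)
      stp <- nn_adam_step(params, g, state, config$learning_rate,
                          weight_decay = config$weight_decay,
                          freeze = freeze)
      params <- stp$params; state <- stp$state
    }
    val_auc <- NA_real_
    if (length(val_idx) > 1 && length(unique(yval)) == 2) {
      pv <- nn_predict(params, Xval, config)
      val_auc <- auc_score(pv, yval)
      if (val_auc > best_auc + 1e-9) {
        best_auc <- val_auc; best_params <- params
        best_epoch <- ep; stall <- 0L
      } else stall <- stall + 1L
    } else {
      best_params <- params; best_epoch <- ep
    }
    history <- rbind(history, data.frame(epoch = ep, loss = tot_loss / nb,
                                         val_auc = val_auc))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val AUC %s", ep,
                      tot_loss / nb,
                      ifelse(is.na(val_auc), "-", sprintf("%.3f", val_auc))))
    if (!is.na(val_auc) && stall >= patience) break
  }

  fitted_tr <- nn_predict(best_params, Xtr, config)
  structure(list(params = best_params, config = config, history = history,
                 fitted_values = fitted_tr, y_train = ytr,
                 best_epoch = best_epoch,
                 val_auc = if (is.finite(best_auc)) best_auc else NA_real_,
                 seed = config$seed, n_train = ntr,
                 data_fingerprint = sprintf("n=%d;L=%d;sum=%.6g", B,
                                            dim(X)[2], sum(X))),
            class = "ctci_fit")
}

# Training-time augmentation: circularly shift each anchor half of every
# sample by an independent uniform offset in [-s, s].  Destroys absolute
# positions (and with them position-specific memorisation) while keeping
# motif content intact except at the wrap seam.
shift_augment <- function(X, s) {
  cpp_shift_augment(X, as.integer(s))
}

nn_predict <- function(params, X, config, chunk = 256L) {
  B <- dim(X)[1]
  out <- numeric(B)
  for (st in seq(1, B, by = chunk)) {
    ii <- st:min(st + chunk - 1, B)
    out[ii] <- nn_forward(params, X[ii, , , drop = FALSE], config)$prob
  }
  out
}

#' Predict interaction probabilities
#'
#' Inference is deterministic: dropout is off, and identical inputs give
#' bitwise-identical probabilities.
#'
#' @param object a fitted `ctci_fit` model.
#' @param newdata encoded pairs as in [ctci_fit()].
#' @param type `"prob"` (numeric vector), `"label"` (0/1 at the configured
#'   threshold), or `"both"` (data frame).
#' @param ... unused.
#' @export
predict.ctci_fit <- function(object, newdata,
                             type = c("prob", "label", "both"), ...) {
  type <- match.arg(type)
  X <- as_input_array(newdata)
  if (dim(X)[2] != object$config$input_len)
    stop("input width ", dim(X)[2], " does not match the fitted model (",
         object$config$input_len, ")", call. = FALSE)
  p <- nn_predict(object$params, X, object$config)
  lab <- as.integer(p > object$config$threshold)
  switch(type, prob = p, label = lab,
         both = data.frame(probability = p, label = lab))
}

#' Evaluate a fitted model on labelled pairs
#'
#' @param object a `ctci_fit` model.
#' @param x encoded pairs.
#' @param y 0/1 labels.
#' @return list with `auc` (rank statistic), `aupr`, `accuracy` at the
#'   configured threshold, and `n`.
#' @export
ctci_evaluate <- function(object, x, y) {
  p <- predict(object, x)
  y <- as.integer(y)
  list(auc = auc_score(p, y), aupr = aupr_score(p, y),
       accuracy = mean(as.integer(p > object$config$threshold) == y),
       n = length(y))
}

#' Fine-tune a fitted model on a new task
#'
#' Warm-starts training from the weights of `object` (transfer learning).
#' Feature stages can be frozen; with `epochs = 0` and everything frozen the
#' returned model is identical to the input, so the warm start itself is
#' observable in the history.
#'
#' @param object pretrained `ctci_fit`.
#' @param x,y target-task encoded pairs and labels.
#' @param epochs fine-tuning epochs (overrides the config).
#' @param freeze `"none"`, `"conv"` (freeze convolutional stages), or
#'   `"all"`.
#' @param learning_rate optional override (defaults to the pretrained
#'   config's rate).
#' @param seed optional new seed for the fine-tuning run.
#' @param ... passed to [ctci_fit()] (e.g. `validation`, `patience`).
#' @export
ctci_finetune <- function(object, x, y, epochs = 5L,
                          freeze = c("none", "conv", "all"),
                          learning_rate = NULL, seed = NULL, ...) {
  freeze <- match.arg(freeze)
  cfg <- object$config
  cfg$epochs <- as.integer(epochs)
  if (!is.null(learning_rate)) cfg$learning_rate <- learning_rate
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  X <- as_input_array(x)
  if (dim(X)[2] != cfg$input_len)
    stop("pretrained checkpoint expects width ", cfg$input_len,
         ", got ", dim(X)[2], call. = FALSE)
  if (epochs == 0) {
    out <- object
    out$history <- object$history[0, ]
    out$warm_start <- TRUE
    return(out)
  }
  fr <- switch(freeze, none = character(), conv = "conv",
               all = c("conv", "attn", "dense"))
  fit <- ctci_fit(X, y, cfg, init = object$params, freeze = fr, ...)
  fit$warm_start <- TRUE
  fit
}

# ---- S3 methods --------------------------------------------------------

#' @export
print.ctci_fit <- function(x, ...) {
  cat("Sequence pair classifier (conv + self-attention)\n")
  cat("  input width :", x$config$input_len, "bp\n")
  cat("  trained on  :", x$n_train, "pairs, seed", x$seed, "\n")
  cat("  epochs run  :", nrow(x$history), " (best:", x$best_epoch, ")\n")
  if (!is.na(x$val_auc))
    cat("  val AUC     :", sprintf("%.3f", x$val_auc), "\n")
  invisible(x)
}

#' @export
summary.ctci_fit <- function(object, ...) {
  np <- sum(vapply(object$params$conv,
                   function(p) length(p$W) + length(p$b), 1)) +
    sum(vapply(object$params$attn,
               function(p) length(p$Wq) * 4, 1)) +
    sum(vapply(object$params$dense, length, 1))
  out <- list(config = object$config, n_parameters = np,
              history = object$history, best_epoch = object$best_epoch,
              val_auc = object$val_auc)
  class(out) <- "summary.ctci_fit"
  out
}

#' @export
print.summary.ctci_fit <- function(x, ...) {
  print(x$config)
  cat("  parameters  :", x$n_parameters, "\n")
  cat("  best epoch  :", x$best_epoch, "of", nrow(x$history), "\n")
  if (!is.na(x$val_auc))
    cat("  val AUC     :", sprintf("%.3f", x$val_auc), "\n")
  invisible(x)
}

#' @export
coef.ctci_fit <- function(object, ...) object$params

#' @export
fitted.ctci_fit <- function(object, ...) object$fitted_values

#' Training-history plot
#'
#' Plots per-epoch training loss and validation AUC.
#' @param x a `ctci_fit`.
#' @param ... passed to [plot()].
#' @export
plot.ctci_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(h$epoch, h$loss, type = "b", xlab = "epoch", ylab = "training loss",
       main = "loss", ...)
  if (any(!is.na(h$val_auc)))
    plot(h$epoch, h$val_auc, type = "b", xlab = "epoch",
         ylab = "validation AUC", main = "validation AUC", ...)
  invisible(x)
}

#' Simulate labels from the fitted interaction probabilities
#'
#' Draws Bernoulli labels from the model's predicted probabilities for
#' `newdata`, the parametric-bootstrap analogue of `simulate()` for a
#' binary classifier.
#'
#' @param object a `ctci_fit`.
#' @param nsim number of label sets.
#' @param seed RNG seed.
#' @param newdata encoded pairs (required).
#' @param ... unused.
#' @return data frame with `nsim` columns of simulated 0/1 labels.
#' @export
simulate.ctci_fit <- function(object, nsim = 1, seed = NULL,
                              newdata = NULL, ...) {
  if (is.null(newdata))
    stop("simulate() needs `newdata` (encoded pairs)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object, newdata)
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
residuals.ctci_fit <- function(object, newdata = NULL, y = NULL, ...) {
  if (is.null(newdata))
    return(object$y_train - object$fitted_values)
  if (is.null(y))
    stop("residuals() on new data needs `y`", call. = FALSE)
  as.numeric(y) - predict(object, newdata)
}

#' Save / load a fitted model checkpoint
#'
#' Single-file container with the configuration embedded.
#' @param object a `ctci_fit`.
#' @param path file path.
#' @export
ctci_save <- function(object, path) {
  stopifnot(inherits(object, "ctci_fit"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname ctci_save
#' @export
ctci_load <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "ctci_fit"))
    stop("file does not contain a ctci_fit checkpoint", call. = FALSE)
  obj
}
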