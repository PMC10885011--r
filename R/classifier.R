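# CNN + scaled dot-product attention classification head.
#
# Pipeline per sequence (operating on language-model representations):
#   conv1d + ReLU -> Q/K/V projections -> scaled dot-product attention ->
#   position pooling -> batch normalization -> dropout -> affine -> softmax.
# All gradients are derived analytically; a finite-difference check lives in
# the test suite.

#' Valid 1-D convolution with ReLU
#'
#' Cross-correlates each filter over the position axis with no padding and
#' applies a ReLU.
#'
#' @param X `positions x channels` input matrix.
#' @param W Kernel bank: a 3-D array `kernel_width x channels x filters`, or
#'   an already flattened `(kernel_width * channels) x filters` matrix whose
#'   rows are ordered width-major (all channels of offset 1, then offset 2,
#'   ...).
#' @param b Per-filter offsets.
#' @return A `(positions - kernel_width + 1) x filters` feature map.
#' @export
conv1d_relu <- function(X, W, b) {
  if (is.array(W) && length(dim(W)) == 3) {
    kw <- dim(W)[1]
    W <- conv_flatten(W)
  } else {
    kw <- nrow(W) / ncol(X)
    if (kw != round(kw)) stopf("kernel rows (%d) not a multiple of channels (%d)",
                               nrow(W), ncol(X))
  }
  P <- nrow(X)
  if (P < kw) stopf("input has %d positions, fewer than the kernel width %d", P, kw)
  patches <- conv_patches(X, kw)
  out <- sweep(patches %*% W, 2, b, "+")
  out * (out > 0)
}

# width-major flattening of a kw x C x F kernel array
conv_flatten <- function(W) {
  kw <- dim(W)[1]; C <- dim(W)[2]; F <- dim(W)[3]
  do.call(rbind, lapply(seq_len(kw), function(w) matrix(W[w, , ], C, F)))
}

# P x C -> (P - kw + 1) x (kw * C) sliding-window patch matrix
conv_patches <- function(X, kw) {
  P <- nrow(X)
  do.call(cbind, lapply(seq_len(kw), function(w)
    X[w:(P - kw + w), , drop = FALSE]))
}

#' Scaled dot-product attention
#'
#' `Weight = softmax(Q K' / sqrt(d_k))` row-wise; the output is `Weight V`.
#' The weight matrix is square with side equal to the number of positions
#' and each row sums to 1.
#'
#' @param Q,K Query and key matrices, `positions x d_k`.
#' @param V Value matrix, `positions x d_v`.
#' @return List with `output` (`positions x d_v`) and `weights` (the
#'   row-stochastic attention matrix).
#' @export
scaled_dot_attention <- function(Q, K, V) {
  if (ncol(Q) == 0) stopf("d_k must be positive")
  if (ncol(Q) != ncol(K)) stopf("Q and K must share their inner dimension")
  if (nrow(Q) != nrow(K) || nrow(K) != nrow(V))
    stopf("Q, K and V must have the same number of positions")
  S <- Q %*% t(K) / sqrt(ncol(Q))
  W <- softmax(S)
  list(output = W %*% V, weights = W)
}

#' Batch normalization
#'
#' Standardizes each feature by minibatch moments in training mode, or by
#' running moments in evaluation mode, then applies the learnable affine
#' `gamma * z_hat + beta`.
#'
#' @param Z `batch x features` activations.
#' @param gamma,beta Per-feature scale and shift.
#' @param training Use batch moments and update the running statistics.
#' @param running_mean,running_var Running moments (evaluation mode input;
#'   updated copies are returned).
#' @param momentum Running-statistics update rate.
#' @param eps Variance floor.
#' @return List with `output`, `running_mean`, `running_var`.
#' @export
batch_normalize <- function(Z, gamma, beta, training = TRUE,
                            running_mean = NULL, running_var = NULL,
                            momentum = 0.1, eps = 1e-5) {
  F <- ncol(Z)
  if (is.null(running_mean)) running_mean <- numeric(F)
  if (is.null(running_var)) running_var <- rep(1, F)
  if (training) {
    mu <- colMeans(Z)
    v <- colMeans(sweep(Z, 2, mu)^2)     # biased (1/m) variance
    running_mean <- (1 - momentum) * running_mean + momentum * mu
    running_var <- (1 - momentum) * running_var + momentum * v
  } else {
    mu <- running_mean
    v <- running_var
  }
  zhat <- sweep(sweep(Z, 2, mu), 2, sqrt(v + eps), "/")
  out <- sweep(sweep(zhat, 2, gamma, "*"), 2, beta, "+")
  list(output = out, running_mean = running_mean, running_var = running_var,
       zhat = zhat, mu = mu, var = v)
}

#' Inverted dropout
#'
#' In training mode keeps each activation with probability `1 - p` and
#' rescales survivors by `1/(1-p)` so the expected activation is unchanged;
#' in evaluation mode it is the identity.
#'
#' @param A Numeric vector, matrix or array of activations.
#' @param p Drop probability in `[0, 1)`.
#' @param training Logical.
#' @return Activations of the same shape.
#' @export
dropout <- function(A, p, training = TRUE) {
  if (p < 0 || p >= 1) stopf("dropout probability must be in [0, 1)")
  if (!training || p == 0) return(A)
  mask <- stats::rbinom(length(A), 1, 1 - p)
  A * mask / (1 - p)
}

#' Numerically stable softmax
#'
#' @param z A vector of logits, or a matrix (softmax applied row-wise).
#' @return Probabilities of the same shape; each (row) sums to 1. Invariant
#'   to adding a constant to all logits.
#' @export
softmax <- function(z) {
  if (any(!is.finite(z))) stopf("softmax requires finite logits")
  if (is.null(dim(z))) {
    z <- z - max(z)
    e <- exp(z)
    return(e / sum(e))
  }
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Categorical cross-entropy
#'
#' `L = -sum_i y_i log(yhat_i)` with a `1e-12` probability floor inside the
#' log.
#'
#' @param y One-hot (or general probability) truth vector.
#' @param y_hat Predicted probability vector of the same length.
#' @return Non-negative loss; 0 iff all mass sits on the true class.
#' @export
cross_entropy <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat))
  -sum(y * log(pmax(y_hat, 1e-12)))
}

#' Classifier-head configuration
#'
#' Defaults follow the tuned per-task values: one convolutional layer of 30
#' filters with kernel size 3 for both tasks; for enhancer identification
#' dropout 0.01, learning rate 1e-3, weight decay 1e-4 and patience 5; for
#' strength prediction dropout 0.1, learning rate 2e-2, weight decay 5e-3
#' and patience 7. Batch size is 64 for both.
#'
#' @param task `"identification"` or `"strength"` (selects the defaults).
#' @param n_filters,kernel_size Convolution bank shape.
#' @param dropout Drop probability before the output layer.
#' @param learning_rate,weight_decay Adam settings.
#' @param batch_size,max_epochs,patience,val_frac Training-loop settings.
#' @param pooling `"mean"` (position mean after attention) or `"attention"`
#'   (positions weighted by the mean attention they receive).
#' @param seed Integer seed.
#' @return A list of class `head_config`.
#' @export
head_config <- function(task = c("identification", "strength"),
                        n_filters = 30L, kernel_size = 3L,
                        dropout = NULL, learning_rate = NULL,
                        weight_decay = NULL, batch_size = 64L,
                        max_epochs = 50L, patience = NULL, val_frac = 0.1,
                        pooling = c("mean", "attention"), seed = 1L) {
  task <- match.arg(task)
  pooling <- match.arg(pooling)
  defaults <- if (task == "identification") {
    list(dropout = 1e-2, learning_rate = 1e-3, weight_decay = 1e-4,
         patience = 5L)
  } else {
    list(dropout = 1e-1, learning_rate = 2e-2, weight_decay = 5e-3,
         patience = 7L)
  }
  cfg <- list(task = task, n_filters = as.integer(n_filters),
              kernel_size = as.integer(kernel_size),
              dropout = dropout %||% defaults$dropout,
              learning_rate = learning_rate %||% defaults$learning_rate,
              weight_decay = weight_decay %||% defaults$weight_decay,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience %||% defaults$patience),
              val_frac = val_frac, pooling = pooling,
              seed = as.integer(seed))
  stopifnot(cfg$dropout >= 0, cfg$dropout < 1, cfg$learning_rate > 0,
            cfg$weight_decay >= 0, cfg$patience >= 1)
  class(cfg) <- "head_config"
  cfg
}

# Initialize head parameters (uses the current RNG stream).
init_head <- function(input_dim, cfg) {
  F <- cfg$n_filters
  kw <- cfg$kernel_size
  Wconv <- matrix(stats::rnorm(kw * input_dim * F, sd = sqrt(2 / (kw * input_dim))),
                  kw * input_dim, F)
  proj <- function() matrix(stats::rnorm(F * F, sd = sqrt(1 / F)), F, F)
  list(Wconv = Wconv, bconv = numeric(F),
       Wq = proj(), bq = numeric(F),
       Wk = proj(), bk = numeric(F),
       Wv = proj(), bv = numeric(F),
       gamma = rep(1, F), beta = numeric(F),
       Wout = matrix(stats::rnorm(F * 2, sd = 0.1), F, 2), bout = numeric(2),
       running_mean = numeric(F), running_var = rep(1, F))
}

# Pipeline up to the pooled per-sequence feature vector (conv -> attention
# -> pooling). Shared by the forward pass and the post-training
# recomputation of batch-norm statistics.
head_pool <- function(params, Xlist, cfg) {
  B <- length(Xlist)
  kw <- cfg$kernel_size
  P <- nrow(Xlist[[1]])
  Pp <- P - kw + 1L
  if (Pp < 1) stopf("sequence representation too short for kernel width %d", kw)
  F <- cfg$n_filters
  patches <- lapply(Xlist, conv_patches, kw = kw)
  big <- do.call(rbind, patches)                     # (B*Pp) x (kw*C)
  pre <- sweep(big %*% params$Wconv, 2, params$bconv, "+")
  act <- pre * (pre > 0)                             # ReLU
  sqF <- sqrt(F)
  Z <- matrix(0, B, F)
  att <- vector("list", B)
  for (b in seq_len(B)) {
    A <- act[((b - 1) * Pp + 1):(b * Pp), , drop = FALSE]
    Q <- sweep(A %*% params$Wq, 2, params$bq, "+")
    K <- sweep(A %*% params$Wk, 2, params$bk, "+")
    V <- sweep(A %*% params$Wv, 2, params$bv, "+")
    S <- Q %*% t(K) / sqF
    W <- softmax(S)
    O <- W %*% V
    if (cfg$pooling == "mean") {
      Z[b, ] <- colMeans(O)
      att[[b]] <- list(A = A, Q = Q, K = K, V = V, W = W, O = O)
    } else {
      w <- colMeans(W)                               # attention received
      Z[b, ] <- as.vector(crossprod(O, w))
      att[[b]] <- list(A = A, Q = Q, K = K, V = V, W = W, O = O, w = w)
    }
  }
  list(Z = Z, big = big, pre = pre, act = act, att = att, B = B, Pp = Pp)
}

# Forward pass over a batch of encodings (list of equal-size P x C matrices).
# Returns class probabilities plus caches for the backward pass; updates
# running BN statistics in training mode (returned in $params).
head_forward <- function(params, Xlist, cfg, training = FALSE) {
  pool <- head_pool(params, Xlist, cfg)
  Z <- pool$Z
  bn <- batch_normalize(Z, params$gamma, params$beta, training = training,
                        running_mean = params$running_mean,
                        running_var = params$running_var)
  if (training) {
    params$running_mean <- bn$running_mean
    params$running_var <- bn$running_var
  }
  drop_mask <- NULL
  Zd <- bn$output
  if (training && cfg$dropout > 0) {
    drop_mask <- matrix(stats::rbinom(length(Zd), 1, 1 - cfg$dropout),
                        nrow(Zd), ncol(Zd)) / (1 - cfg$dropout)
    Zd <- Zd * drop_mask
  }
  logits <- sweep(Zd %*% params$Wout, 2, params$bout, "+")
  probs <- softmax(logits)
  list(probs = probs, params = params,
       cache = list(big = pool$big, pre = pool$pre, att = pool$att, Z = Z,
                    bn = bn, drop_mask = drop_mask, Zd = Zd, B = pool$B,
                    Pp = pool$Pp))
}

# Replace the running batch-norm moments by the exact moments of the pooled
# features over a reference set (the training data), so evaluation-mode
# normalization matches the distribution the affine layer was trained
# against.
head_refresh_bn <- function(params, encodings, cfg) {
  n <- length(encodings)
  Zs <- lapply(split(seq_len(n), ceiling(seq_len(n) / cfg$batch_size)),
               function(chunk) head_pool(params, encodings[chunk], cfg)$Z)
  Z <- do.call(rbind, Zs)
  mu <- colMeans(Z)
  params$running_mean <- mu
  params$running_var <- colMeans(sweep(Z, 2, mu)^2)
  params
}

# Backward pass: y is a 0/1 vector (positive class = column 2).
head_backward <- function(params, fwd, y, cfg) {
  cache <- fwd$cache
  B <- cache$B; Pp <- cache$Pp; F <- cfg$n_filters
  probs <- fwd$probs
  onehot <- cbind(1 - y, y)
  dlogits <- (probs - onehot) / B
  g <- list()
  g$Wout <- crossprod(cache$Zd, dlogits)
  g$bout <- colSums(dlogits)
  dZd <- dlogits %*% t(params$Wout)
  if (!is.null(cache$drop_mask)) dZd <- dZd * cache$drop_mask
  # batch-norm backward (training-mode moments)
  bn <- cache$bn
  zhat <- bn$zhat
  g$gamma <- colSums(dZd * zhat)
  g$beta <- colSums(dZd)
  m <- nrow(zhat)
  istd <- 1 / sqrt(bn$var + 1e-5)
  dzhat <- sweep(dZd, 2, params$gamma, "*")
  dvar <- colSums(dzhat * sweep(cache$Z, 2, bn$mu)) * (-0.5) * istd^3
  dmu <- colSums(sweep(dzhat, 2, -istd, "*")) +
    dvar * colMeans(-2 * sweep(cache$Z, 2, bn$mu))
  dZ <- sweep(dzhat, 2, istd, "*") +
    sweep(sweep(cache$Z, 2, bn$mu), 2, 2 * dvar / m, "*") +
    matrix(dmu / m, m, F, byrow = TRUE)
  # attention + pooling backward, per sequence
  dact <- matrix(0, B * Pp, F)
  g$Wq <- matrix(0, F, F); g$bq <- numeric(F)
  g$Wk <- matrix(0, F, F); g$bk <- numeric(F)
  g$Wv <- matrix(0, F, F); g$bv <- numeric(F)
  sqF <- sqrt(F)
  for (b in seq_len(B)) {
    a <- cache$att[[b]]
    dz <- dZ[b, ]
    if (cfg$pooling == "mean") {
      dO <- matrix(dz / Pp, Pp, F, byrow = TRUE)
      dW_extra <- NULL
    } else {
      dO <- outer(a$w, dz)                    # Pp x F
      dw <- as.vector(a$O %*% dz)             # Pp
      dW_extra <- matrix(dw / Pp, Pp, Pp, byrow = TRUE)
    }
    dV <- crossprod(a$W, dO)
    dWmat <- dO %*% t(a$V)
    if (!is.null(dW_extra)) dWmat <- dWmat + dW_extra
    dS <- a$W * (dWmat - rowSums(dWmat * a$W))
    dQ <- dS %*% a$K / sqF
    dK <- crossprod(dS, a$Q) / sqF
    g$Wq <- g$Wq + crossprod(a$A, dQ); g$bq <- g$bq + colSums(dQ)
    g$Wk <- g$Wk + crossprod(a$A, dK); g$bk <- g$bk + colSums(dK)
    g$Wv <- g$Wv + crossprod(a$A, dV); g$bv <- g$bv + colSums(dV)
    dA <- dQ %*% t(params$Wq) + dK %*% t(params$Wk) + dV %*% t(params$Wv)
    dact[((b - 1) * Pp + 1):(b * Pp), ] <- dA
  }
  dpre <- dact * (cache$pre > 0)
  g$Wconv <- crossprod(cache$big, dpre)
  g$bconv <- colSums(dpre)
  g
}

head_loss <- function(probs, y) {
  p_true <- ifelse(y == 1, probs[, 2], probs[, 1])
  mean(-log(pmax(p_true, 1e-12)))
}

#' Train the classification head on fixed sequence representations
#'
#' Optimizes the conv/attention/normalization/output parameters with Adam
#' and categorical cross-entropy, early-stopping on a stratified internal
#' validation split; the parameters with the best validation loss are kept.
#' The language model is frozen at this stage: its representations are the
#' inputs.
#'
#' @param encodings List of `positions x channels` matrices (from
#'   [encode()]).
#' @param y Binary labels (1 = positive class: enhancer / strong).
#' @param config A [head_config()].
#' @return An object of class `classifier_head` with `params`, `config` and
#'   a per-epoch `history`.
#' @export
train_classifier_head <- function(encodings, y, config = head_config()) {
  stopifnot(length(encodings) == length(y))
  if (length(unique(y)) < 2) stopf("training data must contain both classes")
  cfg <- config
  input_dim <- ncol(encodings[[1]])
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  with_seed(cfg$seed, {
    params <- init_head(input_dim, cfg)
    n <- length(y)
    # stratified validation split
    val_idx <- unlist(lapply(unique(y), function(cl) {
      ii <- which(y == cl)
      ii <- sample(ii)
      ii[seq_len(max(1L, round(cfg$val_frac * length(ii))))]
    }))
    train_idx <- setdiff(seq_len(n), val_idx)
    eval_loss <- function(p) {
      tot <- 0
      for (chunk in split(val_idx, ceiling(seq_along(val_idx) / cfg$batch_size))) {
        fw <- head_forward(p, encodings[chunk], cfg, training = FALSE)
        tot <- tot + head_loss(fw$probs, y[chunk]) * length(chunk)
      }
      tot / length(val_idx)
    }
    opt <- adam_init(params[setdiff(names(params),
                                    c("running_mean", "running_var"))])
    best_val <- eval_loss(params)
    best_params <- params
    wait <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(train_idx)
      ep_loss <- 0
      for (chunk in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
        fw <- head_forward(params, encodings[chunk], cfg, training = TRUE)
        params <- fw$params      # running BN stats updated
        loss <- head_loss(fw$probs, y[chunk])
        if (!is.finite(loss))
          stopf("classifier training diverged (non-finite loss at epoch %d)", epoch)
        ep_loss <- ep_loss + loss * length(chunk)
        grads <- head_backward(params, fw, y[chunk], cfg)
        learn <- params[names(opt$m)]
        upd <- adam_step(learn, grads[names(opt$m)], opt,
                         lr = cfg$learning_rate,
                         weight_decay = cfg$weight_decay)
        params[names(opt$m)] <- upd$params
        opt <- upd$state
      }
      # exact batch-norm moments over the training set for evaluation mode
      params <- head_refresh_bn(params, encodings[train_idx], cfg)
      val <- eval_loss(params)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = ep_loss / length(ord),
                                           val_loss = val))
      if (val < best_val - 1e-8) {
        best_val <- val; best_params <- params; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  structure(list(params = best_params, config = cfg, history = history),
            class = "classifier_head")
}

#' Class probabilities for sequences under a language model + head
#'
#' Runs the full evaluation-mode pipeline: encode with the (frozen) language
#' model, convolve, attend, pool, normalize with running statistics and apply
#' the softmax output layer. Deterministic (no RNG is consumed).
#'
#' @param lm A `language_model`.
#' @param head A `classifier_head` from [train_classifier_head()].
#' @param sequences Character vector of sequences or a [benchmark_dataset()].
#' @return A `n x 2` matrix of class probabilities with columns
#'   `negative`/`positive` (positive = enhancer or strong enhancer,
#'   depending on the head's task).
#' @export
classify <- function(lm, head, sequences) {
  stopifnot(inherits(lm, "language_model"), inherits(head, "classifier_head"))
  seqs <- corpus_sequences(sequences)
  min_len <- lm$vocab$k + head$config$kernel_size - 1L
  too_short <- nchar(seqs) < min_len
  if (any(too_short))
    stopf("%d sequence(s) shorter than the minimum length %d (k + kernel - 1)",
          sum(too_short), min_len)
  enc <- encode(lm, seqs)
  probs <- matrix(0, length(seqs), 2,
                  dimnames = list(NULL, c("negative", "positive")))
  lens <- vapply(enc, nrow, 1L)
  for (L in unique(lens)) {
    sel <- which(lens == L)
    for (chunk in split(sel, ceiling(seq_along(sel) / head$config$batch_size))) {
      fw <- head_forward(head$params, enc[chunk], head$config,
                         training = FALSE)
      probs[chunk, ] <- fw$probs
    }
  }
  probs
}
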