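# LSTM cell and layer with hand-derived backward pass, plus DropConnect
# weight regularization.
#
# Gate equations (per time step t, input x_t, previous hidden h, cell c):
#   i = sigmoid(Wi x + Ui h + bi)        input gate
#   f = sigmoid(Wf x + Uf h + bf)        forget gate
#   o = sigmoid(Wo x + Uo h + bo)        output gate
#   g = tanh(Wc x + Uc h)                candidate (no bias, as modeled)
#   c_t = i * g + f * c
#   h_t = o * tanh(c_t)
# Parameters are kept as separate per-gate matrices; the layer runner fuses
# them column-wise for BLAS efficiency.

#' Initialize parameters for one LSTM layer
#'
#' Weights are drawn uniformly from +/- 1/sqrt(hidden_size) using the current
#' RNG stream; biases start at zero.
#'
#' @param input_size Number of input features per time step.
#' @param hidden_size Number of hidden units.
#' @return List of class `lstm_params` with per-gate input weights
#'   `Wi, Wf, Wo, Wc` (input_size x hidden_size), recurrent weights
#'   `Ui, Uf, Uo, Uc` (hidden_size x hidden_size) and biases `bi, bf, bo`.
#' @export
lstm_layer_params <- function(input_size, hidden_size) {
  s <- 1 / sqrt(hidden_size)
  rmat <- function(nr, nc) matrix(stats::runif(nr * nc, -s, s), nr, nc)
  structure(list(
    Wi = rmat(input_size, hidden_size), Wf = rmat(input_size, hidden_size),
    Wo = rmat(input_size, hidden_size), Wc = rmat(input_size, hidden_size),
    Ui = rmat(hidden_size, hidden_size), Uf = rmat(hidden_size, hidden_size),
    Uo = rmat(hidden_size, hidden_size), Uc = rmat(hidden_size, hidden_size),
    bi = numeric(hidden_size), bf = numeric(hidden_size),
    bo = numeric(hidden_size)), class = "lstm_params")
}

#' One LSTM cell step
#'
#' Evaluates the gate equations for a (batch of) input vector(s).
#'
#' @param x Input: a vector of length `input_size` or a `batch x input_size`
#'   matrix.
#' @param state `NULL` (zero state) or a list with `h` and `c`, each a vector
#'   or `batch x hidden_size` matrix.
#' @param params An [lstm_layer_params()] list.
#' @return List with the new `h` and `c` (matrices of `batch x hidden_size`).
#' @export
lstm_cell_step <- function(x, state = NULL, params) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  H <- length(params$bi)
  if (ncol(params$Wi) != H || nrow(params$Wi) != ncol(x))
    stopf("input width %d does not match Wi (%d x %d)", ncol(x),
          nrow(params$Wi), ncol(params$Wi))
  B <- nrow(x)
  if (is.null(state)) state <- list(h = matrix(0, B, H), c = matrix(0, B, H))
  h <- state$h; c_prev <- state$c
  if (is.null(dim(h))) h <- matrix(h, nrow = B)
  if (is.null(dim(c_prev))) c_prev <- matrix(c_prev, nrow = B)
  i <- sigmoid(sweep(x %*% params$Wi + h %*% params$Ui, 2, params$bi, "+"))
  f <- sigmoid(sweep(x %*% params$Wf + h %*% params$Uf, 2, params$bf, "+"))
  o <- sigmoid(sweep(x %*% params$Wo + h %*% params$Uo, 2, params$bo, "+"))
  g <- tanh(x %*% params$Wc + h %*% params$Uc)
  c_t <- i * g + f * c_prev
  list(h = o * tanh(c_t), c = c_t)
}

#' Apply DropConnect to LSTM weight matrices
#'
#' Zeroes individual elements of the recurrent (`Ui, Uf, Uo`) and
#' non-recurrent (`Wi, Wf, Wo`) gate weight matrices independently with
#' probability `p`, rescaling survivors by `1/(1-p)` so the expected weight
#' is preserved; one mask is drawn per call and is intended to be shared by
#' the full forward and backward pass of a batch. In evaluation mode the
#' parameters are returned unchanged. The candidate weights `Wc, Uc` are not
#' masked.
#'
#' @param params An [lstm_layer_params()] list.
#' @param p Drop probability in `[0, 1)`.
#' @param training Apply masking (`TRUE`) or pass through (`FALSE`).
#' @return List with `params` (possibly masked) and `masks` (the 0/1 masks
#'   used, `NULL` in evaluation mode).
#' @export
apply_dropconnect <- function(params, p, training = TRUE) {
  if (p < 0 || p >= 1) stopf("dropconnect probability must be in [0, 1)")
  if (!training || p == 0) return(list(params = params, masks = NULL))
  masked <- params
  masks <- list()
  for (nm in c("Wi", "Wf", "Wo", "Ui", "Uf", "Uo")) {
    m <- matrix(stats::rbinom(length(params[[nm]]), 1, 1 - p),
                nrow(params[[nm]]), ncol(params[[nm]]))
    masks[[nm]] <- m
    masked[[nm]] <- params[[nm]] * m / (1 - p)
  }
  list(params = masked, masks = masks)
}

# Fuse per-gate matrices column-wise in gate order i, f, g, o.
fuse_lstm <- function(params) {
  H <- length(params$bi)
  list(Wx = cbind(params$Wi, params$Wf, params$Wc, params$Wo),
       Uh = cbind(params$Ui, params$Uf, params$Uc, params$Uo),
       b = c(params$bi, params$bf, numeric(H), params$bo),
       H = H)
}

# Split fused gradient blocks back into per-gate matrices.
unfuse_grads <- function(dWx, dUh, db, H) {
  idx <- function(j) ((j - 1) * H + 1):(j * H)
  structure(list(
    Wi = dWx[, idx(1), drop = FALSE], Wf = dWx[, idx(2), drop = FALSE],
    Wo = dWx[, idx(4), drop = FALSE], Wc = dWx[, idx(3), drop = FALSE],
    Ui = dUh[, idx(1), drop = FALSE], Uf = dUh[, idx(2), drop = FALSE],
    Uo = dUh[, idx(4), drop = FALSE], Uc = dUh[, idx(3), drop = FALSE],
    bi = db[idx(1)], bf = db[idx(2)], bo = db[idx(4)]), class = "lstm_params")
}

# Run one LSTM layer over a sequence of inputs.
# X: list over time of batch x input_size matrices.
# Returns h (list over time) and, if keep_cache, everything the backward
# pass needs.
lstm_layer_forward <- function(X, params, keep_cache = FALSE) {
  fused <- fuse_lstm(params)
  H <- fused$H
  Tlen <- length(X)
  B <- nrow(X[[1]])
  h <- matrix(0, B, H); c_t <- matrix(0, B, H)
  hs <- vector("list", Tlen)
  cache <- if (keep_cache) {
    list(i = vector("list", Tlen), f = vector("list", Tlen),
         g = vector("list", Tlen), o = vector("list", Tlen),
         c = vector("list", Tlen), h_prev = vector("list", Tlen),
         c_prev = vector("list", Tlen), X = X)
  } else NULL
  for (t in seq_len(Tlen)) {
    Z <- sweep(X[[t]] %*% fused$Wx + h %*% fused$Uh, 2, fused$b, "+")
    i <- sigmoid(Z[, 1:H, drop = FALSE])
    f <- sigmoid(Z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(Z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(Z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- i * g + f * c_t
    if (keep_cache) {
      cache$i[[t]] <- i; cache$f[[t]] <- f; cache$g[[t]] <- g
      cache$o[[t]] <- o; cache$c[[t]] <- c_new
      cache$h_prev[[t]] <- h; cache$c_prev[[t]] <- c_t
    }
    c_t <- c_new
    h <- o * tanh(c_t)
    hs[[t]] <- h
  }
  list(h = hs, cache = cache, fused = fused)
}

# Backpropagate through one LSTM layer.
# dH: list over time of gradients w.r.t. the layer's hidden outputs.
# Returns dX (list over time) and per-gate parameter gradients.
lstm_layer_backward <- function(dH, fwd) {
  cache <- fwd$cache
  fused <- fwd$fused
  H <- fused$H
  Tlen <- length(dH)
  B <- nrow(dH[[1]])
  dWx <- matrix(0, nrow(fused$Wx), 4 * H)
  dUh <- matrix(0, H, 4 * H)
  db <- numeric(4 * H)
  dX <- vector("list", Tlen)
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  tWx <- t(fused$Wx); tUh <- t(fused$Uh)
  for (t in rev(seq_len(Tlen))) {
    dh <- dH[[t]] + dh_next
    i <- cache$i[[t]]; f <- cache$f[[t]]; g <- cache$g[[t]]; o <- cache$o[[t]]
    tc <- tanh(cache$c[[t]])
    do_ <- dh * tc
    dc <- dc_next + dh * o * (1 - tc * tc)
    di <- dc * g
    dg <- dc * i
    df <- dc * cache$c_prev[[t]]
    dc_next <- dc * f
    dZ <- cbind(di * i * (1 - i), df * f * (1 - f),
                dg * (1 - g * g), do_ * o * (1 - o))
    dX[[t]] <- dZ %*% tWx
    dh_next <- dZ %*% tUh
    dWx <- dWx + crossprod(cache$X[[t]], dZ)
    dUh <- dUh + crossprod(cache$h_prev[[t]], dZ)
    db <- db + colSums(dZ)
  }
  # The candidate-gate bias slot is unused (no bias in the g equation).
  grads <- unfuse_grads(dWx, dUh, db, H)
  list(dX = dX, grads = grads)
}

# Multiply parameter gradients by the DropConnect masks (chain rule through
# the mask-and-rescale applied at forward time).
mask_lstm_grads <- function(grads, masks, p) {
  if (is.null(masks)) return(grads)
  for (nm in names(masks)) grads[[nm]] <- grads[[nm]] * masks[[nm]] / (1 - p)
  grads
}
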