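# Independent reference implementations used as oracles, written as plain
# elementwise loops so they share no code path with the package internals.

ref_sigmoid <- function(x) 1 / (1 + exp(-x))

# Plain-formula LSTM cell on a single input vector.
ref_lstm_cell <- function(x, h_prev, c_prev, p) {
  i <- ref_sigmoid(as.vector(x %*% p$Wi) + as.vector(h_prev %*% p$Ui) + p$bi)
  f <- ref_sigmoid(as.vector(x %*% p$Wf) + as.vector(h_prev %*% p$Uf) + p$bf)
  o <- ref_sigmoid(as.vector(x %*% p$Wo) + as.vector(h_prev %*% p$Uo) + p$bo)
  g <- tanh(as.vector(x %*% p$Wc) + as.vector(h_prev %*% p$Uc))
  c_t <- i * g + f * c_prev
  list(h = o * tanh(c_t), c = c_t)
}

# Nested-loop valid 1-D cross-correlation + ReLU; W is kw x C x F.
ref_conv1d_relu <- function(X, W, b) {
  kw <- dim(W)[1]; C <- dim(W)[2]; F <- dim(W)[3]
  P <- nrow(X)
  out <- matrix(0, P - kw + 1, F)
  for (p in seq_len(P - kw + 1)) {
    for (f in seq_len(F)) {
      acc <- b[f]
      for (w in seq_len(kw)) for (cc in seq_len(C)) {
        acc <- acc + X[p + w - 1, cc] * W[w, cc, f]
      }
      out[p, f] <- max(acc, 0)
    }
  }
  out
}

# Row-by-row scaled dot-product attention.
ref_attention <- function(Q, K, V) {
  n <- nrow(Q)
  O <- matrix(0, n, ncol(V))
  for (r in seq_len(n)) {
    s <- numeric(n)
    for (j in seq_len(n)) s[j] <- sum(Q[r, ] * K[j, ]) / sqrt(ncol(Q))
    w <- exp(s - max(s)); w <- w / sum(w)
    for (cc in seq_len(ncol(V))) O[r, cc] <- sum(w * V[, cc])
  }
  O
}

# All-pairs concordance (Mann-Whitney) AUROC with half-credit for ties.
ref_auroc_pairs <- function(y, score) {
  pos <- score[y == 1]; neg <- score[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# Central finite-difference gradient of f at x (a numeric array).
fd_grad <- function(f, x, h = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# Small, fast configurations for pipeline tests.
tiny_lm_config <- function(seed = 1L, max_epochs = 2L, ...) {
  lm_config(embedding_size = 12L, hidden_size = 12L, max_epochs = max_epochs,
            learning_rate = 3e-3, seed = seed, ...)
}
tiny_head_config <- function(task = "identification", seed = 1L,
                             n_filters = 12L, max_epochs = 20L, ...) {
  head_config(task, n_filters = n_filters, max_epochs = max_epochs,
              seed = seed, ...)
}

random_dna <- function(n, length, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""),
    "")
}

gc_fraction <- function(seqs) {
  vapply(strsplit(seqs, ""), function(s) mean(s %in% c("G", "C")), 1)
}
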