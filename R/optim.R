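# Adam optimizer over arbitrarily nested lists of numeric arrays.
# L2 weight decay is added to the gradient (as in common deep-learning
# toolkits' Adam), not decoupled.

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) return(lapply(p, zero_like))
    p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    g <- g + weight_decay * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# Elementwise sum of two equally shaped nested gradient lists.
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- grads_add(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}
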