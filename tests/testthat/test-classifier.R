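test_that("conv1d_relu matches hand convolution and clips negatives", {
  # single channel [1,2,3,4], filter [1,1,1]: windows sum to 6 and 9
  X <- matrix(c(1, 2, 3, 4), ncol = 1)
  W <- array(1, dim = c(3, 1, 1))
  expect_equal(as.vector(conv1d_relu(X, W, 0)), c(6, 9))
  expect_equal(as.vector(conv1d_relu(X, array(-1, dim = c(3, 1, 1)), 0)),
               c(0, 0))
  expect_equal(as.vector(conv1d_relu(X, array(0, dim = c(3, 1, 1)), 0)),
               c(0, 0))
  expect_error(conv1d_relu(matrix(1, 2, 1), W, 0), "fewer than")
})

test_that("conv1d_relu equals the nested-loop oracle on random instances", {
  set.seed(14)
  for (i in 1:8) {
    P <- sample(4:10, 1); C <- sample(1:4, 1)
    kw <- sample(1:3, 1); F <- sample(1:5, 1)
    X <- matrix(rnorm(P * C), P, C)
    W <- array(rnorm(kw * C * F), dim = c(kw, C, F))
    b <- rnorm(F)
    expect_equal(conv1d_relu(X, W, b), ref_conv1d_relu(X, W, b),
                 tolerance = 1e-10)
  }
})

test_that("scaled dot-product attention is row-stochastic and exact", {
  set.seed(15)
  # single position: output is V itself
  att1 <- scaled_dot_attention(matrix(rnorm(3), 1), matrix(rnorm(3), 1),
                               matrix(c(2, -1), 1))
  expect_equal(att1$output, matrix(c(2, -1), 1))

  # identical key rows: uniform weights, output rows = column means of V
  Q <- matrix(rnorm(12), 4, 3)
  K <- matrix(rep(rnorm(3), each = 4), 4, 3)
  V <- matrix(rnorm(8), 4, 2)
  att2 <- scaled_dot_attention(Q, K, V)
  for (r in 1:4) expect_equal(as.vector(att2$output[r, ]), colMeans(V),
                              tolerance = 1e-12)

  for (i in 1:5) {
    n <- sample(2:7, 1); dk <- sample(1:4, 1); dv <- sample(1:3, 1)
    Q <- matrix(rnorm(n * dk), n); K <- matrix(rnorm(n * dk), n)
    V <- matrix(rnorm(n * dv), n)
    att <- scaled_dot_attention(Q, K, V)
    expect_equal(dim(att$weights), c(n, n))
    expect_lt(max(abs(rowSums(att$weights) - 1)), 1e-12)
    expect_equal(att$output, ref_attention(Q, K, V), tolerance = 1e-10)
  }
  expect_error(scaled_dot_attention(matrix(0, 2, 0), matrix(0, 2, 0),
                                    matrix(0, 2, 1)), "d_k")
})

test_that("batch normalization standardizes by minibatch moments", {
  Z <- matrix(c(1, 2, 3), ncol = 1)
  bn <- batch_normalize(Z, gamma = 1, beta = 0, eps = 1e-12)
  expect_equal(as.vector(bn$output), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-6)
  expect_equal(round(as.vector(bn$output), 4), c(-1.2247, 0, 1.2247))

  const <- matrix(5, 4, 2)
  bnc <- batch_normalize(const, gamma = c(1, 1), beta = c(0, 0))
  expect_lt(max(abs(bnc$output)), 1e-6)

  bn2 <- batch_normalize(Z, gamma = 2, beta = 5, eps = 1e-12)
  expect_equal(bn2$output, 2 * bn$output + 5, tolerance = 1e-9)

  # evaluation mode uses the supplied running moments
  bne <- batch_normalize(Z, gamma = 1, beta = 0, training = FALSE,
                         running_mean = 2, running_var = 1, eps = 0)
  expect_equal(as.vector(bne$output), c(-1, 0, 1))
})

test_that("inverted dropout preserves expectation and is inert at evaluation", {
  A <- rep(1, 1e5)
  expect_identical(dropout(A, 0), A)
  expect_identical(dropout(A, 0.4, training = FALSE), A)
  set.seed(19)
  Ad <- dropout(A, 0.4)
  expect_lt(abs(mean(Ad) - 1), 0.02)
  expect_error(dropout(A, 1), "\\[0, 1\\)")
})

test_that("softmax and cross-entropy obey their closed-form identities", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(rep(3, 5)), rep(0.2, 5))
  z <- rnorm(6)
  expect_equal(softmax(z), softmax(z + 100), tolerance = 1e-12)
  expect_error(softmax(c(1, Inf)), "finite")

  expect_equal(cross_entropy(c(0, 1), c(0, 1)), 0)
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), log(2))
  expect_equal(cross_entropy(c(0, 0, 1, 0), rep(0.25, 4)), log(4))
  expect_gte(cross_entropy(c(1, 0), c(1e-30, 1)), 0)  # probability floor
})

test_that("analytic head gradients agree with finite differences", {
  for (pooling in c("mean", "attention")) {
    cfg <- head_config("identification", n_filters = 4, kernel_size = 2,
                       dropout = 0, pooling = pooling, seed = 1)
    set.seed(77)
    params <- enhancerlm:::init_head(3, cfg)
    Xlist <- lapply(1:4, function(i) matrix(rnorm(6 * 3), 6, 3))
    y <- c(1, 0, 1, 0)
    loss_with <- function(params) {
      fw <- enhancerlm:::head_forward(params, Xlist, cfg, training = TRUE)
      enhancerlm:::head_loss(fw$probs, y)
    }
    fw <- enhancerlm:::head_forward(params, Xlist, cfg, training = TRUE)
    g <- enhancerlm:::head_backward(params, fw, y, cfg)
    for (nm in c("Wconv", "bconv", "Wq", "Wk", "Wv", "bv", "gamma", "beta",
                 "Wout", "bout")) {
      fd <- fd_grad(function(x) {
        p2 <- params; p2[[nm]] <- x; loss_with(p2)
      }, params[[nm]])
      denom <- max(abs(fd), abs(g[[nm]]), 1e-6)
      expect_lt(max(abs(fd - g[[nm]])) / denom, 1e-4,
                label = sprintf("gradient mismatch for %s (%s pooling)",
                                nm, pooling))
    }
  }
})

test_that("classification is a pure evaluation-mode function", {
  corpus <- random_dna(30, 40, seed = 3)
  v <- build_vocabulary(corpus, 2)
  lm <- init_language_model(v, lm_config(embedding_size = 8, hidden_size = 8,
                                         seed = 2))
  enc <- encode(lm, corpus)
  y <- rep(c(1, 0), 15)
  head <- train_classifier_head(enc, y, head_config("identification",
                                                    n_filters = 6,
                                                    max_epochs = 2, seed = 3))
  set.seed(123)
  rng_before <- .Random.seed
  p1 <- classify(lm, head, corpus)
  expect_identical(.Random.seed, rng_before)
  expect_equal(unname(rowSums(p1)), rep(1, 30), tolerance = 1e-12)
  p2 <- classify(lm, head, c(corpus[1], corpus[1]))
  expect_identical(p2[1, ], p2[2, ])

  expect_error(classify(lm, head, "ACG"), "shorter than")
})
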