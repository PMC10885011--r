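test_that("lstm cell matches hand-evaluated gate equations", {
  # all-zero parameters: gates 0.5, candidate 0, so h = c = 0
  p0 <- lstm_layer_params(2, 3)
  for (nm in c("Wi", "Wf", "Wo", "Wc", "Ui", "Uf", "Uo", "Uc")) p0[[nm]][] <- 0
  st <- lstm_cell_step(c(1, -1), NULL, p0)
  expect_equal(unname(st$h[1, ]), rep(0, 3))
  expect_equal(unname(st$c[1, ]), rep(0, 3))

  # scalar case: W = 1, U = 0, b = 0, x = 0.5
  p1 <- lstm_layer_params(1, 1)
  for (nm in c("Wi", "Wf", "Wo", "Wc")) p1[[nm]][] <- 1
  for (nm in c("Ui", "Uf", "Uo", "Uc")) p1[[nm]][] <- 0
  st <- lstm_cell_step(0.5, NULL, p1)
  g <- 1 / (1 + exp(-0.5))
  expect_equal(st$c[1, 1], g * tanh(0.5), tolerance = 1e-10)
  expect_equal(st$h[1, 1], g * tanh(g * tanh(0.5)), tolerance = 1e-10)
  expect_equal(st$c[1, 1], 0.2877, tolerance = 1e-3)
  expect_equal(st$h[1, 1], 0.1742, tolerance = 1e-3)
})

test_that("lstm cell equals an independent reference on random instances", {
  set.seed(3)
  for (i in 1:10) {
    D <- sample(1:5, 1); H <- sample(1:6, 1)
    p <- lstm_layer_params(D, H)
    x <- rnorm(D); h0 <- rnorm(H); c0 <- rnorm(H)
    got <- lstm_cell_step(x, list(h = h0, c = c0), p)
    want <- ref_lstm_cell(x, h0, c0, p)
    expect_equal(as.vector(got$h), want$h, tolerance = 1e-10)
    expect_equal(as.vector(got$c), want$c, tolerance = 1e-10)
  }
})

test_that("running a sequence keeps gates and hidden states bounded", {
  set.seed(8)
  p <- lstm_layer_params(3, 4)
  state <- NULL
  for (t in 1:30) {
    state <- lstm_cell_step(rnorm(3, sd = 3), state, p)
    expect_true(all(abs(state$h) < 1))
    expect_true(all(is.finite(state$c)))
  }
})

test_that("dropconnect masks the six gate matrices at the stated rate", {
  set.seed(5)
  p <- lstm_layer_params(256, 256)
  expect_identical(apply_dropconnect(p, 0)$params, p)
  expect_identical(apply_dropconnect(p, 0.4, training = FALSE)$params, p)
  dc <- apply_dropconnect(p, 0.4)
  frac <- mean(dc$params$Ui == 0)
  expect_lt(abs(frac - 0.4), 0.02)
  expect_identical(dc$params$Uc, p$Uc)  # candidate weights are never masked
  # surviving weights are rescaled to preserve the expectation
  kept <- dc$params$Wi != 0
  expect_equal(dc$params$Wi[kept], p$Wi[kept] / 0.6, tolerance = 1e-12)
  expect_error(apply_dropconnect(p, 1), "\\[0, 1\\)")
})

test_that("embedding dropout zeroes whole vectors at the stated rate", {
  set.seed(6)
  E <- matrix(rnorm(50), 10, 5)
  ids <- sample(10, 10000, replace = TRUE)
  expect_identical(embed_with_dropout(ids, E, training = FALSE),
                   E[ids, ])
  X <- embed_with_dropout(ids, E, p_embeddings = 0.3, p_embeddings_dim = 0,
                          training = TRUE)
  frac_zero <- mean(rowSums(X != 0) == 0)
  expect_lt(abs(frac_zero - 0.3), 0.02)
  # certain drop
  X1 <- embed_with_dropout(ids[1:50], E, p_embeddings = 1, training = TRUE)
  expect_true(all(X1 == 0))
})

test_that("lm_forward has the right shape and near-uniform initial entropy", {
  set.seed(2)
  corpus <- random_dna(30, 40, seed = 9)
  v <- build_vocabulary(corpus, 2)
  model <- init_language_model(v, lm_config(embedding_size = 8,
                                            hidden_size = 8, seed = 3))
  logits <- lm_forward(model, corpus[1:4])
  expect_equal(dim(logits), c(4, 39, v$size))  # bos + 39 k-mers -> 39 inputs
  expect_identical(logits, lm_forward(model, corpus[1:4]))  # eval-mode purity

  # untrained model: mean cross-entropy close to ln(vocab size)
  streams <- lapply(corpus[1:10], numericalize, vocab = v, bos = TRUE)
  lg <- lm_forward(model, corpus[1:10])
  ce <- 0; ntok <- 0
  for (b in 1:10) {
    tgt <- streams[[b]][-1]
    for (t in seq_along(tgt)) {
      p <- exp(lg[b, t, ] - max(lg[b, t, ]))
      p <- p / sum(p)
      ce <- ce + -log(p[tgt[t]]); ntok <- ntok + 1
    }
  }
  expect_lt(abs(ce / ntok - log(v$size)) / log(v$size), 0.10)
})

test_that("pretraining beats the uniform baseline and is reproducible", {
  corpus <- generate_identification_dataset(
    synthetic_spec(n_per_class = 100, length = 60, seed = 21))$seq
  cfg <- lm_config(embedding_size = 12, hidden_size = 12, max_epochs = 3,
                   learning_rate = 3e-3, seed = 4)
  m1 <- pretrain_lm(corpus, 2, cfg)
  expect_lt(m1$history$val_loss[nrow(m1$history)], log(m1$vocab$size))
  m2 <- pretrain_lm(corpus, 2, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params$E, m2$params$E)
})

test_that("early stopping halts on sustained held-out deterioration", {
  corpus <- random_dna(40, 30, seed = 2)
  # a deliberately unstable learning rate forces the loss to bounce
  cfg <- lm_config(embedding_size = 8, hidden_size = 8, max_epochs = 40,
                   learning_rate = 0.5, patience = 1, seed = 1)
  m <- pretrain_lm(corpus, 2, cfg)
  expect_lt(nrow(m$history), 40)
})

test_that("a tiny corpus can be memorized with regularization off", {
  corpus <- random_dna(6, 16, seed = 33)
  cfg <- lm_config(embedding_size = 24, hidden_size = 48, max_epochs = 1000,
                   learning_rate = 3e-2, weight_decay = 0, dropconnect = 0,
                   p_embeddings = 0, p_embeddings_dim = 0, patience = 1000,
                   val_frac = 0.15, seed = 2)
  m <- pretrain_lm(corpus, 2, cfg)
  # from the uniform baseline ln(19) ~ 2.94 down to near zero
  expect_lt(min(m$history$train_loss), 0.2)
})

test_that("fine-tuning adapts to a GC-shifted corpus without a new vocabulary", {
  base <- generate_identification_dataset(
    synthetic_spec(n_per_class = 60, length = 50, gc_positive = 0.3,
                   gc_negative = 0.3, seed = 12))$seq
  shifted <- generate_identification_dataset(
    synthetic_spec(n_per_class = 60, length = 50, gc_positive = 0.7,
                   gc_negative = 0.7, seed = 13))$seq
  cfg <- lm_config(embedding_size = 12, hidden_size = 12, max_epochs = 3,
                   learning_rate = 3e-3, seed = 6)
  m <- pretrain_lm(base, 2, cfg, vocab = build_vocabulary(c(base, shifted), 2))

  shifted_ce <- function(model) {
    lg <- lm_forward(model, shifted[1:30])
    streams <- lapply(shifted[1:30], numericalize, vocab = model$vocab,
                      bos = TRUE)
    tot <- 0; ntok <- 0
    for (b in seq_len(dim(lg)[1])) {
      tgt <- streams[[b]][-1]
      for (t in seq_along(tgt)) {
        p <- exp(lg[b, t, ] - max(lg[b, t, ])); p <- p / sum(p)
        tot <- tot - log(p[tgt[t]]); ntok <- ntok + 1
      }
    }
    tot / ntok
  }
  before <- shifted_ce(m)
  m2 <- fine_tune_lm(m, shifted, cfg)
  expect_lt(shifted_ce(m2), before)
  expect_gt(nrow(m2$history), nrow(m$history))  # history appended

  # zero epochs: unchanged
  cfg0 <- cfg; cfg0$max_epochs <- 0L
  expect_identical(fine_tune_lm(m, shifted, cfg0), m)

  other_vocab <- build_vocabulary("ACGT", 2)
  expect_error(fine_tune_lm(m, shifted, vocab = other_vocab),
               "vocabulary mismatch")
})

test_that("encode returns deterministic per-position hidden states", {
  corpus <- random_dna(6, 30, seed = 5)
  v <- build_vocabulary(corpus, 2)
  model <- init_language_model(v, lm_config(embedding_size = 10,
                                            hidden_size = 14, seed = 8))
  enc <- encode(model, corpus)
  expect_length(enc, 6)
  expect_equal(dim(enc[[1]]), c(29, 14))  # L - k + 1 positions x hidden
  expect_identical(enc, encode(model, corpus))
  expect_identical(encode(model, c(corpus[1], corpus[1]))[[1]],
                   encode(model, c(corpus[1], corpus[1]))[[2]])
})
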