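# Self-supervised next-k-mer language model: stochastic embedding layer,
# a stack of weight-dropped LSTM layers, and an affine decoder to
# next-token logits. Trained with Adam on categorical cross-entropy with
# early stopping on a held-out split.

#' Language-model configuration
#'
#' Defaults are the tuned values for this architecture: 400-dimensional
#' embeddings, three LSTM layers of 256 units, DropConnect 0.4 on the gate
#' weight matrices, embedding dropouts 0.001, Adam with learning rate 1e-4
#' and weight decay 1e-2, batch size 64 and early-stopping patience 50.
#'
#' @param embedding_size Embedding vector dimension.
#' @param hidden_size Hidden units per LSTM layer.
#' @param n_layers Number of stacked LSTM layers.
#' @param dropconnect Drop probability for [apply_dropconnect()].
#' @param p_embeddings Probability of zeroing a whole token embedding vector.
#' @param p_embeddings_dim Probability of zeroing individual embedding
#'   components of surviving vectors.
#' @param learning_rate,weight_decay Adam settings.
#' @param batch_size Sequences per minibatch.
#' @param max_epochs Upper bound on training epochs.
#' @param patience Early-stopping patience (epochs without held-out
#'   improvement).
#' @param val_frac Fraction of the corpus held out for early stopping.
#' @param seed Integer seed controlling initialization, splits and dropout.
#' @return A list of class `lm_config`.
#' @export
lm_config <- function(embedding_size = 400L, hidden_size = 256L,
                      n_layers = 3L, dropconnect = 0.4,
                      p_embeddings = 1e-3, p_embeddings_dim = 1e-3,
                      learning_rate = 1e-4, weight_decay = 1e-2,
                      batch_size = 64L, max_epochs = 20L, patience = 50L,
                      val_frac = 0.1, seed = 1L) {
  stopifnot(embedding_size >= 1, hidden_size >= 1, n_layers >= 1,
            dropconnect >= 0, dropconnect < 1,
            p_embeddings >= 0, p_embeddings < 1,
            p_embeddings_dim >= 0, p_embeddings_dim < 1,
            learning_rate > 0, weight_decay >= 0, batch_size >= 1,
            max_epochs >= 0, patience >= 1, val_frac > 0, val_frac < 1)
  structure(list(embedding_size = as.integer(embedding_size),
                 hidden_size = as.integer(hidden_size),
                 n_layers = as.integer(n_layers), dropconnect = dropconnect,
                 p_embeddings = p_embeddings,
                 p_embeddings_dim = p_embeddings_dim,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), val_frac = val_frac,
                 seed = as.integer(seed)), class = "lm_config")
}

#' Initialize an untrained language model
#'
#' @param vocab A [build_vocabulary()] result.
#' @param config An [lm_config()].
#' @return An object of class `language_model` holding the vocabulary,
#'   configuration, parameters (embedding matrix `E`, LSTM layer parameters,
#'   decoder `Wd`/`bd`) and an empty training history.
#' @export
init_language_model <- function(vocab, config = lm_config()) {
  stopifnot(inherits(vocab, "kmer_vocab"), inherits(config, "lm_config"))
  with_seed(config$seed, {
    E <- matrix(stats::rnorm(vocab$size * config$embedding_size, sd = 0.1),
                vocab$size, config$embedding_size)
    layers <- vector("list", config$n_layers)
    for (l in seq_len(config$n_layers)) {
      input_size <- if (l == 1) config$embedding_size else config$hidden_size
      layers[[l]] <- lstm_layer_params(input_size, config$hidden_size)
    }
    Wd <- matrix(stats::rnorm(config$hidden_size * vocab$size, sd = 0.05),
                 config$hidden_size, vocab$size)
  })
  structure(list(vocab = vocab, config = config,
                 params = list(E = E, layers = layers, Wd = Wd,
                               bd = numeric(vocab$size)),
                 history = data.frame(phase = character(0), epoch = integer(0),
                                      train_loss = numeric(0),
                                      val_loss = numeric(0)),
                 trained = FALSE),
            class = "language_model")
}

#' @export
print.language_model <- function(x, ...) {
  cat(sprintf(
    "k-mer language model: k=%d, vocab=%d, embedding=%d, %d LSTM layers x %d units%s\n",
    x$vocab$k, x$vocab$size, x$config$embedding_size, x$config$n_layers,
    x$config$hidden_size, if (x$trained) " (trained)" else " (untrained)"))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  last epoch: train CE %.4f, held-out CE %.4f\n",
                last$train_loss, last$val_loss))
  }
  invisible(x)
}

#' Look up token embeddings with stochastic regularization
#'
#' In training mode each token's embedding vector is zeroed with probability
#' `p_embeddings`; components of surviving vectors are independently zeroed
#' with probability `p_embeddings_dim`. Survivors are rescaled so the
#' expected embedding is unchanged. In evaluation mode this is a plain row
#' lookup.
#'
#' @param ids Integer token ids.
#' @param E Embedding matrix (vocabulary size x embedding size).
#' @param p_embeddings,p_embeddings_dim Drop probabilities.
#' @param training Logical.
#' @return A `length(ids) x ncol(E)` matrix of (possibly dropped) embeddings.
#' @export
embed_with_dropout <- function(ids, E, p_embeddings = 1e-3,
                               p_embeddings_dim = 1e-3, training = FALSE) {
  stopifnot(all(ids >= 1), all(ids <= nrow(E)))
  X <- E[ids, , drop = FALSE]
  mult <- embed_dropout_mult(length(ids), ncol(E), p_embeddings,
                             p_embeddings_dim, training)
  if (!is.null(mult)) X <- X * mult
  X
}

# Multiplier matrix implementing both embedding dropouts (NULL = identity).
embed_dropout_mult <- function(n, emb, p, pd, training) {
  if (!training || (p == 0 && pd == 0)) return(NULL)
  if (p >= 1) return(matrix(0, n, emb))   # certain drop: no rescaling
  keep_row <- stats::rbinom(n, 1, 1 - p) / (1 - p)
  mult <- matrix(keep_row, n, emb)
  if (pd > 0) {
    mult <- mult * matrix(stats::rbinom(n * emb, 1, 1 - pd) / (1 - pd), n, emb)
  }
  mult
}

# ---- internal stack forward/backward -------------------------------------

# inputs: B x T integer id matrix. Returns top-layer hidden states as a list
# over time plus everything needed for the backward pass.
lm_stack_forward <- function(params, inputs, cfg, training = FALSE,
                             keep_cache = FALSE) {
  B <- nrow(inputs); Tlen <- ncol(inputs)
  ids_flat <- as.vector(inputs)            # column-major: t-th block = batch
  Xflat <- params$E[ids_flat, , drop = FALSE]
  mult <- embed_dropout_mult(length(ids_flat), ncol(params$E),
                             cfg$p_embeddings, cfg$p_embeddings_dim, training)
  if (!is.null(mult)) Xflat <- Xflat * mult
  X <- lapply(seq_len(Tlen), function(t)
    Xflat[((t - 1) * B + 1):(t * B), , drop = FALSE])
  layer_fwds <- vector("list", length(params$layers))
  layer_masks <- vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    dc <- apply_dropconnect(params$layers[[l]], cfg$dropconnect, training)
    layer_masks[l] <- list(dc$masks)   # may be NULL; keep list slot
    fwd <- lstm_layer_forward(X, dc$params, keep_cache = keep_cache)
    layer_fwds[[l]] <- fwd
    X <- fwd$h
  }
  list(h_top = X, layer_fwds = layer_fwds, layer_masks = layer_masks,
       emb_mult = mult, ids_flat = ids_flat, B = B, Tlen = Tlen)
}

# dH_top: list over time of gradients w.r.t. top hidden states.
lm_stack_backward <- function(params, fwd, dH_top, cfg) {
  nl <- length(params$layers)
  layer_grads <- vector("list", nl)
  dH <- dH_top
  for (l in rev(seq_len(nl))) {
    bwd <- lstm_layer_backward(dH, fwd$layer_fwds[[l]])
    layer_grads[[l]] <- mask_lstm_grads(bwd$grads, fwd$layer_masks[[l]],
                                        cfg$dropconnect)
    dH <- bwd$dX
  }
  # dH now holds gradients w.r.t. the embedded inputs
  dXflat <- do.call(rbind, dH)
  if (!is.null(fwd$emb_mult)) dXflat <- dXflat * fwd$emb_mult
  grouped <- rowsum(dXflat, group = fwd$ids_flat)
  dE <- params$E * 0
  dE[as.integer(rownames(grouped)), ] <- grouped
  list(E = dE, layers = layer_grads)
}

# Fused decoder forward + loss + backward for one batch.
# inputs/targets: B x T; target_mask: B x T logical (FALSE at padding).
lm_train_step <- function(params, inputs, targets, target_mask, cfg,
                          training = TRUE) {
  fwd <- lm_stack_forward(params, inputs, cfg, training = training,
                          keep_cache = training)
  B <- fwd$B; Tlen <- fwd$Tlen; V <- ncol(params$Wd)
  n_tok <- sum(target_mask)
  loss <- 0
  dH_top <- if (training) vector("list", Tlen) else NULL
  dWd <- if (training) params$Wd * 0 else NULL
  dbd <- if (training) numeric(V) else NULL
  tWd <- t(params$Wd)
  for (t in seq_len(Tlen)) {
    H_t <- fwd$h_top[[t]]
    logits <- sweep(H_t %*% params$Wd, 2, params$bd, "+")
    logits <- logits - apply(logits, 1, max)
    expz <- exp(logits)
    p <- expz / rowSums(expz)
    mask_t <- target_mask[, t]
    tgt <- targets[, t]
    rows <- which(mask_t)
    if (length(rows)) {
      loss <- loss - sum(log(pmax(p[cbind(rows, tgt[rows])], 1e-12)))
    }
    if (training) {
      dlog <- p
      dlog[cbind(rows, tgt[rows])] <- dlog[cbind(rows, tgt[rows])] - 1
      dlog[!mask_t, ] <- 0
      dlog <- dlog / n_tok
      dH_top[[t]] <- dlog %*% tWd
      dWd <- dWd + crossprod(H_t, dlog)
      dbd <- dbd + colSums(dlog)
    }
  }
  loss <- loss / n_tok
  if (!training) return(list(loss = loss))
  grads <- lm_stack_backward(params, fwd, dH_top, cfg)
  grads$Wd <- dWd
  grads$bd <- dbd
  list(loss = loss, grads = grads)
}

# Build padded id batches from a list of token streams (bos already
# prepended). Returns list of lists(inputs, targets, mask).
lm_make_batches <- function(streams, batch_size, pad_id) {
  n <- length(streams)
  idx <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  lapply(idx, function(ii) {
    lens <- vapply(streams[ii], length, 1L)
    Tmax <- max(lens) - 1L        # inputs drop the last token
    B <- length(ii)
    inputs <- matrix(pad_id, B, Tmax)
    targets <- matrix(pad_id, B, Tmax)
    mask <- matrix(FALSE, B, Tmax)
    for (j in seq_len(B)) {
      s <- streams[[ii[j]]]
      L <- length(s) - 1L
      inputs[j, seq_len(L)] <- s[seq_len(L)]
      targets[j, seq_len(L)] <- s[1L + seq_len(L)]
      mask[j, seq_len(L)] <- TRUE
    }
    list(inputs = inputs, targets = targets, mask = mask)
  })
}

corpus_sequences <- function(corpus) {
  if (inherits(corpus, "benchmark_dataset")) corpus$seq
  else as.character(corpus)
}

# Shared training loop for pretraining and fine-tuning.
lm_train_loop <- function(model, corpus, cfg, phase) {
  seqs <- corpus_sequences(corpus)
  if (length(seqs) == 0) stopf("corpus is empty")
  vocab <- model$vocab
  streams <- lapply(seqs, numericalize, vocab = vocab, bos = TRUE)
  params <- model$params
  history <- model$history
  with_seed(cfg$seed, {
    n <- length(streams)
    n_val <- max(1L, round(cfg$val_frac * n))
    if (n < 2) { n_val <- 0L }
    perm <- sample(n)
    val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
    train_idx <- setdiff(perm, val_idx)
    val_batches <- if (n_val > 0)
      lm_make_batches(streams[val_idx], cfg$batch_size, vocab$pad_id)
    else NULL
    eval_loss <- function(p, batches) {
      tot <- 0; ntok <- 0
      for (b in batches) {
        r <- lm_train_step(p, b$inputs, b$targets, b$mask, cfg,
                           training = FALSE)
        nb <- sum(b$mask)
        tot <- tot + r$loss * nb; ntok <- ntok + nb
      }
      tot / ntok
    }
    best_params <- params
    best_val <- if (!is.null(val_batches)) eval_loss(params, val_batches) else Inf
    opt <- adam_init(params)
    wait <- 0L
    epoch <- 0L
    while (epoch < cfg$max_epochs) {
      epoch <- epoch + 1L
      order_ep <- sample(train_idx)
      batches <- lm_make_batches(streams[order_ep], cfg$batch_size,
                                 vocab$pad_id)
      ep_loss <- 0; ep_tok <- 0
      for (b in batches) {
        step <- lm_train_step(params, b$inputs, b$targets, b$mask, cfg,
                              training = TRUE)
        if (!is.finite(step$loss))
          stopf("language-model training diverged (non-finite loss at epoch %d)",
                epoch)
        nb <- sum(b$mask)
        ep_loss <- ep_loss + step$loss * nb; ep_tok <- ep_tok + nb
        upd <- adam_step(params, step$grads, opt, lr = cfg$learning_rate,
                         weight_decay = cfg$weight_decay)
        params <- upd$params; opt <- upd$state
      }
      val <- if (!is.null(val_batches)) eval_loss(params, val_batches) else NA_real_
      history <- rbind(history, data.frame(
        phase = phase, epoch = epoch, train_loss = ep_loss / ep_tok,
        val_loss = val))
      if (!is.null(val_batches)) {
        if (val < best_val - 1e-8) {
          best_val <- val; best_params <- params; wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= cfg$patience) break
        }
      } else {
        best_params <- params
      }
    }
  })
  model$params <- best_params
  model$history <- history
  model$trained <- TRUE
  model
}

#' Pretrain a next-k-mer language model
#'
#' Builds a k-mer vocabulary from the corpus (unless one is supplied),
#' initializes the model and optimizes next-k-mer cross-entropy with Adam.
#' A held-out fraction of the corpus drives early stopping; the parameters
#' with the best held-out loss are returned, so the final held-out loss never
#' exceeds the initial one.
#'
#' @param corpus Character vector of sequences or a [benchmark_dataset()].
#' @param k K-mer size.
#' @param config An [lm_config()].
#' @param vocab Optional pre-built [build_vocabulary()] (must use the same
#'   `k`).
#' @return A trained `language_model` with a `history` data frame of
#'   per-epoch train/held-out cross-entropies.
#' @export
pretrain_lm <- function(corpus, k, config = lm_config(), vocab = NULL) {
  seqs <- corpus_sequences(corpus)
  if (length(seqs) == 0) stopf("corpus is empty")
  if (is.null(vocab)) vocab <- build_vocabulary(seqs, k)
  if (vocab$k != k) stopf("vocabulary was built for k=%d, not k=%d", vocab$k, k)
  model <- init_language_model(vocab, config)
  lm_train_loop(model, seqs, config, phase = "pretrain")
}

#' Fine-tune a language model on a task corpus
#'
#' Continues next-k-mer training of an existing model on new sequences,
#' appending to its history. Useful for adapting a generically pretrained
#' model to the distribution of a labeled task corpus before classification.
#'
#' @param model A `language_model`.
#' @param corpus Sequences (character vector or [benchmark_dataset()]).
#' @param config Optional [lm_config()]; defaults to the model's own
#'   configuration. `max_epochs = 0` returns the model unchanged.
#' @param vocab Optional vocabulary; if supplied it must be identical to the
#'   model's (a mismatch is an error, since embeddings are tied to ids).
#' @return The fine-tuned `language_model`.
#' @export
fine_tune_lm <- function(model, corpus, config = NULL, vocab = NULL) {
  stopifnot(inherits(model, "language_model"))
  if (!is.null(vocab) && !identical(vocab$tokens, model$vocab$tokens))
    stopf("vocabulary mismatch: fine-tuning must reuse the pretraining vocabulary")
  cfg <- config %||% model$config
  if (cfg$max_epochs == 0) return(model)
  lm_train_loop(model, corpus, cfg, phase = "finetune")
}

#' Next-k-mer logits for a batch of sequences
#'
#' @param model A `language_model`.
#' @param sequences Character vector of equal-length sequences.
#' @param training Apply the stochastic layers (dropouts); `FALSE` gives the
#'   deterministic evaluation-mode forward pass.
#' @return An array `(batch, positions, vocab)`: the logits at position `t`
#'   predict the token at position `t + 1` of the bos-prefixed stream, i.e.
#'   entry `[, 1, ]` predicts the first real k-mer.
#' @export
lm_forward <- function(model, sequences, training = FALSE) {
  stopifnot(inherits(model, "language_model"))
  if (length(sequences) == 0) stopf("empty batch")
  streams <- lapply(corpus_sequences(sequences), numericalize,
                    vocab = model$vocab, bos = TRUE)
  lens <- vapply(streams, length, 1L)
  if (length(unique(lens)) != 1)
    stopf("lm_forward requires equal-length sequences")
  inputs <- do.call(rbind, streams)[, seq_len(lens[1] - 1L), drop = FALSE]
  fwd <- lm_stack_forward(model$params, inputs, model$config,
                          training = training)
  V <- ncol(model$params$Wd)
  out <- array(0, dim = c(nrow(inputs), ncol(inputs), V))
  for (t in seq_len(ncol(inputs))) {
    out[, t, ] <- sweep(fwd$h_top[[t]] %*% model$params$Wd, 2,
                        model$params$bd, "+")
  }
  out
}

#' Encode sequences as per-position language-model representations
#'
#' Runs the evaluation-mode (deterministic) forward pass and returns the
#' final LSTM layer's hidden state at every k-mer position.
#'
#' @param model A `language_model`.
#' @param sequences Character vector of sequences or a [benchmark_dataset()].
#' @param batch_size Sequences per forward batch.
#' @return A list (one element per sequence) of `positions x hidden_size`
#'   matrices.
#' @export
encode <- function(model, sequences, batch_size = NULL) {
  stopifnot(inherits(model, "language_model"))
  seqs <- corpus_sequences(sequences)
  bs <- batch_size %||% model$config$batch_size
  streams <- lapply(seqs, numericalize, vocab = model$vocab, bos = TRUE)
  lens <- vapply(streams, length, 1L)
  out <- vector("list", length(seqs))
  for (L in unique(lens)) {
    sel <- which(lens == L)
    for (chunk in split(sel, ceiling(seq_along(sel) / bs))) {
      inputs <- do.call(rbind, streams[chunk])   # includes bos at column 1
      fwd <- lm_stack_forward(model$params, inputs, model$config,
                              training = FALSE)
      # positions 2..L of the stream are the real k-mers
      H <- ncol(fwd$h_top[[1]])
      stacked <- vapply(2:L, function(t) fwd$h_top[[t]],
                        matrix(0, length(chunk), H))   # B x H x (L-1)
      for (j in seq_along(chunk)) {
        out[[chunk[j]]] <- t(matrix(stacked[j, , ], nrow = H))
      }
    }
  }
  out
}
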