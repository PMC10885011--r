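# One-call model fitting in the classic R modelling idiom: enhancer_fit()
# returns a classed object with print/summary/predict/plot methods.

#' Fit a two-stage enhancer classifier
#'
#' Trains the full pipeline on a labeled dataset: builds the k-mer
#' vocabulary, pretrains the next-k-mer language model on the training
#' sequences (self-supervised), then trains the CNN-attention classifier
#' head on the frozen language-model representations. An internal
#' stratified holdout (`test_frac`) is scored to report training-time
#' metrics; set `test_frac = 0` to train on everything.
#'
#' @param data A [benchmark_dataset()] (from [load_benchmark()] or the
#'   synthetic generators). Its task attribute selects the positive class:
#'   enhancer vs non-enhancer for identification, strong vs weak for
#'   strength.
#' @param k K-mer size; defaults to 2 for identification and 4 for strength.
#' @param lm_config An [lm_config()].
#' @param head_config A [head_config()]; defaults to the task's tuned values.
#' @param pretrain Set `FALSE` to skip self-supervised pretraining and use a
#'   randomly initialized encoder (the ablation baseline).
#' @param test_frac Fraction held out for the reported evaluation metrics.
#' @param seed Master seed for the split and both training stages.
#' @return An object of class `enhancer_fit` with components `lm`, `head`,
#'   `metrics` (a [compute_metrics()] report on the holdout, or `NULL`),
#'   `task`, `k` and `call`.
#' @examples
#' \donttest{
#' ds <- generate_identification_dataset(
#'   synthetic_spec(n_per_class = 60, length = 80, seed = 1))
#' fit <- enhancer_fit(ds, k = 2,
#'   lm_config = lm_config(embedding_size = 8, hidden_size = 8,
#'                         max_epochs = 1),
#'   head_config = head_config("identification", n_filters = 8,
#'                             max_epochs = 3))
#' predict(fit, ds$seq[1:3])
#' }
#' @export
enhancer_fit <- function(data, k = NULL, lm_config = NULL, head_config = NULL,
                         pretrain = TRUE, test_frac = 0.25, seed = 1L) {
  stopifnot(inherits(data, "benchmark_dataset"))
  task <- attr(data, "task")
  k <- k %||% if (task == "strength") 4L else 2L
  lm_cfg <- reseed(lm_config %||% lm_config(), seed)
  head_cfg <- reseed(head_config %||% head_config(task), seed)
  y <- dataset_y(data)
  if (test_frac > 0) {
    split <- holdout_split(y, test_frac, seed)
  } else {
    split <- list(train = seq_along(y), test = integer(0))
  }
  fit <- fit_and_score(data, split$train,
                       if (length(split$test)) split$test else split$train,
                       k, lm_cfg, head_cfg, pretrain = pretrain)
  structure(list(lm = fit$lm, head = fit$head,
                 metrics = if (length(split$test)) fit$metrics else NULL,
                 task = task, k = k, n_train = length(split$train),
                 n_test = length(split$test), seed = seed,
                 pretrain = pretrain, call = match.call()),
            class = "enhancer_fit")
}

#' @export
print.enhancer_fit <- function(x, ...) {
  cat(sprintf("Two-stage enhancer classifier (task: %s, k = %d)\n",
              x$task, x$k))
  cat(sprintf("  encoder: %s language model, vocab %d, %d x %d LSTM units\n",
              if (x$pretrain) "pretrained" else "random",
              x$lm$vocab$size, x$lm$config$n_layers, x$lm$config$hidden_size))
  cat(sprintf("  head: %d filters (kernel %d), trained on %d sequences\n",
              x$head$config$n_filters, x$head$config$kernel_size, x$n_train))
  if (!is.null(x$metrics))
    cat(sprintf("  holdout (n=%d): ACC %.1f%%, MCC %.3f, AUROC %.3f\n",
                x$n_test, x$metrics$ACC, x$metrics$MCC, x$metrics$AUROC))
  invisible(x)
}

#' @export
summary.enhancer_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$metrics)) {
    cat("\nHoldout metrics:\n")
    print(object$metrics)
    cat(sprintf("bias assessment: %s\n", bias_report(object$metrics)))
  }
  lm_hist <- object$lm$history
  if (nrow(lm_hist)) {
    cat(sprintf("\nlanguage model: %d epoch(s), final held-out CE %.4f\n",
                nrow(lm_hist), lm_hist$val_loss[nrow(lm_hist)]))
  }
  head_hist <- object$head$history
  if (nrow(head_hist)) {
    cat(sprintf("classifier head: %d epoch(s), best val loss %.4f\n",
                nrow(head_hist), min(head_hist$val_loss)))
  }
  invisible(object)
}

#' Predict enhancer class for new sequences
#'
#' @param object An [enhancer_fit()] model.
#' @param newdata Character vector of sequences or a [benchmark_dataset()].
#' @param type `"prob"` for the two-column probability matrix, `"class"` for
#'   hard labels at threshold 0.5, `"score"` for the positive-class
#'   probability vector.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.enhancer_fit <- function(object, newdata,
                                 type = c("prob", "class", "score"), ...) {
  type <- match.arg(type)
  probs <- classify(object$lm, object$head, newdata)
  pos_label <- if (object$task == "strength") "strong" else "enhancer"
  neg_label <- if (object$task == "strength") "weak" else "non_enhancer"
  switch(type,
         prob = {
           colnames(probs) <- c(neg_label, pos_label)
           probs
         },
         score = probs[, 2],
         class = ifelse(probs[, 2] >= 0.5, pos_label, neg_label))
}

#' Plot training history of a fitted enhancer classifier
#'
#' Shows the language-model and classifier-head loss curves.
#'
#' @param x An [enhancer_fit()] model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.enhancer_fit <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  lm_hist <- x$lm$history
  if (nrow(lm_hist)) {
    graphics::matplot(seq_len(nrow(lm_hist)),
                      cbind(lm_hist$train_loss, lm_hist$val_loss),
                      type = "l", lty = 1:2, col = c("black", "red"),
                      xlab = "epoch", ylab = "cross-entropy",
                      main = "language model", ...)
    graphics::legend("topright", c("train", "held-out"), lty = 1:2,
                     col = c("black", "red"), bty = "n")
  }
  hh <- x$head$history
  if (nrow(hh)) {
    graphics::matplot(hh$epoch, cbind(hh$train_loss, hh$val_loss),
                      type = "l", lty = 1:2, col = c("black", "red"),
                      xlab = "epoch", ylab = "cross-entropy",
                      main = "classifier head", ...)
  }
  invisible(x)
}
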