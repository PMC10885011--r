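# Metric suite, stratified cross-validation, grid search and the two
# experiment drivers (k-mer-size sweep, language-model ablation).

#' Six-measure evaluation report for binary scores
#'
#' Thresholds the positive-class scores, tabulates the confusion counts and
#' computes accuracy, sensitivity and specificity (as percentages), the
#' Matthews correlation coefficient, AUROC (trapezoidal integration of the
#' ROC curve, tie-aware) and AUPRC (step-wise precision-recall
#' integration). The balanced accuracy `(SN + SP) / 2` is reported
#' alongside. With a single-class truth vector the ranking metrics are
#' undefined and returned as `NA` with a warning.
#'
#' @param y_true 0/1 labels (1 = positive class).
#' @param y_score Positive-class probabilities or scores.
#' @param threshold Decision threshold on the score (default 0.5).
#' @return An object of class `metric_report`.
#' @export
compute_metrics <- function(y_true, y_score, threshold = 0.5) {
  stopifnot(length(y_true) == length(y_score))
  y <- as.integer(y_true)
  stopifnot(all(y %in% c(0L, 1L)))
  pred <- as.integer(y_score >= threshold)
  TP <- sum(pred == 1 & y == 1); TN <- sum(pred == 0 & y == 0)
  FP <- sum(pred == 1 & y == 0); FN <- sum(pred == 0 & y == 1)
  n <- length(y)
  ACC <- 100 * (TP + TN) / n
  SN <- if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_
  SP <- if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_
  denom <- sqrt(prod(c(TN + FN, TN + FP, TP + FN, TP + FP)))
  MCC <- if (denom > 0) ((TP * TN) - (FP * FN)) / denom else 0
  if (length(unique(y)) < 2) {
    warnf("y_true contains a single class: AUROC/AUPRC are undefined")
    AUROC <- NA_real_; AUPRC <- NA_real_
  } else {
    AUROC <- auroc_trapezoid(y, y_score)
    AUPRC <- auprc_step(y, y_score)
  }
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN, n = n,
                 threshold = threshold, ACC = ACC, SN = SN, SP = SP,
                 MCC = MCC, AUROC = AUROC, AUPRC = AUPRC,
                 balanced_accuracy = (SN + SP) / 2),
            class = "metric_report")
}

# Tie-aware trapezoidal area under the ROC curve.
auroc_trapezoid <- function(y, score) {
  ord <- order(score, decreasing = TRUE)
  y <- y[ord]; score <- score[ord]
  # cumulative counts at each distinct threshold
  last_of_tie <- c(score[-1] != score[-length(score)], TRUE)
  tp <- cumsum(y)[last_of_tie]
  fp <- cumsum(1 - y)[last_of_tie]
  P <- sum(y); N <- length(y) - P
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# Step-wise (average-precision style) area under the precision-recall curve,
# with tied scores grouped.
auprc_step <- function(y, score) {
  ord <- order(score, decreasing = TRUE)
  y <- y[ord]; score <- score[ord]
  last_of_tie <- c(score[-1] != score[-length(score)], TRUE)
  tp <- cumsum(y)[last_of_tie]
  n_pred <- seq_along(y)[last_of_tie]
  P <- sum(y)
  precision <- tp / n_pred
  recall <- tp / P
  sum(diff(c(0, recall)) * precision)
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("confusion (threshold %.2f): TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$threshold, x$TP, x$TN, x$FP, x$FN, x$n))
  cat(sprintf("ACC %.2f%%  SN %.2f%%  SP %.2f%%  MCC %.4f  AUROC %.4f  AUPRC %.4f\n",
              x$ACC, x$SN, x$SP, x$MCC, x$AUROC, x$AUPRC))
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(TP = x$TP, TN = x$TN, FP = x$FP, FN = x$FN, ACC = x$ACC,
             SN = x$SN, SP = x$SP, MCC = x$MCC, AUROC = x$AUROC,
             AUPRC = x$AUPRC, balanced_accuracy = x$balanced_accuracy)
}

#' Classify a predictor's sensitivity/specificity bias
#'
#' A difference of more than 5 percentage points between sensitivity and
#' specificity marks a biased predictor: excess sensitivity (false
#' positives) is type-1-prone, excess specificity (false negatives) is
#' type-2-prone.
#'
#' @param report A [compute_metrics()] result, or a list with `SN` and `SP`
#'   percentages.
#' @return `"unbiased"`, `"type1_prone"` or `"type2_prone"`.
#' @export
bias_report <- function(report) {
  d <- report$SN - report$SP
  if (abs(d) <= 5) "unbiased" else if (d > 5) "type1_prone" else "type2_prone"
}

#' Stratified k-fold assignment
#'
#' Partitions examples into folds with per-fold class ratios within one
#' example of the global ratio. Deterministic under `seed`.
#'
#' @param y Binary labels (or a [benchmark_dataset()], whose task label is
#'   used).
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1..n_folds`.
#' @export
stratified_kfold <- function(y, n_folds = 5L, seed = 1L) {
  if (inherits(y, "benchmark_dataset")) y <- dataset_y(y)
  counts <- table(y)
  if (any(counts < n_folds))
    stopf("n_folds = %d exceeds the smallest class count (%d)", n_folds,
          min(counts))
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in names(counts)) {
      ii <- sample(which(y == cl))
      fold[ii] <- rep_len(seq_len(n_folds), length(ii))
    }
  })
  fold
}

# Stratified train/test index split.
holdout_split <- function(y, test_frac = 0.25, seed = 1L) {
  test_idx <- integer(0)
  with_seed(seed, {
    for (cl in unique(y)) {
      ii <- sample(which(y == cl))
      test_idx <- c(test_idx, ii[seq_len(max(1L, round(test_frac * length(ii))))])
    }
  })
  list(train = setdiff(seq_along(y), test_idx), test = sort(test_idx))
}

#' Train a classifier head on a labeled dataset
#'
#' Encodes the dataset with a (frozen) language model and trains the
#' CNN-attention head on the task's binary labels.
#'
#' @param dataset A [benchmark_dataset()] with both classes present.
#' @param lm A `language_model`.
#' @param config A [head_config()].
#' @return A `classifier_head`.
#' @export
train_classifier <- function(dataset, lm, config = NULL) {
  stopifnot(inherits(dataset, "benchmark_dataset"))
  cfg <- config %||% head_config(attr(dataset, "task"))
  enc <- encode(lm, dataset$seq)
  train_classifier_head(enc, dataset_y(dataset), cfg)
}

# Train LM (optional) + head on train rows of `dataset`; evaluate on test
# rows. Workhorse behind cross_validate / kmer_sweep / ablation_lm.
fit_and_score <- function(dataset, train, test, k, lm_cfg, head_cfg,
                          pretrain = TRUE, lm = NULL) {
  y <- dataset_y(dataset)
  if (is.null(lm)) {
    vocab <- build_vocabulary(dataset$seq[train], k)
    lm <- if (pretrain) {
      pretrain_lm(dataset$seq[train], k, lm_cfg, vocab = vocab)
    } else {
      init_language_model(vocab, lm_cfg)
    }
  }
  enc_train <- encode(lm, dataset$seq[train])
  head <- train_classifier_head(enc_train, y[train], head_cfg)
  probs <- classify(lm, head, dataset$seq[test])
  list(metrics = compute_metrics(y[test], probs[, "positive"]),
       scores = probs[, "positive"], lm = lm, head = head)
}

reseed <- function(cfg, seed) { cfg$seed <- as.integer(seed %% 2147483647); cfg }

#' Stratified 5-fold cross-validation of the full pipeline
#'
#' For every fold: builds the k-mer vocabulary and (optionally) pretrains
#' the language model on the fold's training sequences only, trains the
#' classifier head, and evaluates on the held-out fold. By default the
#' language model is retrained per fold so no test sequence influences
#' representation learning; `shared_lm = TRUE` trains one model on all
#' sequences first (cheaper, but lets unlabeled test sequences into
#' language-model training).
#'
#' @param dataset A [benchmark_dataset()].
#' @param k K-mer size.
#' @param lm_config,head_config Configurations; their seeds are re-derived
#'   per fold from `seed`.
#' @param n_folds Number of folds.
#' @param seed Master seed (fold assignment and per-fold training).
#' @param pretrain `FALSE` replaces the pretrained language model by a
#'   randomly initialized encoder.
#' @param shared_lm Train a single language model on the full dataset.
#' @return An object of class `cv_result`: per-fold `metric_report`s, their
#'   `mean` metrics, and the fold assignment.
#' @export
cross_validate <- function(dataset, k = 2L, lm_config = lm_config(),
                           head_config = NULL, n_folds = 5L, seed = 1L,
                           pretrain = TRUE, shared_lm = FALSE) {
  stopifnot(inherits(dataset, "benchmark_dataset"))
  head_cfg <- head_config %||% head_config(attr(dataset, "task"))
  fold <- stratified_kfold(dataset, n_folds = n_folds, seed = seed)
  shared <- NULL
  if (shared_lm) {
    shared <- pretrain_lm(dataset$seq, k, reseed(lm_config, seed),
                          vocab = build_vocabulary(dataset$seq, k))
  }
  reports <- vector("list", n_folds)
  t0 <- proc.time()[["elapsed"]]
  for (f in seq_len(n_folds)) {
    fit <- fit_and_score(dataset, which(fold != f), which(fold == f), k,
                         reseed(lm_config, seed + 1000 * f),
                         reseed(head_cfg, seed + 1000 * f),
                         pretrain = pretrain, lm = shared)
    reports[[f]] <- fit$metrics
  }
  structure(list(folds = reports, mean = metrics_mean(reports),
                 fold_assignment = fold, k = k, n_folds = n_folds,
                 seed = seed, pretrain = pretrain,
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "cv_result")
}

metrics_mean <- function(reports) {
  keys <- c("ACC", "SN", "SP", "MCC", "AUROC", "AUPRC", "balanced_accuracy")
  sapply(keys, function(k) mean(vapply(reports, function(r) r[[k]], 1)))
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (k=%d, %s language model)\n",
              x$n_folds, x$k,
              if (x$pretrain) "pretrained" else "randomly initialized"))
  tab <- do.call(rbind, lapply(x$folds, as.data.frame))
  tab <- rbind(tab, c(rep(NA, 4), x$mean[colnames(tab)[-(1:4)]]))
  rownames(tab) <- c(paste0("fold", seq_along(x$folds)), "mean")
  print(round(tab[, c("ACC", "SN", "SP", "MCC", "AUROC", "AUPRC")], 4))
  invisible(x)
}

#' @export
as.data.frame.cv_result <- function(x, ...) {
  tab <- do.call(rbind, lapply(x$folds, as.data.frame))
  tab <- cbind(fold = seq_along(x$folds), tab)
  mean_row <- cbind(fold = NA, TP = NA, TN = NA, FP = NA, FN = NA,
                    as.data.frame(t(x$mean))[c("ACC", "SN", "SP", "MCC",
                                               "AUROC", "AUPRC",
                                               "balanced_accuracy")])
  rbind(tab, mean_row)
}

#' Grid search over hyperparameter candidates
#'
#' Exhaustively (or up to `budget` configurations, in deterministic order)
#' evaluates every combination of the supplied candidate lists on a
#' stratified holdout split, ranking by validation MCC with accuracy and
#' then smaller model size as tie-breaks. Fields named like [head_config()]
#' arguments configure the head; `embedding_size`, `hidden_size` and
#' `n_layers` configure the language model (which is retrained per distinct
#' combination).
#'
#' @param dataset A [benchmark_dataset()].
#' @param grid Named list of candidate vectors.
#' @param k K-mer size.
#' @param lm_config Base [lm_config()].
#' @param seed Master seed.
#' @param budget Maximum number of configurations to evaluate.
#' @param test_frac Holdout fraction used for validation scoring.
#' @param pretrain Pretrain the language model (else random encoder).
#' @return List with `best` (the winning configuration as a named list) and
#'   `leaderboard` (one row per evaluated configuration, ranked).
#' @export
grid_search <- function(dataset, grid, k = 2L, lm_config = lm_config(),
                        seed = 1L, budget = Inf, test_frac = 0.25,
                        pretrain = FALSE) {
  if (length(grid) == 0 || any(!vapply(grid, length, 1L)))
    stopf("grid must be a non-empty named list of non-empty candidate vectors")
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  n_eval <- min(nrow(combos), budget)
  combos <- combos[seq_len(n_eval), , drop = FALSE]
  y <- dataset_y(dataset)
  split <- holdout_split(y, test_frac, seed)
  lm_fields <- intersect(names(combos), c("embedding_size", "hidden_size",
                                          "n_layers"))
  head_fields <- setdiff(names(combos), lm_fields)
  task <- attr(dataset, "task")
  lm_cache <- list()
  rows <- vector("list", n_eval)
  for (i in seq_len(n_eval)) {
    lm_cfg <- reseed(lm_config, seed)
    for (f in lm_fields) lm_cfg[[f]] <- combos[i, f]
    lm_key <- paste(unlist(combos[i, lm_fields]), collapse = "_")
    if (is.null(lm_cache[[lm_key]])) {
      vocab <- build_vocabulary(dataset$seq[split$train], k)
      lm_cache[[lm_key]] <- if (pretrain) {
        pretrain_lm(dataset$seq[split$train], k, lm_cfg, vocab = vocab)
      } else init_language_model(vocab, lm_cfg)
    }
    head_cfg <- do.call(head_config,
                        c(list(task = task), as.list(combos[i, head_fields,
                                                            drop = FALSE]),
                          list(seed = seed)))
    m <- tryCatch(
      fit_and_score(dataset, split$train, split$test, k, lm_cfg,
                    head_cfg, lm = lm_cache[[lm_key]])$metrics,
      error = function(e) list(MCC = -Inf, ACC = -Inf, AUROC = NA_real_))
    rows[[i]] <- cbind(combos[i, , drop = FALSE],
                       data.frame(MCC = m$MCC, ACC = m$ACC, AUROC = m$AUROC))
  }
  leaderboard <- do.call(rbind, rows)
  size_proxy <- if ("n_filters" %in% names(leaderboard))
    leaderboard$n_filters else rep(0, nrow(leaderboard))
  ord <- order(-leaderboard$MCC, -leaderboard$ACC, size_proxy)
  leaderboard <- leaderboard[ord, , drop = FALSE]
  rownames(leaderboard) <- NULL
  list(best = as.list(leaderboard[1, names(combos), drop = FALSE]),
       leaderboard = leaderboard)
}

#' Performance as a function of k-mer size
#'
#' Re-runs the full pipeline (vocabulary, language model, head) for each
#' k-mer size on a shared stratified train/test split and tabulates the
#' evaluation measures per k.
#'
#' @param dataset A [benchmark_dataset()].
#' @param k_values Integer vector of k-mer sizes.
#' @param lm_config,head_config Configurations (seeds re-derived per k from
#'   `seed`).
#' @param seed Master seed.
#' @param test_frac Holdout fraction.
#' @param pretrain Pretrain the language model per k.
#' @return A data frame with one row per k and columns
#'   ACC/SN/SP/MCC/AUROC/AUPRC.
#' @export
kmer_sweep <- function(dataset, k_values = 1:6, lm_config = lm_config(),
                       head_config = NULL, seed = 1L, test_frac = 0.25,
                       pretrain = TRUE) {
  stopifnot(inherits(dataset, "benchmark_dataset"))
  if (any(k_values > min(nchar(dataset$seq))))
    stopf("some k exceed the shortest sequence length")
  head_cfg <- head_config %||% head_config(attr(dataset, "task"))
  y <- dataset_y(dataset)
  split <- holdout_split(y, test_frac, seed)
  rows <- lapply(k_values, function(k) {
    fit <- fit_and_score(dataset, split$train, split$test, k,
                         reseed(lm_config, seed + k),
                         reseed(head_cfg, seed + k), pretrain = pretrain)
    cbind(data.frame(k = k), as.data.frame(fit$metrics))
  })
  do.call(rbind, rows)
}

#' Language-model ablation: pretrained versus random embeddings
#'
#' Runs two otherwise identical pipelines on the same stratified train/test
#' split: one whose encoder is the pretrained (self-supervised) language
#' model, one whose encoder is randomly initialized. Reports both metric
#' sets and the AUROC/AUPRC deltas (pretrained minus random).
#'
#' @param dataset A [benchmark_dataset()].
#' @param k K-mer size.
#' @param lm_config,head_config Configurations.
#' @param seed Master seed (shared by both arms).
#' @param test_frac Holdout fraction.
#' @return An object of class `lm_ablation`.
#' @export
ablation_lm <- function(dataset, k = 2L, lm_config = lm_config(),
                        head_config = NULL, seed = 1L, test_frac = 0.25) {
  stopifnot(inherits(dataset, "benchmark_dataset"))
  head_cfg <- head_config %||% head_config(attr(dataset, "task"))
  y <- dataset_y(dataset)
  split <- holdout_split(y, test_frac, seed)
  arm <- function(pretrain) {
    fit_and_score(dataset, split$train, split$test, k,
                  reseed(lm_config, seed), reseed(head_cfg, seed),
                  pretrain = pretrain)$metrics
  }
  pre <- arm(TRUE)
  rnd <- arm(FALSE)
  structure(list(pretrained = pre, random = rnd,
                 delta_auroc = pre$AUROC - rnd$AUROC,
                 delta_auprc = pre$AUPRC - rnd$AUPRC,
                 split = split, k = k, seed = seed),
            class = "lm_ablation")
}

#' @export
print.lm_ablation <- function(x, ...) {
  cat("language-model ablation (pretrained vs random encoder)\n")
  cat(sprintf("  pretrained: AUROC %.4f  AUPRC %.4f\n",
              x$pretrained$AUROC, x$pretrained$AUPRC))
  cat(sprintf("  random:     AUROC %.4f  AUPRC %.4f\n",
              x$random$AUROC, x$random$AUPRC))
  cat(sprintf("  delta:      AUROC %+.4f AUPRC %+.4f\n",
              x$delta_auroc, x$delta_auprc))
  invisible(x)
}
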