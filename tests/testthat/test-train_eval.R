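test_that("compute_metrics reproduces hand-evaluated confusion formulas", {
  # perfect separation
  perfect <- compute_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(perfect$ACC, 100)
  expect_equal(perfect$SN, 100)
  expect_equal(perfect$SP, 100)
  expect_equal(perfect$MCC, 1)
  expect_equal(perfect$AUROC, 1)
  expect_equal(perfect$AUPRC, 1)

  # TP=50 TN=40 FP=10 FN=0, constructed from scores around 0.5
  y <- c(rep(1, 50), rep(0, 40), rep(0, 10))
  s <- c(rep(0.9, 50), rep(0.1, 40), rep(0.9, 10))
  m <- compute_metrics(y, s)
  expect_equal(c(m$TP, m$TN, m$FP, m$FN), c(50, 40, 10, 0))
  expect_equal(m$ACC, 90)
  expect_equal(m$SN, 100)
  expect_equal(m$SP, 80)
  expect_equal(m$MCC,
               (50 * 40 - 10 * 0) / sqrt((40 + 0) * (40 + 10) * (50 + 0) * (50 + 10)))
  expect_equal(m$balanced_accuracy, 90)
})

test_that("random scores on balanced labels give chance-level AUROC", {
  set.seed(100)
  y <- rep(c(0, 1), 5000)
  m <- compute_metrics(y, runif(10000))
  expect_lt(abs(m$AUROC - 0.5), 0.02)
})

test_that("AUROC equals the all-pairs concordance oracle, ties included", {
  set.seed(101)
  y <- rbinom(200, 1, 0.5)
  score <- round(runif(200), 1)  # heavy ties
  m <- compute_metrics(y, score)
  expect_equal(m$AUROC, ref_auroc_pairs(y, score), tolerance = 1e-9)
  # independent library cross-check
  expect_equal(m$AUROC,
               as.numeric(pROC::auc(pROC::roc(y, score, quiet = TRUE,
                                              direction = "<",
                                              levels = c(0, 1)))),
               tolerance = 1e-9)

  expect_warning(m1 <- compute_metrics(rep(1, 5), runif(5)), "single class")
  expect_true(is.na(m1$AUROC))
})

test_that("bias classification follows the five-point sensitivity rule", {
  expect_equal(bias_report(list(SN = 94.6, SP = 94.9)), "unbiased")
  expect_equal(bias_report(list(SN = 96.1, SP = 53.7)), "type1_prone")
  expect_equal(bias_report(list(SN = 53.7, SP = 96.1)), "type2_prone")
  expect_equal(bias_report(list(SN = 80, SP = 80)), "unbiased")
})

test_that("stratified folds partition the data with balanced classes", {
  y <- rep(c(0, 1), each = 5)
  fold <- stratified_kfold(y, 5, seed = 3)
  for (f in 1:5) {
    expect_equal(sum(fold == f & y == 0), 1)
    expect_equal(sum(fold == f & y == 1), 1)
  }
  expect_identical(fold, stratified_kfold(y, 5, seed = 3))

  y2 <- rep(c(0, 1), c(40, 37))
  fold2 <- stratified_kfold(y2, 5, seed = 9)
  expect_setequal(unique(fold2), 1:5)
  expect_equal(length(fold2), 77)
  ratios <- sapply(1:5, function(f) sum(fold2 == f & y2 == 1))
  expect_lte(diff(range(ratios)), 1)

  expect_error(stratified_kfold(c(0, 1, 1, 1), 3), "exceeds")
})

test_that("cross-validation yields one report per fold and aggregates them", {
  ds <- generate_identification_dataset(
    synthetic_spec(n_per_class = 25, length = 40, gc_positive = 0.65,
                   gc_negative = 0.35, seed = 17))
  cv <- cross_validate(ds, k = 2, lm_config = tiny_lm_config(),
                       head_config = tiny_head_config(max_epochs = 6),
                       n_folds = 5, seed = 2, pretrain = FALSE)
  expect_length(cv$folds, 5)
  expect_setequal(unique(cv$fold_assignment), 1:5)
  expect_equal(cv$mean[["AUROC"]],
               mean(vapply(cv$folds, function(r) r$AUROC, 1)))
  tab <- as.data.frame(cv)
  expect_equal(nrow(tab), 6)  # 5 folds + mean row
})

test_that("grid search ranks configurations and survives diverging ones", {
  ds <- generate_identification_dataset(
    synthetic_spec(n_per_class = 20, length = 40, gc_positive = 0.7,
                   gc_negative = 0.3, seed = 23))
  g1 <- grid_search(ds, list(n_filters = 8L), k = 2,
                    lm_config = tiny_lm_config(), seed = 1)
  expect_equal(g1$best$n_filters, 8L)
  expect_equal(nrow(g1$leaderboard), 1)

  g2 <- grid_search(ds, list(learning_rate = c(1e3, 1e-3),
                             max_epochs = 8L),
                    k = 2, lm_config = tiny_lm_config(), seed = 1)
  expect_equal(nrow(g2$leaderboard), 2)
  expect_equal(g2$best$learning_rate, 1e-3)  # the absurd rate diverges

  expect_error(grid_search(ds, list()), "non-empty")
})

test_that("the head memorizes a small sample with regularization off", {
  corpus <- random_dna(10, 40, seed = 55)
  v <- build_vocabulary(corpus, 2)
  lm <- init_language_model(v, lm_config(embedding_size = 10,
                                         hidden_size = 12, seed = 5))
  enc <- encode(lm, corpus)
  y <- rep(c(1, 0), 5)
  head <- train_classifier_head(
    enc, y, head_config("identification", n_filters = 10, dropout = 0,
                        weight_decay = 0, learning_rate = 5e-3,
                        max_epochs = 200, patience = 200, val_frac = 0.2,
                        seed = 6))
  expect_lt(min(head$history$train_loss), 0.05)
})

test_that("early stopping in the head trainer respects patience", {
  corpus <- random_dna(24, 30, seed = 77)
  v <- build_vocabulary(corpus, 2)
  lm <- init_language_model(v, lm_config(embedding_size = 8, hidden_size = 8,
                                         seed = 1))
  enc <- encode(lm, corpus)
  y <- rep(c(1, 0), 12)  # pure noise: validation loss cannot keep improving
  head <- train_classifier_head(
    enc, y, head_config("identification", n_filters = 6, max_epochs = 100,
                        patience = 2, learning_rate = 5e-2, seed = 2))
  expect_lt(nrow(head$history), 100)
})
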