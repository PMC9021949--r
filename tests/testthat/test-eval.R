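test_that("confusion matrix counts match a dictionary oracle", {
  expect_identical(unname(confusion_matrix(c(0L, 1L), c(0L, 1L))[1:2, 1:2]),
                   diag(1L, 2))
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    truth <- sample(0:8, n, replace = TRUE)
    pred <- sample(0:8, n, replace = TRUE)
    cm <- confusion_matrix(pred, truth)
    expect_identical(sum(cm), n)
    expect_identical(as.integer(rowSums(cm)), tabulate(truth + 1L, 9L))
    # dictionary-count oracle
    for (pair in sample(81, 5)) {
      i <- (pair - 1) %/% 9; j <- (pair - 1) %% 9
      expect_identical(cm[i + 1, j + 1], sum(truth == i & pred == j))
    }
  }
  expect_error(confusion_matrix(c(0L, 9L), c(0L, 1L)), "out of range")
  expect_error(confusion_matrix(0L, c(0L, 1L)), "equal length")
})

test_that("micro-averaged F1 equals accuracy in single-label multiclass", {
  set.seed(72)
  for (rep in 1:10) {
    n <- 1000L
    truth <- sample(0:8, n, replace = TRUE)
    pred <- sample(0:8, n, replace = TRUE)
    cm <- confusion_matrix(pred, truth)
    acc <- sum(diag(cm)) / n
    prf <- prf_scores(cm)
    expect_identical(prf$micro$f1, acc)
    expect_identical(prf$micro$precision, acc)
    expect_identical(prf$micro$recall, acc)
  }
})

test_that("log-loss analytic limits", {
  n <- 50L
  labels <- sample(0:8, n, replace = TRUE)
  unif <- matrix(1 / 9, n, 9)
  expect_equal(log_loss(unif, labels), log(9), tolerance = 1e-12)
  perfect <- diag(9)[labels + 1L, ]
  expect_equal(log_loss(perfect, labels), 0, tolerance = 1e-12)
  expect_error(log_loss(matrix(numeric(0), 0, 9), integer(0)), "empty")
})

test_that("the four-sample hand-computed ROC gives AUC 0.75", {
  # scores (0.9, 0.8, 0.3, 0.1) against labels (+, -, +, -):
  # 3 of 4 positive/negative pairs are correctly ordered
  probs <- cbind(1 - c(0.9, 0.8, 0.3, 0.1), c(0.9, 0.8, 0.3, 0.1))
  labels <- c(1L, 0L, 1L, 0L)
  roc <- roc_curves(probs, labels)
  expect_equal(roc$per_class[[2]]$auc, 0.75)
})

test_that("ROC limits: perfect separation and label-independent scores", {
  set.seed(73)
  n <- 300L
  labels <- sample(0:8, n, replace = TRUE)
  perfect <- 0.1 + 0.8 * diag(9)[labels + 1L, ]
  perfect <- perfect / rowSums(perfect)
  roc <- roc_curves(perfect, labels)
  expect_true(all(vapply(roc$per_class, `[[`, numeric(1), "auc") == 1))
  expect_equal(roc$macro_auc, 1)
  # scores independent of the labels concentrate near AUC 0.5
  n <- 4000L
  labels <- sample(0:1, n, replace = TRUE)
  s <- stats::runif(n)
  probs <- cbind(1 - s, s)
  auc <- roc_curves(probs, labels)$per_class[[2]]$auc
  npos <- sum(labels == 1); nneg <- n - npos
  se <- sqrt((npos + nneg + 1) / (12 * npos * nneg))
  expect_lt(abs(auc - 0.5), 3 * se)
})

test_that("authored AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(74)
  n <- 250L
  labels <- sample(0:8, n, replace = TRUE)
  raw <- matrix(stats::rexp(n * 9), n, 9)
  # inject signal so AUCs are away from 0.5
  raw[cbind(seq_len(n), labels + 1L)] <- raw[cbind(seq_len(n), labels + 1L)] +
    stats::rexp(n, 1 / 2)
  probs <- raw / rowSums(raw)
  mine <- roc_curves(probs, labels)
  for (cls in 0:8) {
    ref <- suppressMessages(
      pROC::auc(pROC::roc(as.integer(labels == cls), probs[, cls + 1L],
                          direction = "<", quiet = TRUE)))
    expect_equal(mine$per_class[[cls + 1L]]$auc, as.numeric(ref),
                 tolerance = 1e-10)
  }
})

test_that("a class absent from the test labels is excluded with a warning", {
  labels <- c(0L, 0L, 1L, 1L)
  probs <- matrix(1 / 3, 4, 3)
  probs[, 1] <- c(0.5, 0.6, 0.2, 0.1)
  probs <- probs / rowSums(probs)
  expect_warning(roc <- roc_curves(probs, labels), "class 2 absent")
  expect_true(is.na(roc$per_class[[3]]$auc))
  expect_false(is.na(roc$macro_auc))
})

test_that("evaluate ties every metric to one prediction pass", {
  sch <- tiny_schema()
  ds <- tiny_dataset(160L, schema = sch)
  sp <- split_train_test(ds, 0.75, seed = 75L)
  m <- train_cfgcnn(sp$train, sch, tiny_config(),
                    train_config(epochs = 8L, batch_size = 32L, seed = 76L))
  rep_ <- suppressWarnings(evaluate(m, sp$test))  # tiny split may miss classes
  expect_identical(sum(rep_$confusion), rep_$n)
  expect_equal(sum(diag(rep_$confusion)) / rep_$n, rep_$accuracy)
  expect_identical(rep_$f1, rep_$accuracy)   # micro-F1 == accuracy
  probs <- predict(m, sp$test, type = "prob")
  expect_equal(rep_$log_loss, cross_entropy_loss(probs, sp$test$labels),
               tolerance = 1e-12)
  expect_error(evaluate(m, symptom_dataset(matrix(integer(0), 0, sch$n_f),
                                           schema = sch)),
               "non-empty")
})
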