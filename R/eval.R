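#' Confusion matrix
#'
#' Entry `(i, j)` counts cases with true class `i` predicted as class `j`
#' (zero-based labels, one-based matrix indices). Row sums are the
#' per-class test counts; the trace over the total is the accuracy.
#'
#' @param preds Zero-based predicted labels.
#' @param labels Zero-based true labels (same length).
#' @param n_classes Number of classes (default 9).
#' @return Integer `n_classes x n_classes` matrix with class-abbreviation
#'   dimnames (rows = truth, columns = prediction).
#' @export
confusion_matrix <- function(preds, labels,
                             n_classes = n_syndrome_classes()) {
  preds <- as.integer(preds); labels <- as.integer(labels)
  if (length(preds) != length(labels)) {
    stop("preds and labels must have equal length", call. = FALSE)
  }
  if (any(preds < 0L | preds >= n_classes | labels < 0L |
          labels >= n_classes)) {
    stop("label out of range [0, ", n_classes, ")", call. = FALSE)
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(preds)) {
    cm[labels[i] + 1L, preds[i] + 1L] <- cm[labels[i] + 1L, preds[i] + 1L] + 1L
  }
  ab <- syndrome_types()$abbrev
  if (n_classes == length(ab)) dimnames(cm) <- list(truth = ab, pred = ab)
  cm
}

#' Precision, recall and F1 (micro and macro averaged)
#'
#' Micro averaging pools true/false positives over classes; in single-label
#' multiclass classification micro precision, recall and F1 all collapse to
#' the accuracy (every false positive is another class's false negative).
#' Macro averaging takes unweighted means of per-class scores; classes
#' absent from `labels` and never predicted are skipped.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return List with `micro` and `macro` sublists of `precision`, `recall`,
#'   `f1`.
#' @export
prf_scores <- function(cm) {
  tp <- diag(cm)
  pred_n <- colSums(cm)
  true_n <- rowSums(cm)
  micro <- sum(tp) / sum(cm)
  per_p <- ifelse(pred_n > 0, tp / pred_n, NA_real_)
  per_r <- ifelse(true_n > 0, tp / true_n, NA_real_)
  per_f <- ifelse(is.na(per_p) | is.na(per_r) | (per_p + per_r) == 0, NA_real_,
                  2 * per_p * per_r / (per_p + per_r))
  list(
    micro = list(precision = micro, recall = micro, f1 = micro),
    macro = list(precision = mean(per_p, na.rm = TRUE),
                 recall = mean(per_r, na.rm = TRUE),
                 f1 = mean(per_f, na.rm = TRUE)),
    per_class = data.frame(precision = per_p, recall = per_r, f1 = per_f)
  )
}

#' Multiclass log-loss
#'
#' Mean of `-log p(true class)` with an `eps` probability floor —
#' independent of (and numerically identical to) the training criterion in
#' [cross_entropy_loss()]. A uniform predictor over 9 classes scores
#' `log(9) ~= 2.19722`.
#'
#' @param probs Probability matrix, one row per case.
#' @param labels Zero-based true labels.
#' @param eps Probability floor.
#' @return Non-negative scalar.
#' @export
log_loss <- function(probs, labels, eps = 1e-15) {
  probs <- as.matrix(probs)
  labels <- as.integer(labels)
  if (nrow(probs) == 0L) stop("empty evaluation set", call. = FALSE)
  stopifnot(length(labels) == nrow(probs),
            all(labels >= 0L & labels < ncol(probs)))
  s <- 0
  for (i in seq_len(nrow(probs))) {
    s <- s - log(max(probs[i, labels[i] + 1L], eps))
  }
  s / nrow(probs)
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class, the class-c probability column is scored against the
#' binary indicator `label == c`: thresholds sweep the unique scores,
#' giving (false positive rate, true positive rate) pairs; the AUC is the
#' trapezoidal area. The macro AUC is the unweighted mean over classes
#' present in `labels`; a class absent from the test set has no defined
#' curve and is excluded with a warning.
#'
#' @param probs Probability matrix (rows sum to 1), one column per class.
#' @param labels Zero-based true labels.
#' @return List with `per_class` (list of `list(points, auc)` where
#'   `points` is a data.frame of `fpr`, `tpr`) and `macro_auc`.
#' @export
roc_curves <- function(probs, labels) {
  probs <- as.matrix(probs)
  labels <- as.integer(labels)
  n_classes <- ncol(probs)
  out <- vector("list", n_classes)
  for (cls in seq_len(n_classes) - 1L) {
    truth <- labels == cls
    if (!any(truth) ) {
      warning("class ", cls, " absent from labels; AUC undefined")
      out[[cls + 1L]] <- list(points = NULL, auc = NA_real_)
      next
    }
    score <- probs[, cls + 1L]
    thr <- sort(unique(score), decreasing = TRUE)
    npos <- sum(truth); nneg <- sum(!truth)
    tpr <- vapply(thr, function(t) sum(score >= t & truth) / npos,
                  numeric(1))
    fpr <- if (nneg > 0) {
      vapply(thr, function(t) sum(score >= t & !truth) / nneg, numeric(1))
    } else rep(NA_real_, length(thr))
    pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
    auc <- if (nneg > 0) {
      sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                           utils::tail(pts$tpr, -1)) / 2)
    } else NA_real_
    out[[cls + 1L]] <- list(points = pts, auc = auc)
  }
  aucs <- vapply(out, `[[`, numeric(1), "auc")
  list(per_class = out,
       macro_auc = mean(aucs, na.rm = TRUE),
       auc = aucs)
}

#' Evaluate a trained model on a labelled dataset
#'
#' One prediction pass (argmax of evaluation-mode probabilities, ties to
#' the lowest class index) feeds every metric: accuracy, micro/macro
#' precision-recall-F1, log-loss, the 9x9 confusion matrix, per-class
#' one-vs-rest ROC/AUC and the macro-average AUC.
#'
#' @param model A trained `cfgcnn_model`.
#' @param dataset A labelled `symptom_dataset`.
#' @return An `eval_report` list with elements `accuracy`, `precision`,
#'   `recall`, `f1` (micro; `macro` holds the macro triple), `log_loss`,
#'   `confusion`, `roc`, `macro_auc`, `n` and the model's training
#'   `history`.
#' @export
evaluate <- function(model, dataset) {
  stopifnot(inherits(model, "cfgcnn_model"),
            inherits(dataset, "symptom_dataset"))
  if (dataset$n == 0L || is.null(dataset$labels)) {
    stop("evaluation requires a non-empty labelled dataset", call. = FALSE)
  }
  probs <- predict(model, dataset, type = "prob")
  preds <- max.col(probs, ties.method = "first") - 1L
  cm <- confusion_matrix(preds, dataset$labels, model$config$n_classes)
  prf <- prf_scores(cm)
  roc <- roc_curves(probs, dataset$labels)
  structure(list(
    accuracy = sum(diag(cm)) / sum(cm),
    precision = prf$micro$precision,
    recall = prf$micro$recall,
    f1 = prf$micro$f1,
    macro = prf$macro,
    per_class = prf$per_class,
    log_loss = log_loss(probs, dataset$labels),
    confusion = cm,
    roc = roc$per_class,
    auc = roc$auc,
    macro_auc = roc$macro_auc,
    n = dataset$n,
    history = model$history
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n =", x$n, "\n")
  cat(sprintf("  accuracy  %.4f   micro-F1 %.4f   macro-F1 %.4f\n",
              x$accuracy, x$f1, x$macro$f1))
  cat(sprintf("  log-loss  %.4f   macro AUC %.4f\n", x$log_loss,
              x$macro_auc))
  invisible(x)
}
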