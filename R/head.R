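#' Combine the two branch features
#'
#' Concatenates the linear cross-feature vector `C` and the nonlinear
#' feature vector `F` into the classification input `I_1 = (C, F)`; order
#' is preserved (`C` first).
#'
#' @param C Cross-network output vector (may be empty under ablation).
#' @param F Feature-generation output vector (may be empty under ablation).
#' @return Numeric vector of length `|C| + |F|`.
#' @export
combine_features <- function(C, F) {
  stopifnot(all(is.finite(C)), all(is.finite(F)))
  c(C, F)
}

#' Numerically stable softmax
#'
#' @param z Numeric vector of logits.
#' @return Probability vector: non-negative, sums to 1; invariant to adding
#'   a constant to all logits.
#' @export
softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Classification head forward pass
#'
#' Relu hidden layers (defaults 1024, 512, 128) followed by a final affine
#' map to the 9 syndrome logits and a softmax. Dropout (inverted, rate
#' `dropout`) is applied to hidden activations only when `training = TRUE`;
#' evaluation is deterministic.
#'
#' @param I1 Combined feature vector.
#' @param params List with lists `W` and `b`: one affine layer per entry,
#'   the last mapping to the 9 classes.
#' @param training Apply dropout masks (default FALSE).
#' @param dropout Dropout rate in `[0, 1)`.
#' @return Probability vector over the syndrome classes (sums to 1 within
#'   1e-9).
#' @export
head_forward <- function(I1, params, training = FALSE, dropout = 0.2) {
  stopifnot(dropout >= 0, dropout < 1)
  a <- I1
  n_layers <- length(params$W)
  for (j in seq_len(n_layers)) {
    if (length(a) != nrow(params$W[[j]])) {
      stop(sprintf("head layer %d expects input of length %d, got %d",
                   j, nrow(params$W[[j]]), length(a)), call. = FALSE)
    }
    a <- as.vector(a %*% params$W[[j]]) + params$b[[j]]
    if (j < n_layers) {
      a <- pmax(a, 0)
      if (training && dropout > 0) {
        keep <- stats::runif(length(a)) >= dropout
        a <- a * keep / (1 - dropout)
      }
    }
    if (any(!is.finite(a))) {
      stop("non-finite activations in head layer ", j, call. = FALSE)
    }
  }
  softmax(a)
}

#' Multiclass cross-entropy loss
#'
#' Mean over the batch of `-log p(true class)`, with probabilities floored
#' at `eps` before the log. Identical (within round-off) to the evaluation
#' log-loss metric; a uniform predictor over 9 classes scores `log(9)`.
#'
#' @param probs Numeric matrix, one probability row per case (a single
#'   vector is treated as a one-row batch).
#' @param labels Zero-based integer class labels.
#' @param eps Probability floor (default 1e-15).
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(probs, labels, eps = 1e-15) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  labels <- as.integer(labels)
  if (nrow(probs) == 0L) stop("empty batch", call. = FALSE)
  if (length(labels) != nrow(probs)) {
    stop("labels length does not match batch size", call. = FALSE)
  }
  if (any(labels < 0L | labels >= ncol(probs))) {
    stop("label out of range", call. = FALSE)
  }
  p <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  mean(-log(pmax(p, eps)))
}
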