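#' One cross layer
#'
#' The explicit feature-crossing map
#' `x_{l+1} = x_0 * (x_l' w_l) + b_l + x_l`,
#' where `x_l' w_l` is a scalar, so input and output dimensions are equal
#' and zeroed parameters give the identity (a residual connection that
#' protects against vanishing gradients). Each layer raises the attainable
#' polynomial degree in the coordinates of `x_0` by one.
#'
#' @param x0 Initial input vector (dimension `d`).
#' @param xl Output of the previous layer (dimension `d`).
#' @param w Layer weight vector (dimension `d`).
#' @param b Layer bias vector (dimension `d`).
#' @return Numeric vector of dimension `d`.
#' @examples
#' cross_layer(c(1, 0), c(2, 3), c(1, 1), c(0, 0))  # (7, 3)
#' @export
cross_layer <- function(x0, xl, w, b) {
  d <- length(x0)
  if (length(xl) != d || length(w) != d || length(b) != d) {
    stop(sprintf(
      "cross_layer dimension mismatch: |x0|=%d, |xl|=%d, |w|=%d, |b|=%d",
      d, length(xl), length(w), length(b)), call. = FALSE)
  }
  x0 * sum(xl * w) + b + xl
}

#' Stacked cross network
#'
#' Applies `L` cross layers starting from `x_1 = cross_layer(x0, x0, ...)`
#' (the first layer crosses the input with itself; the input feeds every
#' layer). With all parameters zero the chain is the identity; `L = 0`
#' returns `x0` unchanged (documented degenerate contract). The result is
#' the linear-branch cross-feature vector `C`.
#'
#' @param x0 Input vector of dimension `d` (flattened embedding).
#' @param W Weight matrix `d x L`, one column per layer.
#' @param B Bias matrix `d x L`, one column per layer.
#' @return Numeric vector of dimension `d`.
#' @export
cross_forward <- function(x0, W, B) {
  if (is.null(W) || length(W) == 0L) return(x0)
  W <- as.matrix(W); B <- as.matrix(B)
  d <- length(x0)
  if (nrow(W) != d || nrow(B) != d || ncol(W) != ncol(B)) {
    stop(sprintf(
      "cross_forward dimension mismatch: d=%d, W %dx%d, B %dx%d",
      d, nrow(W), ncol(W), nrow(B), ncol(B)), call. = FALSE)
  }
  xl <- x0
  for (l in seq_len(ncol(W))) {
    xl <- cross_layer(x0, xl, W[, l], B[, l])
  }
  xl
}

#' Initialize cross-network parameters
#'
#' Weights are small zero-mean normal draws (scale `1/sqrt(d)`), biases
#' zero, so early outputs stay near the residual identity.
#'
#' @param d Input dimension (`n_f * k`).
#' @param n_layers Number of cross layers (default 6).
#' @param seed Integer seed.
#' @return List with matrices `W` and `b`, both `d x n_layers`.
#' @export
init_cross <- function(d, n_layers = 6L, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    list(W = matrix(stats::rnorm(d * n_layers, sd = 1 / sqrt(d)), d, n_layers),
         b = matrix(0, d, n_layers))
  })
}
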