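#' One convolution round of the feature-generation branch
#'
#' 2-D convolution whose `h x 1` kernel slides along the field axis only
#' (same-padded there, so output height equals input height), sums over
#' input channels, and applies tanh. Padding start row is
#' `floor((h - 1) / 2)`.
#'
#' @param input Numeric array `H x k x c` (fields x embedding dim x
#'   channels). A plain `H x k` matrix is treated as `c = 1`.
#' @param kernel Numeric array `h x c x m` (kernel height x input channels
#'   x output channels).
#' @param bias Numeric vector of length `m` (one per output channel).
#' @return Numeric array `H x k x m` with entries in `(-1, 1)`.
#' @export
conv_round <- function(input, kernel, bias = NULL) {
  if (length(dim(input)) == 2L) dim(input) <- c(dim(input), 1L)
  if (length(dim(kernel)) == 2L) dim(kernel) <- c(dim(kernel), 1L)
  H <- dim(input)[1]; k <- dim(input)[2]; cc <- dim(input)[3]
  h <- dim(kernel)[1]; m <- dim(kernel)[3]
  if (dim(kernel)[2] != cc) {
    stop(sprintf("kernel expects %d input channels, input has %d",
                 dim(kernel)[2], cc), call. = FALSE)
  }
  if (is.null(bias)) bias <- numeric(m)
  stopifnot(length(bias) == m, H >= 1L)
  pad <- (h - 1L) %/% 2L
  out <- array(0, c(H, k, m))
  for (mm in seq_len(m)) {
    acc <- matrix(bias[mm], H, k)
    for (t in seq_len(h)) {
      delta <- t - 1L - pad  # input row = output row + delta
      src_lo <- max(1L, 1L + delta)
      src_hi <- min(H, H + delta)
      if (src_lo > src_hi) next
      dst <- seq.int(src_lo, src_hi) - delta
      for (ci in seq_len(cc)) {
        acc[dst, ] <- acc[dst, ] +
          kernel[t, ci, mm] * input[seq.int(src_lo, src_hi), , ci]
      }
    }
    out[, , mm] <- tanh(acc)
  }
  out
}

#' Non-overlapping max pooling along the field axis
#'
#' Maximum over `p` consecutive rows per (column, channel); output height
#' `floor(H / p)`, trailing remainder rows dropped.
#'
#' @param x Numeric array `H x k x c` (matrix treated as `c = 1`).
#' @param p Pool height, `1 <= p <= H`.
#' @return Numeric array `floor(H/p) x k x c`.
#' @export
max_pool <- function(x, p) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  H <- dim(x)[1]; k <- dim(x)[2]; cc <- dim(x)[3]
  p <- as.integer(p)
  if (p < 1L || H < p) {
    stop(sprintf("pool height p=%d invalid for input height H=%d", p, H),
         call. = FALSE)
  }
  Hp <- H %/% p
  out <- array(-Inf, c(Hp, k, cc))
  for (t in seq_len(p)) {
    out <- pmax(out, x[seq.int(t, by = p, length.out = Hp), , , drop = FALSE])
  }
  out
}

#' Recombination layer
#'
#' The fully connected tanh mixing step `R_i = tanh(S_i W_i + B_i)`: the
#' pooled tensor is flattened (R array order: rows fastest, then columns,
#' then channels), mapped affinely to `r`·`k` outputs, tanh-activated and
#' reshaped to an r-by-k matrix — manufacturing `r` new feature rows in the shared
#' embedding width.
#'
#' @param S Pooled array `H' x k x m` (matrix treated as `m = 1`).
#' @param W Weight matrix `(H' * k * m) x (r * k)`.
#' @param b Bias vector of length `r`·`k`.
#' @param r Number of output feature rows.
#' @param k Embedding width of the output rows.
#' @return Numeric matrix with `r` rows and `k` columns.
#' @export
recombine <- function(S, W, b, r, k) {
  flat <- as.vector(S)
  if (nrow(W) != length(flat) || ncol(W) != r * k || length(b) != r * k) {
    stop(sprintf(
      "recombine shape mismatch: |S|=%d, W %dx%d, |b|=%d, r*k=%d",
      length(flat), nrow(W), ncol(W), length(b), r * k), call. = FALSE)
  }
  matrix(tanh(as.vector(flat %*% W) + b), r, k)
}

#' Shape inference for the feature-generation branch
#'
#' Dry-run shape algebra, no weights involved: round `i` sees input height
#' `H_i` (`H_1 = n_f`, `H_{i+1} = floor(H_i / p)`), emits a convolution
#' tensor `H_i x k x m_i`, a pooled tensor `H_{i+1} x k x m_i` and a
#' recombined matrix of `r_i = maps_per_row * H_{i+1}` rows by `k` columns.
#'
#' @param n_f Number of fields.
#' @param k Embedding width.
#' @param channels Integer vector of output channels per round.
#' @param pool Pool height `p`.
#' @param maps_per_row New feature rows generated per pooled row.
#' @return data.frame with one row per round: `round`, `H_in`, `H_out`,
#'   `channels`, `r`; attribute `mlp_input` holds the flattened
#'   concatenation length `sum(r) * k`.
#' @export
fgcnn_shapes <- function(n_f = 60L, k = 8L, channels = c(14L, 16L, 18L),
                         pool = 2L, maps_per_row = 3L) {
  H <- as.integer(n_f)
  rows <- lapply(seq_along(channels), function(i) {
    if (H < pool) {
      stop(sprintf("round %d: input height %d smaller than pool %d",
                   i, H, pool), call. = FALSE)
    }
    Ho <- H %/% as.integer(pool)
    row <- data.frame(round = i, H_in = H, H_out = Ho,
                      channels = as.integer(channels[i]),
                      r = as.integer(maps_per_row) * Ho)
    H <<- Ho
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "mlp_input") <- sum(out$r) * as.integer(k)
  out
}

#' Full forward pass of the feature-generation branch
#'
#' Round 1 consumes the embedded matrix `E` (as a single-channel tensor);
#' each later round consumes the previous pooled tensor. The recombined
#' matrices `R_1..R_n` are stacked along the row axis, flattened (rows
#' fastest) and passed through an internal relu MLP, yielding the nonlinear
#' feature vector `F` that carries both local (convolutional) and global
#' (MLP) cross features.
#'
#' @param E Numeric matrix `n_f x k`.
#' @param params List with per-round `conv` (`K`, `b`) and `recomb`
#'   (`W`, `b`, `r`) parameter sets and `mlp` (lists `W`, `b`), as built by
#'   [init_model()].
#' @param pool Pool height `p`.
#' @return Numeric feature vector `F` (length = last MLP layer size).
#' @export
fgcnn_forward <- function(E, params, pool = 2L) {
  k <- ncol(E)
  x <- E
  dim(x) <- c(nrow(E), k, 1L)
  Rs <- vector("list", length(params$conv))
  for (i in seq_along(params$conv)) {
    C <- conv_round(x, params$conv[[i]]$K, params$conv[[i]]$b)
    S <- max_pool(C, pool)
    Rs[[i]] <- recombine(S, params$recomb[[i]]$W, params$recomb[[i]]$b,
                         params$recomb[[i]]$r, k)
    x <- S
  }
  flat <- as.vector(do.call(rbind, Rs))
  a <- flat
  for (j in seq_along(params$mlp$W)) {
    a <- pmax(as.vector(a %*% params$mlp$W[[j]]) + params$mlp$b[[j]], 0)
  }
  a
}
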