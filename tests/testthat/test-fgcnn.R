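# quadruple-loop convolution oracle: same-padded along the field axis only
conv_oracle <- function(input, kernel, bias) {
  H <- dim(input)[1]; k <- dim(input)[2]; cc <- dim(input)[3]
  h <- dim(kernel)[1]; m <- dim(kernel)[3]
  pad <- (h - 1) %/% 2
  out <- array(0, c(H, k, m))
  for (mm in 1:m) for (o in 1:H) for (j in 1:k) {
    acc <- bias[mm]
    for (t in 1:h) for (ci in 1:cc) {
      src <- o + t - 1 - pad
      if (src >= 1 && src <= H) acc <- acc + kernel[t, ci, mm] * input[src, j, ci]
    }
    out[o, j, mm] <- tanh(acc)
  }
  out
}

pool_oracle <- function(x, p) {
  H <- dim(x)[1]; Hp <- H %/% p
  out <- array(NA_real_, c(Hp, dim(x)[2], dim(x)[3]))
  for (oo in 1:Hp) for (j in 1:dim(x)[2]) for (cc in 1:dim(x)[3]) {
    out[oo, j, cc] <- max(x[((oo - 1) * p + 1):(oo * p), j, cc])
  }
  out
}

test_that("convolution agrees with the quadruple-loop oracle", {
  set.seed(51)
  for (rep in 1:60) {
    H <- sample(4:8, 1); k <- sample(2:4, 1); cc <- sample(1:3, 1)
    h <- sample(1:4, 1); m <- sample(1:3, 1)
    input <- array(stats::rnorm(H * k * cc), c(H, k, cc))
    kern <- array(stats::rnorm(h * cc * m), c(h, cc, m))
    bias <- stats::rnorm(m)
    expect_lt(max(abs(conv_round(input, kern, bias) -
                      conv_oracle(input, kern, bias))), 1e-10)
  }
  # a fixed reference shape: 6 x 3 x 2 input
  input <- array(stats::rnorm(36), c(6, 3, 2))
  kern <- array(stats::rnorm(4 * 2 * 2), c(4, 2, 2))
  bias <- stats::rnorm(2)
  expect_lt(max(abs(conv_round(input, kern, bias) -
                    conv_oracle(input, kern, bias))), 1e-10)
})

test_that("convolution limits: zero parameters and identity kernel", {
  input <- array(stats::rnorm(24), c(4, 3, 2))
  zk <- array(0, c(3, 2, 2))
  expect_true(all(conv_round(input, zk, c(0, 0)) == 0))
  one <- array(1, c(1, 1, 1))
  x <- matrix(stats::rnorm(12), 4, 3)
  expect_equal(as.vector(conv_round(x, one, 0)), as.vector(tanh(x)),
               tolerance = 1e-12)
  # output height equals input height (same padding)
  expect_identical(dim(conv_round(input, array(1, c(4, 2, 5)), rep(0, 5))),
                   c(4L, 3L, 5L))
})

test_that("max pooling drops remainder rows and matches its oracle", {
  x <- array(stats::rnorm(14), c(7, 2, 1))
  got <- max_pool(x, 2L)
  expect_identical(dim(got), c(3L, 2L, 1L))
  expect_equal(got, pool_oracle(x, 2L))
  # the 7th row cannot influence the result
  x2 <- x
  x2[7, , ] <- 1e6
  expect_equal(max_pool(x2, 2L), got)
  set.seed(52)
  for (rep in 1:40) {
    H <- sample(2:9, 1); p <- sample(1:H, 1)
    xx <- array(stats::rnorm(H * 6), c(H, 3, 2))
    expect_equal(max_pool(xx, p), pool_oracle(xx, p))
  }
  expect_equal(max_pool(x, 1L), x)                 # p = 1 identity
  cst <- array(2.5, c(6, 2, 2))
  expect_true(all(max_pool(cst, 3L) == 2.5))       # constant input
  expect_error(max_pool(array(0, c(2, 1, 1)), 3L), "p=3")
})

test_that("recombination matches the explicit matrix-product oracle", {
  set.seed(53)
  for (rep in 1:40) {
    Hp <- sample(1:4, 1); k <- sample(1:3, 1); m <- sample(1:3, 1)
    r <- sample(1:4, 1)
    S <- array(stats::rnorm(Hp * k * m), c(Hp, k, m))
    W <- matrix(stats::rnorm(Hp * k * m * r * k), Hp * k * m, r * k)
    b <- stats::rnorm(r * k)
    oracle <- matrix(tanh(as.vector(t(W) %*% as.vector(S)) + b), r, k)
    expect_lt(max(abs(recombine(S, W, b, r, k) - oracle)), 1e-10)
  }
  # W = 0 passes the bias through tanh
  S <- array(stats::rnorm(6), c(3, 2, 1))
  b <- stats::rnorm(4)
  expect_equal(recombine(S, matrix(0, 6, 4), b, 2L, 2L),
               matrix(tanh(b), 2, 2))
  # scalar case: r = k = 1, S = s, W = 2 -> tanh(2 s)
  expect_equal(recombine(array(0.3, c(1, 1, 1)), matrix(2, 1, 1), 0, 1L, 1L),
               matrix(tanh(0.6), 1, 1))
})

test_that("shape algebra follows the floor recurrence", {
  sh <- fgcnn_shapes(60L, 8L, c(14L, 16L, 18L), pool = 2L, maps_per_row = 3L)
  expect_identical(sh$H_in, c(60L, 30L, 15L))
  expect_identical(sh$H_out, c(30L, 15L, 7L))
  expect_identical(sh$r, c(90L, 45L, 21L))
  expect_identical(attr(sh, "mlp_input"), 1248L)
  set.seed(54)
  for (rep in 1:25) {
    nf <- sample(8:64, 1); p <- sample(2:3, 1)
    nr <- sample(1:3, 1)
    ch <- sample(2:6, nr, replace = TRUE)
    ok <- tryCatch(fgcnn_shapes(nf, 4L, ch, p, 2L), error = function(e) NULL)
    H <- nf
    feasible <- TRUE
    for (i in seq_len(nr)) {
      if (H < p) { feasible <- FALSE; break }
      H <- H %/% p
    }
    if (!feasible) {
      expect_null(ok)
    } else {
      H <- nf
      for (i in seq_len(nr)) {
        expect_identical(ok$H_in[i], H)
        H <- H %/% p
        expect_identical(ok$H_out[i], H)
        expect_identical(ok$r[i], 2L * H)
      }
    }
  }
})

test_that("full pooling collapses a round to one row", {
  sh <- fgcnn_shapes(6L, 3L, 4L, pool = 6L, maps_per_row = 3L)
  expect_identical(sh$H_out, 1L)
  x <- array(stats::rnorm(6 * 3 * 4), c(6, 3, 4))
  expect_identical(dim(max_pool(x, 6L)), c(1L, 3L, 4L))
})

test_that("with all weights zero the branch output ignores the input", {
  sch <- tiny_schema()
  cfg <- tiny_config()
  m <- init_model(sch, cfg, seed = 55L)
  p <- m$params$fgcnn
  for (i in seq_along(p$conv)) {
    p$conv[[i]]$K[] <- 0
    p$conv[[i]]$b[] <- stats::rnorm(length(p$conv[[i]]$b))
    p$recomb[[i]]$W[] <- 0
    p$recomb[[i]]$b[] <- stats::rnorm(length(p$recomb[[i]]$b))
  }
  emb <- m$params$emb
  E1 <- embed_record(rep(-1L, sch$n_f), emb, sch)
  E2 <- embed_record(c(0L, 1L, 0L, 2L, 1L, 1L), emb, sch)
  expect_equal(fgcnn_forward(E1, p, cfg$pool), fgcnn_forward(E2, p, cfg$pool))
})
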