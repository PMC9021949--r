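#' Model architecture configuration
#'
#' Defaults follow the reference architecture: embedding width 8, a 6-layer
#' cross network, three convolution rounds with 14/16/18 output channels
#' and kernel height 4, pool height 2, three recombination feature maps per
#' pooled row, a 3-layer internal MLP (256, 128, 64) in the
#' feature-generation branch, and a classification head with hidden sizes
#' 1024, 512, 128 over 9 classes with dropout 0.2.
#'
#' @param k Embedding width.
#' @param cross_layers Number of cross layers `L`.
#' @param conv_channels Output channels per convolution round.
#' @param kernel_height Field-axis kernel extent `h`.
#' @param pool Pool height `p`.
#' @param maps_per_row Recombination feature rows per pooled row.
#' @param fgcnn_mlp Hidden sizes of the feature-generation MLP.
#' @param head_hidden Hidden sizes of the classification head.
#' @param n_classes Number of output classes.
#' @param dropout Head dropout rate in `[0, 1)`.
#' @param ablation One of `"full"`, `"cross_only"`, `"fgcnn_only"`.
#' @return A `cfgcnn_config` list.
#' @export
cfgcnn_config <- function(k = 8L, cross_layers = 6L,
                          conv_channels = c(14L, 16L, 18L),
                          kernel_height = 4L, pool = 2L, maps_per_row = 3L,
                          fgcnn_mlp = c(256L, 128L, 64L),
                          head_hidden = c(1024L, 512L, 128L),
                          n_classes = n_syndrome_classes(), dropout = 0.2,
                          ablation = c("full", "cross_only", "fgcnn_only")) {
  ablation <- match.arg(ablation)
  stopifnot(k >= 1L, cross_layers >= 0L, kernel_height >= 1L, pool >= 1L,
            maps_per_row >= 1L, dropout >= 0, dropout < 1,
            length(conv_channels) >= 1L, all(conv_channels >= 1L))
  structure(list(
    k = as.integer(k), cross_layers = as.integer(cross_layers),
    conv_channels = as.integer(conv_channels),
    kernel_height = as.integer(kernel_height), pool = as.integer(pool),
    maps_per_row = as.integer(maps_per_row),
    fgcnn_mlp = as.integer(fgcnn_mlp),
    head_hidden = as.integer(head_hidden),
    n_classes = as.integer(n_classes), dropout = dropout,
    ablation = ablation
  ), class = "cfgcnn_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}
he_normal <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
}

#' Initialize all learnable parameters of the model
#'
#' Embedding tables: zero-mean normal (sd 0.1), one dedicated row per field
#' for missing values. Cross layers: weights at scale `1/sqrt(d)`, biases
#' zero (near-identity start). Convolution and recombination (tanh):
#' Glorot-uniform. Relu MLP and head hidden layers: He-normal; output
#' layer: Glorot-uniform. All draws come from a single seeded stream, so
#' initialization is a pure function of (schema, config, seed).
#'
#' @param schema A `symptom_schema`.
#' @param config A [cfgcnn_config()].
#' @param seed Integer seed.
#' @return An untrained model object of class `cfgcnn_model` with elements
#'   `schema`, `config`, `params`, `shapes` and `history` (NULL).
#' @export
init_model <- function(schema, config = cfgcnn_config(), seed = 1L) {
  stopifnot(inherits(schema, "symptom_schema"),
            inherits(config, "cfgcnn_config"))
  n_f <- schema$n_f
  k <- config$k
  d <- n_f * k
  shapes <- fgcnn_shapes(n_f, k, config$conv_channels, config$pool,
                         config$maps_per_row)
  f_dim <- config$fgcnn_mlp[length(config$fgcnn_mlp)]
  head_in <- switch(config$ablation,
                    full = d + f_dim, cross_only = d, fgcnn_only = f_dim)
  params <- withr::with_seed(as.integer(seed), {
    card <- schema$fields$cardinality
    rows <- sum(card + 1L)
    emb <- list(table = matrix(stats::rnorm(rows * k, sd = 0.1), rows, k),
                offsets = c(0L, cumsum(card + 1L))[seq_len(n_f)],
                k = k)
    cross <- list(
      W = matrix(stats::rnorm(d * config$cross_layers, sd = 1 / sqrt(d)),
                 d, config$cross_layers),
      b = matrix(0, d, config$cross_layers)
    )
    h <- config$kernel_height
    conv <- vector("list", nrow(shapes))
    recomb <- vector("list", nrow(shapes))
    c_in <- 1L
    for (i in seq_len(nrow(shapes))) {
      m <- shapes$channels[i]
      lim <- sqrt(6 / (h * c_in + h * m))
      conv[[i]] <- list(
        K = array(stats::runif(h * c_in * m, -lim, lim), c(h, c_in, m)),
        b = numeric(m)
      )
      in_dim <- shapes$H_out[i] * k * m
      out_dim <- shapes$r[i] * k
      recomb[[i]] <- list(W = glorot(in_dim, out_dim), b = numeric(out_dim),
                          r = shapes$r[i])
      c_in <- m
    }
    mlp_in <- attr(shapes, "mlp_input")
    sizes <- c(mlp_in, config$fgcnn_mlp)
    mlp <- list(W = vector("list", length(config$fgcnn_mlp)),
                b = vector("list", length(config$fgcnn_mlp)))
    for (j in seq_along(config$fgcnn_mlp)) {
      mlp$W[[j]] <- he_normal(sizes[j], sizes[j + 1])
      mlp$b[[j]] <- numeric(sizes[j + 1])
    }
    hs <- c(head_in, config$head_hidden, config$n_classes)
    nh <- length(hs) - 1L
    head <- list(W = vector("list", nh), b = vector("list", nh))
    for (j in seq_len(nh)) {
      head$W[[j]] <- if (j < nh) he_normal(hs[j], hs[j + 1])
                     else glorot(hs[j], hs[j + 1])
      head$b[[j]] <- numeric(hs[j + 1])
    }
    list(emb = emb, cross = cross,
         fgcnn = list(conv = conv, recomb = recomb, mlp = mlp),
         head = head)
  })
  structure(list(schema = schema, config = config, params = params,
                 shapes = shapes, history = NULL, trained = FALSE),
            class = "cfgcnn_model")
}

#' @export
print.cfgcnn_model <- function(x, ...) {
  np <- sum(vapply(rapply(x$params, length, how = "unlist"), sum, 1))
  cat("<cfgcnn_model> ", x$schema$n_f, " fields, k=", x$config$k,
      ", ", x$config$cross_layers, " cross layers, ",
      length(x$config$conv_channels), " conv rounds (",
      paste(x$config$conv_channels, collapse = "/"), "), ablation=",
      x$config$ablation, if (x$trained) ", trained" else ", untrained",
      "\n", sep = "")
  invisible(x)
}

cpp_cfg <- function(model, extra = list()) {
  cfg <- model$config
  base <- list(
    n_f = model$schema$n_f, k = cfg$k, pool = cfg$pool,
    h = cfg$kernel_height, channels = cfg$conv_channels,
    r = model$shapes$r, n_classes = cfg$n_classes,
    dropout = cfg$dropout,
    ablation = match(cfg$ablation,
                     c("full", "cross_only", "fgcnn_only")) - 1L
  )
  utils::modifyList(base, extra)
}

#' Predicted class probabilities or labels
#'
#' Runs the deterministic evaluation-mode forward pass (dropout off) in
#' double precision. Argmax ties break to the lowest class index.
#'
#' @param object A `cfgcnn_model`.
#' @param newdata A `symptom_dataset` or integer code matrix.
#' @param type `"prob"` for the probability matrix, `"class"` for
#'   zero-based predicted labels.
#' @param ... Unused.
#' @return Numeric `n x 9` matrix or integer vector.
#' @export
predict.cfgcnn_model <- function(object, newdata,
                                 type = c("prob", "class"), ...) {
  type <- match.arg(type)
  codes <- if (inherits(newdata, "symptom_dataset")) newdata$codes
           else as.matrix(newdata)
  storage.mode(codes) <- "integer"
  probs <- cfgcnn_forward_cpp(object$params, codes, cpp_cfg(object))
  colnames(probs) <- syndrome_types()$abbrev[seq_len(object$config$n_classes)]
  if (type == "prob") probs else max.col(probs, ties.method = "first") - 1L
}

# Reference forward pass composed from the exposed per-module operations
# (single record, pure R). Used to cross-validate the C++ engine.
forward_reference <- function(model, codes) {
  p <- model$params
  cfg <- model$config
  E <- embed_record(codes, p$emb, model$schema)
  C <- NULL
  F <- NULL
  if (cfg$ablation != "fgcnn_only") {
    C <- cross_forward(flatten_embedding(E), p$cross$W, p$cross$b)
  }
  if (cfg$ablation != "cross_only") {
    F <- fgcnn_forward(E, p$fgcnn, cfg$pool)
  }
  I1 <- combine_features(if (is.null(C)) numeric(0) else C,
                         if (is.null(F)) numeric(0) else F)
  head_forward(I1, p$head, training = FALSE, dropout = cfg$dropout)
}

#' Model gradients via backpropagation
#'
#' Analytic gradients of the mean cross-entropy loss on a batch, computed
#' in double precision with dropout off. Exposed so that the full model can
#' be validated against central finite differences.
#'
#' @param model A `cfgcnn_model`.
#' @param codes Integer code matrix (batch).
#' @param labels Zero-based labels.
#' @return List with `loss` (scalar) and `grads` (same structure as
#'   `model$params`).
#' @export
model_gradients <- function(model, codes, labels) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  cfgcnn_grad_cpp(model$params, codes, as.integer(labels), cpp_cfg(model))
}

#' Loss of the model on a batch (evaluation-mode forward)
#'
#' @param model A `cfgcnn_model`.
#' @param codes Integer code matrix.
#' @param labels Zero-based labels.
#' @return Mean cross-entropy (double).
#' @export
model_loss <- function(model, codes, labels) {
  probs <- predict(model, codes, type = "prob")
  cross_entropy_loss(probs, labels)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a version-tagged RDS file holding the configuration,
#' schema and all parameter tensors.
#'
#' @param model A `cfgcnn_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cfgcnn_model"))
  saveRDS(list(format = "cfgcnn_checkpoint", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "cfgcnn_checkpoint")) {
    stop("not a cfgcnn checkpoint: ", path, call. = FALSE)
  }
  obj$model
}
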