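#' Training configuration
#'
#' Defaults follow the reference protocol: learning rate 0.001, 1000
#' iterations (one iteration = one full pass over the training set),
#' mini-batches of 256, adaptive-moment (Adam) updates. `precision`
#' selects the arithmetic of the training core: `"single"` (default, fast
#' on one CPU) or `"double"`.
#'
#' @param learning_rate Adam step size (> 0; 0 is allowed and leaves
#'   parameters untouched, useful as a no-op control).
#' @param epochs Number of full passes over the training data.
#' @param batch_size Mini-batch size (>= 1).
#' @param seed Integer seed driving initialization order, shuffling and
#'   dropout.
#' @param precision `"single"` or `"double"`.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 1000L,
                         batch_size = 256L, seed = 1L,
                         precision = c("single", "double")) {
  precision <- match.arg(precision)
  stopifnot(learning_rate >= 0, epochs >= 1L, batch_size >= 1L)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 precision = precision),
            class = "train_config")
}

#' Train the dual-branch classifier
#'
#' Minimizes the multiclass cross-entropy by mini-batch Adam with inverted
#' dropout on the head's hidden activations. Training is deterministic
#' given the seed: parameter initialization, epoch shuffling and dropout
#' masks all derive from it. The per-epoch history records the running
#' training-set accuracy and loss (aggregated over the epoch's forward
#' passes).
#'
#' @param dataset A labelled `symptom_dataset`.
#' @param schema The `symptom_schema` the records conform to.
#' @param config A [cfgcnn_config()] (architecture + ablation switch).
#' @param train A [train_config()].
#' @return A trained `cfgcnn_model` whose `history` element is a
#'   data.frame with columns `epoch`, `accuracy`, `loss`.
#' @export
train_cfgcnn <- function(dataset, schema, config = cfgcnn_config(),
                         train = train_config()) {
  stopifnot(inherits(dataset, "symptom_dataset"),
            inherits(train, "train_config"))
  if (dataset$n == 0L) stop("empty training set", call. = FALSE)
  if (is.null(dataset$labels)) stop("training requires labels", call. = FALSE)
  model <- init_model(schema, config, seed = train$seed)
  cfg <- cpp_cfg(model, list(
    epochs = train$epochs, batch_size = train$batch_size,
    lr = train$learning_rate, seed = train$seed,
    precision = train$precision
  ))
  fit <- cfgcnn_train_cpp(model$params, dataset$codes, dataset$labels, cfg)
  model$params <- fit$params
  model$history <- data.frame(epoch = seq_len(train$epochs),
                              accuracy = fit$history$accuracy,
                              loss = fit$history$loss)
  model$trained <- TRUE
  model$train_config <- train
  model
}
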