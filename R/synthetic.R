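#' The nine dysmenorrhea syndrome classes
#'
#' The fixed output label set, in catalogue order, with the case counts of
#' the 5,273-record dysmenorrhea corpus the class imbalance is modelled on.
#' Label `i` (zero-based) always refers to row `i + 1` of this table.
#'
#' @return A data.frame with columns `name`, `abbrev` and `count`.
#' @export
syndrome_types <- function() {
  data.frame(
    name = c(
      "Liver-kidney depletion",
      "Pattern of congealing cold with stasis",
      "Cold-dampness stagnation",
      "Liver constraint and dampness-heat",
      "Deficiency of qi and blood",
      "Qi stagnation and blood stasis",
      "Kidney deficiency and blood stasis",
      "Dampness-heat stasis obstruction",
      "Yang deficiency and internal cold"
    ),
    abbrev = c("LKD", "PCCBS", "CDS", "LCD", "DQB", "QBS", "KDBS", "SDH",
               "YDIC"),
    count = c(514L, 720L, 568L, 522L, 575L, 751L, 543L, 544L, 536L),
    stringsAsFactors = FALSE
  )
}

#' @rdname syndrome_types
#' @export
n_syndrome_classes <- function() 9L

#' Default class priors from the dysmenorrhea corpus
#'
#' Class prevalences proportional to the corpus counts (total 5,273),
#' normalized to sum to one. The distribution is imbalanced: the modal
#' class, qi stagnation and blood stasis, holds 751 cases (14.2%).
#'
#' @return Named numeric vector of length 9 summing to 1.
#' @export
default_class_priors <- function() {
  st <- syndrome_types()
  stats::setNames(st$count / sum(st$count), st$name)
}

#' Configuration for the synthetic record generator
#'
#' @param n_samples Number of records to draw.
#' @param class_priors Nine non-negative class probabilities summing to 1
#'   (default: [default_class_priors()]).
#' @param signal_strength Probability `q` in `[0, 1]` that an observed field
#'   carries its class's characteristic code rather than a uniform draw.
#' @param missing_rate Probability `rho` in `[0, 1]` that a field is
#'   censored to -1, independently per field.
#' @param seed Integer seed; generation is a pure function of
#'   (config, schema, profiles).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_samples, class_priors = default_class_priors(),
                             signal_strength = 0.9, missing_rate = 0.3,
                             seed = 1L) {
  n_samples <- as.integer(n_samples)
  stopifnot(n_samples >= 1L)
  class_priors <- as.numeric(class_priors)
  if (length(class_priors) != n_syndrome_classes() ||
      any(class_priors < 0)) {
    stop("class_priors must be 9 non-negative values", call. = FALSE)
  }
  if (abs(sum(class_priors) - 1) > 1e-9) {
    stop("class_priors must sum to 1 (within 1e-9)", call. = FALSE)
  }
  if (signal_strength < 0 || signal_strength > 1) {
    stop("signal_strength must lie in [0, 1]", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate > 1) {
    stop("missing_rate must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_samples = n_samples, class_priors = class_priors,
                 signal_strength = signal_strength,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "generator_config")
}

#' Draw class-conditional characteristic symptom profiles
#'
#' Each class receives one characteristic code per field, drawn uniformly
#' from that field's vocabulary. When cardinalities permit, classes are
#' guaranteed to differ in at least one field (colliding pairs are redrawn
#' in the widest field).
#'
#' @param schema A `symptom_schema`.
#' @param n_classes Number of classes (default 9).
#' @param seed Integer seed; profiles are deterministic given the seed.
#' @return Integer matrix `n_classes x n_f`; entry `(c, f)` in
#'   `[0, cardinality_f)`.
#' @export
make_profiles <- function(schema, n_classes = n_syndrome_classes(),
                          seed = 1L) {
  stopifnot(inherits(schema, "symptom_schema"))
  card <- schema$fields$cardinality
  withr::with_seed(as.integer(seed), {
    prof <- vapply(card, function(m) sample.int(m, n_classes, replace = TRUE),
                   integer(n_classes)) - 1L
    prof <- matrix(prof, nrow = n_classes)
    # separability guarantee: redraw the widest field for identical pairs
    if (max(card) > 1L) {
      fwide <- which.max(card)
      repeat {
        dup <- duplicated(apply(prof, 1, paste, collapse = ","))
        if (!any(dup)) break
        prof[dup, fwide] <- sample.int(card[fwide], sum(dup),
                                       replace = TRUE) - 1L
      }
    }
    prof
  })
}

#' Generate a synthetic labelled symptom dataset
#'
#' For each record a label is drawn from the class priors; then,
#' independently per field, the code is censored to -1 with probability
#' `missing_rate`, otherwise it equals the label's characteristic code with
#' probability `signal_strength` and a uniform vocabulary draw with
#' probability `1 - signal_strength`. This mixture gives tunable
#' separability (`q = 1, rho = 0` is perfectly separable; `q = 0` makes
#' features independent of labels, so the Bayes rule degenerates to the
#' majority class).
#'
#' @param config A [generator_config()].
#' @param schema A `symptom_schema`.
#' @param profiles Characteristic-code matrix from [make_profiles()].
#' @return A labelled `symptom_dataset`.
#' @export
generate_dataset <- function(config, schema, profiles) {
  stopifnot(inherits(config, "generator_config"),
            inherits(schema, "symptom_schema"))
  n <- config$n_samples
  n_f <- schema$n_f
  card <- schema$fields$cardinality
  if (ncol(profiles) != n_f) stop("profiles do not match schema",
                                  call. = FALSE)
  withr::with_seed(config$seed, {
    labels <- sample.int(n_syndrome_classes(), n, replace = TRUE,
                         prob = config$class_priors) - 1L
    codes <- matrix(-1L, n, n_f)
    miss <- matrix(stats::runif(n * n_f) < config$missing_rate, n, n_f)
    sig <- matrix(stats::runif(n * n_f) < config$signal_strength, n, n_f)
    for (f in seq_len(n_f)) {
      col <- ifelse(sig[, f], profiles[labels + 1L, f],
                    sample.int(card[f], n, replace = TRUE) - 1L)
      col[miss[, f]] <- -1L
      codes[, f] <- col
    }
    symptom_dataset(codes, labels = labels, schema = schema,
                    validate = FALSE)
  })
}

#' Random train/test partition
#'
#' Disjoint, exhaustive split of a dataset; the training set holds
#' `round(train_fraction * n)` records. The default 0.75 gives the 3:1
#' train:test ratio of the reference experiment.
#'
#' @param dataset A `symptom_dataset`.
#' @param train_fraction Fraction of records assigned to training,
#'   strictly between 0 and 1.
#' @param seed Integer seed determining the permutation.
#' @param stratify Draw the split per class instead of simple random
#'   (default FALSE, matching the simple 3:1 protocol).
#' @return List with elements `train` and `test`, both `symptom_dataset`s.
#' @export
split_train_test <- function(dataset, train_fraction = 0.75, seed = 1L,
                             stratify = FALSE) {
  stopifnot(inherits(dataset, "symptom_dataset"))
  if (dataset$n < 2L) stop("dataset must hold at least 2 records",
                           call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (stratify && is.null(dataset$labels)) {
    stop("stratified splitting requires labels", call. = FALSE)
  }
  idx_train <- withr::with_seed(as.integer(seed), {
    if (!stratify) {
      n_train <- as.integer(round(train_fraction * dataset$n))
      n_train <- max(1L, min(dataset$n - 1L, n_train))
      sample.int(dataset$n)[seq_len(n_train)]
    } else {
      # training share drawn class by class
      unlist(lapply(split(seq_len(dataset$n), dataset$labels),
                    function(ix) {
        ix <- ix[sample.int(length(ix))]
        ix[seq_len(round(train_fraction * length(ix)))]
      }), use.names = FALSE)
    }
  })
  idx_test <- setdiff(seq_len(dataset$n), idx_train)
  if (length(idx_test) == 0L) {
    idx_test <- idx_train[length(idx_train)]
    idx_train <- idx_train[-length(idx_train)]
  }
  take <- function(idx) {
    structure(list(codes = dataset$codes[idx, , drop = FALSE],
                   labels = if (is.null(dataset$labels)) NULL
                            else dataset$labels[idx],
                   n = length(idx)),
              class = "symptom_dataset")
  }
  list(train = take(idx_train), test = take(idx_test))
}
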