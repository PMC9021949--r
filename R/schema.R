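#' The 60-field four-examination symptom catalogue
#'
#' Field names and their diagnostic category, in fixed catalogue order.
#' The four TCM data-acquisition channels partition the fields
#' 30/6/22/2: inspection, listening and smelling, inquiry, palpation.
#'
#' @return A data.frame with columns `name` and `category`.
#' @keywords internal
tcm_field_catalogue <- function() {
  inspection <- c(
    "Expression", "Complexion", "Physique", "Posture", "Head", "Face",
    "Nose", "Eye", "Ear", "Mouth", "Tooth", "Neck", "Chest", "Abdomen",
    "Lumbar", "Exterior genitalia", "Anus", "Skin", "Phlegm", "Saliva",
    "Vomitus", "Excrement", "Urinating",
    "Index fingers' superficial venules", "Tongue nature", "Tongue shape",
    "Tongue color", "Tongue coating nature", "Tongue coating color",
    "Hypoglossal vessels"
  )
  listening <- c(
    "Voice", "Breathing sound", "Snoring", "Coughing sound", "Belching",
    "Tone"
  )
  inquiry <- c(
    "Cold and heat", "Sweating", "Pain site", "Nature of pain",
    "Head discomfort", "Physical discomfort", "Limb discomfort",
    "Ear discomfort", "Eye discomfort", "Sleep", "Diet", "Thirst",
    "Abnormal defecation", "Abnormal urine", "Menstrual period",
    "Menstrual color", "Menstrual volume", "Menstrual nature", "Emotion",
    "Family history", "Vaccination history", "Physiological abnormality"
  )
  palpation <- c("Pulse condition", "Pressing feeling")
  data.frame(
    name = c(inspection, listening, inquiry, palpation),
    category = rep(
      c("inspection", "listening_smelling", "inquiry", "palpation"),
      times = c(length(inspection), length(listening), length(inquiry),
                length(palpation))
    ),
    stringsAsFactors = FALSE
  )
}

#' Build the default 60-field symptom schema
#'
#' Constructs the fixed catalogue of 60 categorical symptom fields grouped
#' into the four diagnostic examinations (inspection 30, listening and
#' smelling 6, inquiry 22, palpation 2). Per-field vocabularies are
#' synthetic placeholders (`"term_1"`, `"term_2"`, ...): the published field
#' list carries no clinical term inventories, so vocabulary sizes are a
#' modelling choice, uniform by default and overridable per field.
#'
#' @param vocab_sizes Optional named integer vector or list mapping field
#'   names to vocabulary sizes; unnamed fields keep `default_cardinality`.
#' @param default_cardinality Vocabulary size for fields not listed in
#'   `vocab_sizes` (default 8).
#' @return An object of class `symptom_schema`: a list with `fields` (a
#'   data.frame of `name`, `category`, `cardinality`), `vocab` (named list
#'   of term vectors) and `n_f` (number of fields).
#' @examples
#' sch <- build_default_schema()
#' sch$n_f                       # 60
#' table(sch$fields$category)
#' build_default_schema(vocab_sizes = c(Tone = 3))$fields["Tone", ]
#' @export
build_default_schema <- function(vocab_sizes = NULL, default_cardinality = 8L) {
  cat60 <- tcm_field_catalogue()
  card <- rep(as.integer(default_cardinality), nrow(cat60))
  names(card) <- cat60$name
  if (!is.null(vocab_sizes)) {
    vs <- unlist(vocab_sizes)
    unknown <- setdiff(names(vs), cat60$name)
    if (length(unknown) > 0L) {
      stop("unknown schema field(s) in vocab_sizes: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    card[names(vs)] <- as.integer(vs)
  }
  new_schema(cat60$name, cat60$category, card)
}

#' Construct a symptom schema from explicit field definitions
#'
#' @param names Character vector of unique field names, in catalogue order.
#' @param categories Character vector of diagnostic categories, one of
#'   `"inspection"`, `"listening_smelling"`, `"inquiry"`, `"palpation"`.
#' @param cardinalities Integer vector of per-field vocabulary sizes (>= 1).
#' @param vocab Optional named list of per-field term vectors; defaults to
#'   synthetic `"term_i"` placeholders of the stated cardinality.
#' @return A `symptom_schema` object.
#' @export
new_schema <- function(names, categories, cardinalities, vocab = NULL) {
  stopifnot(length(names) == length(categories),
            length(names) == length(cardinalities))
  if (anyDuplicated(names)) {
    stop("field names must be unique within a schema", call. = FALSE)
  }
  ok <- categories %in% c("inspection", "listening_smelling", "inquiry",
                          "palpation")
  if (!all(ok)) {
    stop("unknown category: ", paste(unique(categories[!ok]), collapse = ", "),
         call. = FALSE)
  }
  cardinalities <- as.integer(cardinalities)
  if (any(cardinalities < 1L)) stop("cardinality must be >= 1", call. = FALSE)
  if (is.null(vocab)) {
    vocab <- lapply(cardinalities, function(m) paste0("term_", seq_len(m)))
    names(vocab) <- names
  } else {
    stopifnot(identical(sort(base::names(vocab)), sort(names)))
    vocab <- vocab[names]
    for (f in names) {
      if (anyDuplicated(vocab[[f]])) {
        stop("vocabulary entries must be unique within field '", f, "'",
             call. = FALSE)
      }
    }
    if (!all(lengths(vocab) == cardinalities)) {
      stop("vocabulary lengths disagree with cardinalities", call. = FALSE)
    }
  }
  fields <- data.frame(
    name = names, category = categories, cardinality = cardinalities,
    row.names = names, stringsAsFactors = FALSE
  )
  structure(list(fields = fields, vocab = vocab, n_f = nrow(fields)),
            class = "symptom_schema")
}

#' @export
print.symptom_schema <- function(x, ...) {
  cat("<symptom_schema> ", x$n_f, " fields\n", sep = "")
  print(table(factor(x$fields$category,
                     levels = c("inspection", "listening_smelling",
                                "inquiry", "palpation"))))
  invisible(x)
}

#' Encode a raw symptom map as an integer-coded record
#'
#' Maps observed term strings to zero-based vocabulary indices; fields not
#' present in `raw` are coded -1 ("symptom absent/unobserved"). -1 is legal
#' in every field: all symptoms can never co-occur, so every real record has
#' missing values.
#'
#' @param raw Named list or character vector mapping field names to observed
#'   term strings. May be empty.
#' @param schema A `symptom_schema`.
#' @return Named integer vector of length `schema$n_f` in schema field order.
#' @examples
#' sch <- build_default_schema()
#' r <- encode_record(list(`Tongue coating color` = "term_1"), sch)
#' r[["Tongue coating color"]]  # 0
#' @export
encode_record <- function(raw, schema) {
  stopifnot(inherits(schema, "symptom_schema"))
  codes <- rep(-1L, schema$n_f)
  names(codes) <- schema$fields$name
  if (length(raw) == 0L) return(codes)
  raw <- as.list(raw)
  unknown <- setdiff(names(raw), schema$fields$name)
  if (length(unknown) > 0L) {
    stop("unknown field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (f in names(raw)) {
    idx <- match(raw[[f]], schema$vocab[[f]])
    if (is.na(idx)) {
      stop("term '", raw[[f]], "' not in vocabulary of field '", f, "'",
           call. = FALSE)
    }
    codes[[f]] <- idx - 1L
  }
  codes
}

#' Decode an integer-coded record back to term strings
#'
#' Inverse of [encode_record()] on present fields; missing (-1) fields are
#' dropped.
#'
#' @param codes Integer vector of length `schema$n_f`.
#' @param schema A `symptom_schema`.
#' @return Named list of term strings for present fields.
#' @export
decode_record <- function(codes, schema) {
  stopifnot(inherits(schema, "symptom_schema"))
  viol <- validate_record(codes, schema)
  if (length(viol) > 0L) stop(paste(viol, collapse = "; "), call. = FALSE)
  present <- which(codes >= 0L)
  out <- lapply(present, function(i) schema$vocab[[i]][codes[i] + 1L])
  names(out) <- schema$fields$name[present]
  out
}

#' Validate an integer-coded record against a schema
#'
#' Violations are returned as data, not raised: each is a human-readable
#' description naming the field position, the offending value and the
#' allowed range.
#'
#' @param codes Integer vector (a candidate record).
#' @param schema A `symptom_schema`.
#' @return Character vector of violation descriptions; empty if valid.
#' @export
validate_record <- function(codes, schema) {
  stopifnot(inherits(schema, "symptom_schema"))
  if (length(codes) != schema$n_f) {
    return(sprintf("record length %d, expected n_f = %d",
                   length(codes), schema$n_f))
  }
  codes <- as.integer(codes)
  card <- schema$fields$cardinality
  bad <- which(is.na(codes) | codes < -1L | codes >= card)
  vapply(bad, function(i) {
    sprintf("field %d ('%s'): value %s outside {-1} U [0, %d)",
            i, schema$fields$name[i], as.character(codes[i]), card[i])
  }, character(1))
}

#' Assemble a symptom dataset
#'
#' @param codes Integer matrix, one row per case, one column per schema
#'   field in schema order; -1 marks missing.
#' @param labels Optional integer vector of zero-based syndrome labels in
#'   `[0, 9)`.
#' @param schema A `symptom_schema`.
#' @param validate Check every record against the schema (default TRUE).
#' @return An object of class `symptom_dataset` with elements `codes`,
#'   `labels` (possibly NULL) and `n`.
#' @export
symptom_dataset <- function(codes, labels = NULL, schema, validate = TRUE) {
  stopifnot(inherits(schema, "symptom_schema"))
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (ncol(codes) != schema$n_f) {
    stop("codes has ", ncol(codes), " columns, expected n_f = ", schema$n_f,
         call. = FALSE)
  }
  colnames(codes) <- schema$fields$name
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(codes)) {
      stop("labels length does not match number of records", call. = FALSE)
    }
    if (any(is.na(labels) | labels < 0L | labels >= n_syndrome_classes())) {
      stop("labels must lie in [0, ", n_syndrome_classes(), ")", call. = FALSE)
    }
  }
  if (validate && nrow(codes) > 0L) {
    card <- schema$fields$cardinality
    bad <- which(t(codes) < -1L | t(codes) >= card, arr.ind = TRUE)
    if (length(bad) > 0L) {
      stop("record ", bad[1, 2], ", field ", bad[1, 1],
           ": code out of range", call. = FALSE)
    }
  }
  structure(list(codes = codes, labels = labels, n = nrow(codes)),
            class = "symptom_dataset")
}

#' @export
print.symptom_dataset <- function(x, ...) {
  cat("<symptom_dataset> ", x$n, " records x ", ncol(x$codes), " fields",
      if (is.null(x$labels)) ", unlabelled" else ", labelled", "\n", sep = "")
  invisible(x)
}

#' Write records to a delimited text file
#'
#' One column per schema field in schema order plus, for labelled datasets,
#' a trailing `label` column; missing values are written as -1.
#'
#' @param dataset A `symptom_dataset`.
#' @param path Output file path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @export
write_records <- function(dataset, path, sep = ",") {
  stopifnot(inherits(dataset, "symptom_dataset"))
  df <- as.data.frame(dataset$codes, check.names = FALSE)
  if (!is.null(dataset$labels)) df$label <- dataset$labels
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}

#' Read records from a delimited text file
#'
#' Expects the header and column order written by [write_records()]. Parse
#' problems (ragged rows, non-integer cells, out-of-range labels) are
#' reported with the offending data line number.
#'
#' @param path Input file path.
#' @param schema A `symptom_schema` giving the expected columns.
#' @return A `symptom_dataset`.
#' @export
read_records <- function(path, schema) {
  stopifnot(inherits(schema, "symptom_schema"))
  header <- strsplit(readLines(path, n = 1L), "[,\t]")[[1]]
  expect <- schema$fields$name
  has_label <- length(header) == length(expect) + 1L &&
    header[length(header)] == "label"
  if (!(identical(header, expect) || has_label)) {
    stop("header does not match schema field order (",
         length(header), " columns found)", call. = FALSE)
  }
  dt <- tryCatch(
    data.table::fread(path, sep = "auto", header = TRUE,
                      colClasses = list(character = seq_along(header)),
                      fill = FALSE),
    error = function(e) stop("parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (nrow(dt) == 0L) {
    return(symptom_dataset(
      matrix(integer(0), 0, schema$n_f),
      labels = if (has_label) integer(0) else NULL, schema = schema
    ))
  }
  mat <- as.matrix(dt)
  suppressWarnings({
    num <- matrix(as.integer(mat), nrow(mat), ncol(mat))
    bad <- which(is.na(num) | num != as.numeric(mat))
  })
  if (length(bad) > 0L) {
    line <- (bad[1] - 1L) %% nrow(mat) + 2L  # +1 header, +1 one-based
    stop("non-integer cell at line ", line, call. = FALSE)
  }
  labels <- NULL
  if (has_label) {
    labels <- num[, ncol(num)]
    out_of_range <- which(labels < 0L | labels >= n_syndrome_classes())
    if (length(out_of_range) > 0L) {
      stop("label out of range at line ", out_of_range[1] + 1L, call. = FALSE)
    }
    num <- num[, -ncol(num), drop = FALSE]
  }
  symptom_dataset(num, labels = labels, schema = schema)
}

#' Serialize a schema to a structured text (YAML) file
#'
#' @param schema A `symptom_schema`.
#' @param path Output path.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "symptom_schema"))
  doc <- list(fields = lapply(seq_len(schema$n_f), function(i) {
    list(name = schema$fields$name[i],
         category = schema$fields$category[i],
         vocabulary = as.list(schema$vocab[[i]]))
  }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a schema from a structured text (YAML) file
#'
#' @param path Input path written by [write_schema()].
#' @return A `symptom_schema`.
#' @export
read_schema <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$fields)) stop("schema file has no 'fields' key",
                                call. = FALSE)
  nm <- vapply(doc$fields, `[[`, character(1), "name")
  ct <- vapply(doc$fields, `[[`, character(1), "category")
  vocab <- lapply(doc$fields, function(f) unlist(f$vocabulary))
  names(vocab) <- nm
  new_schema(nm, ct, lengths(vocab), vocab = vocab)
}
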