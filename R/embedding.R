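#' Field-wise one-hot encoding of a record
#'
#' Concatenates one indicator block per field. Each block has
#' `cardinality_f + 1` slots: slot 1 fires for a missing field (-1), slot
#' `c + 2` for code `c`. Every record therefore lights exactly `n_f` ones.
#'
#' @param codes Integer record of length `schema$n_f` (-1 = missing).
#' @param schema A `symptom_schema`.
#' @return Integer 0/1 vector of length `sum(cardinality + 1)`.
#' @export
one_hot <- function(codes, schema) {
  stopifnot(inherits(schema, "symptom_schema"))
  viol <- validate_record(codes, schema)
  if (length(viol) > 0L) stop(paste(viol, collapse = "; "), call. = FALSE)
  card <- schema$fields$cardinality
  offsets <- c(0L, cumsum(card + 1L))
  v <- integer(sum(card + 1L))
  v[offsets[seq_len(schema$n_f)] + as.integer(codes) + 2L] <- 1L
  v
}

#' Initialize embedding tables
#'
#' One table per field with `cardinality_f + 1` rows of width `k`; row 1 is
#' the dedicated learned representation of "missing" (-1), so records with
#' absent symptoms still map to a fully dense matrix. Tables are stacked
#' into a single matrix with per-field row offsets.
#'
#' @param schema A `symptom_schema`.
#' @param k Embedding width shared by every field.
#' @param seed Integer seed.
#' @param sd Standard deviation of the normal initializer.
#' @return List with `table` (stacked matrix, `sum(cardinality + 1)` rows x
#'   `k` columns), `offsets` (0-based first-row offset per field) and `k`.
#' @export
init_embedding <- function(schema, k = 8L, seed = 1L, sd = 0.1) {
  stopifnot(inherits(schema, "symptom_schema"), k >= 1L)
  card <- schema$fields$cardinality
  rows <- sum(card + 1L)
  tab <- withr::with_seed(as.integer(seed),
                          matrix(stats::rnorm(rows * k, sd = sd), rows, k))
  list(table = tab, offsets = c(0L, cumsum(card + 1L))[seq_len(schema$n_f)],
       k = as.integer(k))
}

#' Embed a record as a dense field-by-dimension matrix
#'
#' Row `f` of the result is the embedding-table row selected by the code of
#' field `f` (row 1 of the field's table for missing). Equivalently, the
#' one-hot vector times the block-diagonal of all tables; the two
#' formulations agree exactly.
#'
#' @param codes Integer record of length `schema$n_f`.
#' @param embedding Tables from [init_embedding()].
#' @param schema A `symptom_schema`.
#' @return Numeric matrix `n_f x k` (the dense matrix consumed by both
#'   feature branches).
#' @export
embed_record <- function(codes, embedding, schema) {
  stopifnot(inherits(schema, "symptom_schema"))
  viol <- validate_record(codes, schema)
  if (length(viol) > 0L) stop(paste(viol, collapse = "; "), call. = FALSE)
  card <- schema$fields$cardinality
  if (length(embedding$offsets) != schema$n_f ||
      nrow(embedding$table) != sum(card + 1L)) {
    stop("embedding tables do not match schema (expected ",
         sum(card + 1L), " rows)", call. = FALSE)
  }
  embedding$table[embedding$offsets + as.integer(codes) + 2L, , drop = FALSE]
}

#' Flatten an embedded matrix to the cross-network input vector
#'
#' Row-major flattening: row `f` of the `n_f x k` matrix occupies positions
#' `[(f-1)*k + 1, f*k]` of the output. Cross-layer weights are
#' order-sensitive, so this convention is fixed and shared with the C++
#' training core.
#'
#' @param E Numeric matrix `n_f x k`.
#' @return Numeric vector of length `n_f * k`.
#' @export
flatten_embedding <- function(E) {
  as.vector(t(E))
}
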