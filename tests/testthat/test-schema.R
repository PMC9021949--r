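test_that("default schema holds the 60-field four-examination catalogue", {
  sch <- build_default_schema()
  expect_s3_class(sch, "symptom_schema")
  expect_identical(sch$n_f, 60L)
  counts <- table(sch$fields$category)
  expect_identical(as.integer(counts[["inspection"]]), 30L)
  expect_identical(as.integer(counts[["listening_smelling"]]), 6L)
  expect_identical(as.integer(counts[["inquiry"]]), 22L)
  expect_identical(as.integer(counts[["palpation"]]), 2L)
  expect_true(all(sch$fields$cardinality == 8L))
  expect_false(anyDuplicated(sch$fields$name) > 0)
})

test_that("vocabulary-size overrides apply per field and reject unknowns", {
  sch <- build_default_schema(vocab_sizes = c(Tone = 3L, Sleep = 12L))
  expect_identical(sch$fields["Tone", "cardinality"], 3L)
  expect_identical(sch$fields["Sleep", "cardinality"], 12L)
  expect_identical(sch$fields["Voice", "cardinality"], 8L)
  expect_error(build_default_schema(vocab_sizes = c(`No such field` = 4L)),
               "No such field")
})

test_that("encoding maps terms to indices and missing fields to -1", {
  sch <- build_default_schema()
  empty <- encode_record(list(), sch)
  expect_identical(unname(empty), rep(-1L, 60L))
  r <- encode_record(list(`Tongue coating color` = "term_1"), sch)
  expect_identical(r[["Tongue coating color"]], 0L)
  expect_identical(sum(r == -1L), 59L)
  expect_error(encode_record(list(Nonfield = "term_1"), sch), "Nonfield")
  expect_error(encode_record(list(Tone = "no_such_term"), sch),
               "no_such_term.*Tone")
})

test_that("encode/decode round-trips every present field", {
  sch <- tiny_schema()
  set.seed(101)
  for (rep in 1:30) {
    present <- sch$fields$name[stats::runif(sch$n_f) < 0.6]
    raw <- lapply(present, function(f) sample(sch$vocab[[f]], 1L))
    names(raw) <- present
    codes <- encode_record(raw, sch)
    expect_length(validate_record(codes, sch), 0L)
    back <- decode_record(codes, sch)
    expect_identical(back[order(names(back))], raw[order(names(raw))])
  }
})

test_that("record validation reports position, value and range", {
  sch <- build_default_schema()
  ok <- rep(-1L, 60L)
  expect_identical(validate_record(ok, sch), character(0))
  bad <- ok
  bad[5] <- 8L  # == cardinality, one past the last valid code
  v <- validate_record(bad, sch)
  expect_length(v, 1L)
  expect_match(v, "field 5")
  expect_match(v, "\\[0, 8\\)")
  v2 <- validate_record(rep(0L, 59L), sch)
  expect_match(v2, "expected n_f = 60")
})

test_that("record files round-trip exactly and parse errors carry lines", {
  sch <- build_default_schema()
  ds <- tiny_dataset(100L, schema = sch, seed = 7L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(ds, path)
  back <- read_records(path, sch)
  expect_identical(back$codes, ds$codes)
  expect_identical(back$labels, ds$labels)

  # header-only file -> empty dataset
  writeLines(paste(c(sch$fields$name, "label"), collapse = ","), path)
  empty <- read_records(path, sch)
  expect_identical(empty$n, 0L)

  # missing header -> error
  writeLines(paste(rep("1", 61), collapse = ","), path)
  expect_error(read_records(path, sch), "header")

  # non-integer cell -> parse error naming the line
  write_records(ds, path)
  lines <- readLines(path)
  lines[4] <- sub("^-1", "x", sub("^[0-9]+", "x", lines[4]))
  writeLines(lines, path)
  expect_error(read_records(path, sch), "line 4")
})

test_that("out-of-range labels in record files are rejected", {
  sch <- tiny_schema()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste(c(sch$fields$name, "label"), collapse = ","),
               paste(c(rep("0", 6), "9"), collapse = ",")), path)
  expect_error(read_records(path, sch), "label out of range at line 2")
})

test_that("schema YAML serialization round-trips", {
  sch <- build_default_schema(vocab_sizes = c(Tone = 3L))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_schema(sch, path)
  back <- read_schema(path)
  expect_identical(back$fields, sch$fields)
  expect_identical(back$vocab, sch$vocab)
})
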