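test_that("class priors reproduce the corpus proportions", {
  st <- syndrome_types()
  expect_identical(sum(st$count), 5273L)
  pri <- default_class_priors()
  expect_equal(sum(pri), 1, tolerance = 1e-12)
  expect_identical(names(which.max(pri)), "Qi stagnation and blood stasis")
  expect_identical(max(st$count), 751L)
  expect_equal(unname(pri), st$count / 5273)
})

test_that("profiles are deterministic, valid and pairwise distinct", {
  sch <- build_default_schema()
  p1 <- make_profiles(sch, seed = 9L)
  p2 <- make_profiles(sch, seed = 9L)
  expect_identical(p1, p2)
  expect_identical(dim(p1), c(9L, 60L))
  card <- sch$fields$cardinality
  expect_true(all(p1 >= 0L & p1 < matrix(card, 9, 60, byrow = TRUE)))
  # pairwise Hamming distance strictly positive
  for (a in 1:8) for (b in (a + 1):9) {
    expect_gt(sum(p1[a, ] != p1[b, ]), 0L)
  }
  # degenerate single-term vocabularies: identical profiles are permitted
  sch1 <- new_schema(c("A", "B"), c("inquiry", "inquiry"), c(1L, 1L))
  pd <- make_profiles(sch1, n_classes = 3L, seed = 1L)
  expect_true(all(pd == 0L))
})

test_that("the perfectly separable limit reproduces the profiles", {
  sch <- tiny_schema()
  prof <- make_profiles(sch, seed = 2L)
  ds <- generate_dataset(
    generator_config(60L, signal_strength = 1, missing_rate = 0, seed = 3L),
    sch, prof)
  for (i in seq_len(ds$n)) {
    expect_identical(unname(ds$codes[i, ]), unname(prof[ds$labels[i] + 1L, ]))
  }
  # nearest-profile classification is perfect
  pred <- apply(ds$codes, 1, function(r) {
    which.min(colSums(t(prof) != r)) - 1L
  })
  expect_identical(as.integer(pred), ds$labels)
})

test_that("generated label frequencies follow the priors", {
  sch <- build_default_schema()
  prof <- make_profiles(sch, seed = 2L)
  ds <- generate_dataset(generator_config(10000L, seed = 4L), sch, prof)
  obs <- tabulate(ds$labels + 1L, nbins = 9L)
  gof <- stats::chisq.test(obs, p = default_class_priors())
  expect_gt(gof$p.value, 0.01)
})

test_that("the realized missing fraction concentrates at the target rate", {
  sch <- tiny_schema()
  prof <- make_profiles(sch, seed = 2L)
  n <- 10000L
  rho <- 0.3
  ds <- generate_dataset(
    generator_config(n, missing_rate = rho, seed = 6L), sch, prof)
  cells <- n * sch$n_f
  se <- sqrt(rho * (1 - rho) / cells)
  expect_lt(abs(mean(ds$codes == -1L) - rho), 3 * se)
})

test_that("field distributions given the label match the generating mixture", {
  sch <- tiny_schema()
  prof <- make_profiles(sch, seed = 2L)
  q <- 0.6
  ds <- generate_dataset(
    generator_config(20000L, signal_strength = q, missing_rate = 0,
                     seed = 8L), sch, prof)
  # for each field: P(code == profile | label) = q + (1-q)/cardinality
  for (f in c(1L, 4L)) {
    card <- sch$fields$cardinality[f]
    expected <- q + (1 - q) / card
    for (cls in c(0L, 5L)) {
      sel <- ds$labels == cls
      hit <- mean(ds$codes[sel, f] == prof[cls + 1L, f])
      se <- sqrt(expected * (1 - expected) / sum(sel))
      expect_lt(abs(hit - expected), 4 * se)
    }
  }
})

test_that("generation is a pure function of config, schema and profiles", {
  sch <- tiny_schema()
  prof <- make_profiles(sch, seed = 2L)
  cfg <- generator_config(500L, seed = 11L)
  d1 <- generate_dataset(cfg, sch, prof)
  d2 <- generate_dataset(cfg, sch, prof)
  expect_identical(d1$codes, d2$codes)
  expect_identical(d1$labels, d2$labels)
})

test_that("generator configuration is validated", {
  expect_error(generator_config(10, class_priors = rep(0.2, 9)), "sum to 1")
  expect_error(generator_config(10, signal_strength = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(10, missing_rate = -0.1), "\\[0, 1\\]")
})

test_that("train/test split is a seeded exhaustive partition", {
  sch <- tiny_schema()
  ds <- tiny_dataset(1000L, schema = sch)
  sp <- split_train_test(ds, 0.75, seed = 1L)
  expect_identical(sp$train$n, 750L)
  expect_identical(sp$test$n, 250L)
  key <- function(d) paste(apply(d$codes, 1, paste, collapse = ","), d$labels)
  expect_identical(sort(c(key(sp$train), key(sp$test))), sort(key(ds)))
  sp2 <- split_train_test(ds, 0.75, seed = 1L)
  expect_identical(sp$train$codes, sp2$train$codes)
  sp3 <- split_train_test(ds, 0.75, seed = 2L)
  expect_false(identical(sp$train$codes, sp3$train$codes))
  # n = 4 at 3:1
  small <- tiny_dataset(4L, schema = sch)
  sp4 <- split_train_test(small, 0.75, seed = 1L)
  expect_identical(sp4$train$n, 3L)
  expect_identical(sp4$test$n, 1L)
  expect_error(split_train_test(tiny_dataset(1L, schema = sch)),
               "at least 2")
})

test_that("stratified splitting preserves per-class shares", {
  sch <- tiny_schema()
  ds <- tiny_dataset(900L, schema = sch)
  sp <- split_train_test(ds, 0.75, seed = 3L, stratify = TRUE)
  key <- function(d) paste(apply(d$codes, 1, paste, collapse = ","), d$labels)
  expect_identical(sort(c(key(sp$train), key(sp$test))), sort(key(ds)))
  for (cls in 0:8) {
    n_cls <- sum(ds$labels == cls)
    expect_identical(sum(sp$train$labels == cls),
                     as.integer(round(0.75 * n_cls)))
  }
  unlab <- symptom_dataset(ds$codes, schema = sch)
  expect_error(split_train_test(unlab, stratify = TRUE), "labels")
})
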