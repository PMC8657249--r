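test_that("load_cohort reads a valid CSV and rejects malformed ones", {
  schema <- toy_schema()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,grade,event", "61,lo,1", "54,hi,0", "47,lo,0"), path)
  ch <- load_cohort(path, schema)
  expect_s3_class(ch, "cohort_table")
  expect_equal(ch$n, 3L)
  expect_equal(ch$labels, c(1L, 0L, 0L))
  expect_identical(levels(ch$features$grade), c("hi", "lo"))

  # outcome column absent
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,grade", "61,lo"), path2)
  expect_error(load_cohort(path2, schema), "event")

  # non-binary outcome names the offending row
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,grade,event", "1,lo,0", "2,lo,1", "3,lo,0", "4,lo,1",
               "5,lo,2"), path3)
  expect_error(load_cohort(path3, schema), "row: 5")
})

test_that("feature_schema enforces its invariants", {
  expect_error(feature_schema(c("a", "a"), c("ordinal", "ordinal"), "y"),
               "unique")
  expect_error(feature_schema("a", c("ordinal", "ordinal"), "y"), "length")
  expect_error(feature_schema("a", "ordinal", "a"), "outcome")
  expect_error(feature_schema("a", "fancy", "y"), "unknown feature kind")
})

test_that("split_cohort sizes, determinism and round-trip", {
  ch <- counted_cohort(70, 30)
  sp <- split_cohort(ch, 0.6, seed = 42)
  expect_length(sp$train_idx, 60L)
  expect_length(sp$test_idx, 40L)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)
  # recombination reproduces the original row set
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_len(ch$n))
  # same seed -> identical indices; different seed -> different
  sp2 <- split_cohort(ch, 0.6, seed = 42)
  expect_identical(sp$train_idx, sp2$train_idx)
  expect_false(identical(sp$train_idx,
                         split_cohort(ch, 0.6, seed = 43)$train_idx))
  # stratification preserves class proportions to within one case
  tab <- table(ch$labels[sp$train_idx])
  expect_equal(as.integer(tab), c(42L, 18L))
})

test_that("registry-scale split gives the exact 60% training count", {
  # oracle: round(27455 * 0.6) = 16473
  ch <- counted_cohort(24090, 3365)
  for (strat in c(TRUE, FALSE)) {
    sp <- split_cohort(ch, 0.6, seed = 7, stratify = strat)
    expect_length(sp$train_idx, 16473L)
    expect_length(sp$test_idx, 27455L - 16473L)
  }
})

test_that("upsample_minority balances exactly and leaves the majority alone", {
  # oracle: minority duplicated up to the majority count
  ch <- counted_cohort(24090, 3365)
  up <- upsample_minority(ch, seed = 5)
  expect_equal(as.integer(table(up$labels)), c(24090L, 24090L))
  expect_equal(mean(up$labels), 0.5)
  # majority multiset untouched (original rows all kept, no extras)
  expect_equal(sum(up$labels == 0L), sum(ch$labels == 0L))

  # balanced input is a fixed point
  chb <- counted_cohort(50, 50)
  expect_equal(upsample_minority(chb, seed = 1)$n, 100L)
  expect_equal(as.integer(table(upsample_minority(chb, 1)$labels)), c(50L, 50L))

  # {0:3, 1:1}: the single minority row appears 3 times
  ch31 <- counted_cohort(3, 1)
  up31 <- upsample_minority(ch31, seed = 2)
  expect_equal(sum(up31$labels == 1L), 3L)
  expect_equal(length(unique(up31$features$age[up31$labels == 1L])), 1L)

  expect_error(upsample_minority(counted_cohort(5, 0)), "both")
})

test_that("encoder one-hots categoricals and freezes the training map", {
  sch <- feature_schema(c("site", "age"), c("categorical", "continuous"), "y")
  tr <- cohort_table(data.frame(site = c("a", "b", "c", "a"),
                                age = 1:4, y = c(0, 1, 0, 1)), sch)
  enc <- fit_encoder(tr)
  x <- apply_encoder(enc, tr)
  # 3 levels -> 2 indicator columns (+ continuous passthrough)
  expect_identical(colnames(x), c("site..b", "site..c", "age"))
  expect_equal(x[, "site..b"], c(0, 1, 0, 0))
  expect_equal(x[, "age"], 1:4, ignore_attr = TRUE)

  # unseen level at transform time -> all-zero indicators + warning
  te <- cohort_table(data.frame(site = c("a", "zz"), age = c(9, 10),
                                y = c(0, 1)), sch)
  expect_warning(xt <- apply_encoder(enc, te), "unseen")
  expect_equal(unname(xt[2, c("site..b", "site..c")]), c(0, 0))

  # all-continuous schema is an identity mapping
  sch2 <- feature_schema(c("a", "b"), c("continuous", "continuous"), "y")
  ch2 <- cohort_table(data.frame(a = c(1.5, 2.5), b = c(3, 4), y = c(0, 1)), sch2)
  x2 <- apply_encoder(fit_encoder(ch2), ch2)
  expect_equal(unname(x2), unname(as.matrix(ch2$features)))
})

test_that("write_split persists a two-column partition CSV", {
  ch <- counted_cohort(6, 4)
  sp <- split_cohort(ch, 0.6, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_split(sp, path)
  df <- read.csv(path)
  expect_identical(names(df), c("row_index", "partition"))
  expect_equal(nrow(df), 10L)
  expect_equal(sum(df$partition == "train"), 6L)
})
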