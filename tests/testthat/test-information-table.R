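test_that("CSV round-trip preserves objects, order and concept", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_information_table(fiveobj$table, path)
  tab <- read_information_table(path, decision_col = "d", id_col = "id",
                                positive_label = "1")
  expect_identical(tab$object_ids, paste0("c", 1:5))
  expect_identical(tab$concept, c("c1", "c3", "c5"))
  expect_equal(tab$values, fiveobj$table$values)

  single <- read_information_table(
    withr::local_tempfile(lines = c("id,a,d", "c1,3,1"), fileext = ".csv"),
    decision_col = "d", id_col = "id")
  expect_length(single$object_ids, 1L)
})

test_that("the packaged five-object CSV loads with its shipped schema", {
  csv <- system.file("extdata", "five_objects.csv", package = "rough3wd")
  cfg <- system.file("extdata", "five_objects.yaml", package = "rough3wd")
  schema <- yaml::read_yaml(cfg)
  tab <- read_information_table(csv, decision_col = schema$decision_col,
                                id_col = schema$id_col,
                                positive_label = schema$positive_label)
  expect_equal(tab$values, fiveobj$table$values)
  expect_identical(tab$concept, fiveobj$table$concept)
  expect_equal(unlist(schema$xi), fiveobj$xi)
})

test_that("validation rejects malformed tables", {
  dup <- withr::local_tempfile(lines = c("id,a,d", "c1,1,1", "c1,2,0"),
                               fileext = ".csv")
  expect_error(read_information_table(dup, decision_col = "d", id_col = "id"),
               "duplicate")
  nofile <- withr::local_tempfile(lines = c("id,a", "c1,1"), fileext = ".csv")
  expect_error(read_information_table(nofile, decision_col = "d",
                                      id_col = "id"), "decision column")
  expect_error(information_table(matrix(-1), decision = TRUE), "nonnegative")
  cat_csv <- withr::local_tempfile(lines = c("id,a,d", "c1,yes,1"),
                                   fileext = ".csv")
  expect_error(read_information_table(cat_csv, decision_col = "d",
                                      id_col = "id"), "encoding")
})

test_that("categorical encoding policies behave as declared", {
  df <- data.frame(x = c("yes", "no", "yes"),
                   z = c("a", "b", "c"), n = c(1, 2, 3))
  ord <- encode_categoricals(df, policy = list(x = c(no = 0, yes = 1),
                                               z = "ordinal"))
  expect_equal(ord$data$x, c(1, 0, 1))
  expect_equal(ord$data$z, c(0, 1, 2))
  expect_error(encode_categoricals(data.frame(x = "maybe"),
                                   policy = list(x = c(no = 0, yes = 1))),
               "unseen")

  oh <- encode_categoricals(df["z"], policy = "onehot")
  expect_equal(ncol(oh$data), 3L)
  expect_true(all(rowSums(oh$data) == 1))

  numeric_only <- encode_categoricals(df["n"], policy = "ordinal")
  expect_identical(numeric_only$data, df["n"])
})

test_that("max-normalization matches the worked cells and its invariants", {
  norm <- max_normalize(fiveobj$table)
  expect_equal(norm$values["c3", "b"], 0.2)
  expect_equal(norm$values["c1", "a"], 0.16)
  expect_equal(max(norm$values[, "a"]), 1)
  # round trip
  expect_equal(sweep(norm$values, 2, norm$column_maxima, "*"),
               fiveobj$table$values)
  # idempotence
  expect_equal(max_normalize(norm)$values, norm$values)
  # scale invariance per column
  scaled <- fiveobj$table
  scaled$values[, "b"] <- scaled$values[, "b"] * 7.3
  expect_equal(max_normalize(scaled)$values, norm$values)
})

test_that("degenerate columns normalize predictably", {
  const <- information_table(matrix(c(5, 5, 0, 0), 2,
                                    dimnames = list(NULL, c("a", "b"))),
                             decision = c(TRUE, FALSE))
  expect_warning(norm <- max_normalize(const), "similarity-inert")
  expect_equal(unname(norm$values[, "a"]), c(1, 1))
  expect_equal(unname(norm$values[, "b"]), c(0, 0))
})
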