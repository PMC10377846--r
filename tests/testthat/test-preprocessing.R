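make_missing_table <- function() {
  labeled_table(
    data.frame(
      a = c(1, NA, NA, NA, 5),        # 3/5 missing -> dropped at 0.5
      b = c(2, NA, 4, 6, NA),         # exactly 40% missing -> kept
      c = factor(c("x", "x", "y", NA, "x")),
      d = c(1, 2, 3, 4, 5)),
    labels = c(0, 1, 0, 1, 1))
}

test_that("drop_sparse removes columns then rows past a strict threshold", {
  tab <- make_missing_table()
  out <- drop_sparse(tab, 0.5)
  expect_false("a" %in% feature_names(out))
  expect_true(all(c("b", "c", "d") %in% feature_names(out)))
  expect_equal(nrow(out$data), 5) # no remaining row above 50%

  # a column with exactly 50% missing is retained
  half <- labeled_table(data.frame(x = c(1, NA, 3, NA), y = 1:4),
                        labels = c(0, 1, 0, 1))
  expect_true("x" %in% feature_names(drop_sparse(half, 0.5)))

  # row sparsity measured over the remaining columns
  rowy <- labeled_table(
    data.frame(x = c(1, NA, 3), y = c(2, NA, 4), z = c(3, 5, 6)),
    labels = c(1, 0, 1))
  expect_equal(nrow(drop_sparse(rowy, 0.5)$data), 2)

  fully <- small_table(n = 30, seed = 1, normalize = FALSE)
  expect_identical(drop_sparse(fully), fully)

  allbad <- labeled_table(data.frame(x = c(NA, NA, 1)), labels = c(0, 1, 1))
  expect_error(drop_sparse(allbad, 0.5), "unusable")
})

test_that("impute fills numeric means and nominal modes, and only those", {
  tab <- labeled_table(
    data.frame(num = c(2, NA, 4),
               nom = factor(c("A", "A", NA), levels = c("A", "B"))),
    labels = c(0, 1, 1))
  out <- impute(tab)
  expect_equal(out$data$num, c(2, 3, 4))
  expect_equal(as.character(out$data$nom), c("A", "A", "A"))
  expect_false(anyNA(out$data))

  # mode with a tie resolves to the earlier level, deterministically
  tie <- labeled_table(
    data.frame(nom = factor(c("B", "A", NA), levels = c("A", "B"))),
    labels = c(0, 1, 1))
  expect_equal(as.character(impute(tie)$data$nom)[3], "A")

  clean <- small_table(n = 40, seed = 2, normalize = FALSE)
  expect_identical(impute(clean), clean)

  dead <- labeled_table(data.frame(x = c(NA_real_, NA_real_), y = c(1, 2)),
                        labels = c(0, 1))
  expect_error(impute(dead), "fully missing")
})

test_that("mean imputation is a fixed point of the column mean", {
  tab <- inject_missing(small_table(n = 200, seed = 3, normalize = FALSE),
                        0.15, seed = 4)
  out <- impute(tab)
  for (nm in names(tab$types)[tab$types == "numeric"]) {
    expect_equal(mean(out$data[[nm]]), mean(tab$data[[nm]], na.rm = TRUE),
                 tolerance = 1e-12)
  }
  # observed cells unchanged
  obs <- !is.na(tab$data$f2)
  expect_identical(out$data$f2[obs], tab$data$f2[obs])
})

test_that("min-max normalization maps extremes and midpoints as required", {
  tab <- labeled_table(
    data.frame(x = c(2, 6, 10), g = factor(c("u", "v", "u"))),
    labels = c(0, 1, 1))
  norm <- min_max_normalize(tab)
  expect_equal(norm$table$data$x, c(0, 0.5, 1))
  expect_identical(norm$table$data$g, tab$data$g)

  # degenerate column maps to 0
  flat <- labeled_table(data.frame(x = c(3, 3, 3), y = c(1, 2, 3)),
                        labels = c(0, 1, 1))
  expect_equal(min_max_normalize(flat)$table$data$x, c(0, 0, 0))

  # range contract and idempotent replay on the fitting table
  big <- small_table(n = 120, seed = 5, normalize = FALSE)
  nb <- min_max_normalize(big)
  mat <- as_feature_matrix(nb$table)[, big$types == "numeric"]
  expect_true(all(mat >= 0 & mat <= 1))
  expect_equal(apply_normalization(big, nb$params), nb$table)

  # params survive serialization
  path <- withr::local_tempfile(fileext = ".json")
  write_normalization_params(nb$params, path)
  back <- read_normalization_params(path)
  expect_equal(apply_normalization(big, back), nb$table)

  expect_error(min_max_normalize(inject_missing(big, 0.1, 1)), "impute")
})

test_that("epworth_category follows the clinical bands and range", {
  expect_match(epworth_category(0), "lower normal")
  expect_match(epworth_category(5), "lower normal")
  expect_match(epworth_category(6), "higher normal")
  expect_match(epworth_category(11), "mild")
  expect_match(epworth_category(12), "mild")
  expect_match(epworth_category(13), "moderate")
  expect_match(epworth_category(16), "significant")
  expect_match(epworth_category(24), "significant")
  expect_error(epworth_category(25), "0,24")
  expect_error(epworth_category(-1), "0,24")
  expect_error(epworth_category(10.5), "whole")
})

test_that("split_groups partitions rows with the documented column handling", {
  tab <- generate_dataset(config = generator_config(seed = 6))
  for (v in c("race", "sex")) {
    gs <- split_groups(tab, group_spec(v))
    expect_length(gs, 2)
    expect_equal(sum(vapply(gs, function(g) nrow(g$data), numeric(1))), 274)
    for (g in gs) expect_equal(n_features(g), 30) # grouping column removed
  }
  ga <- split_groups(tab, group_spec("age"))
  expect_equal(sum(vapply(ga, function(g) nrow(g$data), numeric(1))), 274)
  for (g in ga) expect_equal(n_features(g), 31) # age retained

  # boundary: the threshold itself goes to the lower group
  small <- labeled_table(data.frame(f2 = c(40, 50, 51)), labels = c(0, 1, 1))
  gs <- split_groups(small, group_spec("age", column = "f2"))
  expect_equal(sort(unname(vapply(gs, function(g) nrow(g$data), numeric(1)))),
               c(1, 2))
  expect_equal(nrow(gs[["age<=50"]]$data), 2)

  expect_error(split_groups(tab, group_spec("race", column = "nope")),
               "not found")
  expect_error(group_spec("height"), "unknown group variable")
})

test_that("the preprocessing pipeline leaves no missing cells", {
  raw <- inject_missing(small_table(n = 150, seed = 7, normalize = FALSE),
                        0.2, seed = 8)
  out <- min_max_normalize(impute(drop_sparse(raw)))$table
  expect_false(anyNA(out$data))
})
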