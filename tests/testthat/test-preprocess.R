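test_that("filter keeps ever-present classes above threshold and aggregates the rest", {
  tab <- normalize_composition(toy_counts())
  out <- filter_classes(tab, filter_spec(min_proportion = 0.01))
  rep <- out$report

  # C is ever-present but peaks at 0.006 < 0.01; D has a zero in s1
  expect_setequal(rep$kept_classes, c("A", "B", "E"))
  expect_setequal(rep$aggregated_classes, c("C", "D"))
  expect_false(rep$other_dropped)
  expect_identical(rep$K_before, 5L + 0L)
  expect_identical(rep$K_after, 4L)
  expect_identical(out$table$class_names, c("A", "B", "E", "LRT other"))
  expect_equal(unname(out$table$values[, "LRT other"]),
               c(0.005, 0.054, 0.056))
  expect_equal(rowSums(out$table$values), rep(1, 3), ignore_attr = TRUE)
  expect_true(all(out$table$values > 0))
})

test_that("an aggregate with a zero sample is dropped and rows renormalized", {
  tab <- toy_counts()
  tab$values <- tab$values[, c("A", "B", "D", "E")]
  tab$class_names <- c("A", "B", "D", "E")
  tab <- normalize_composition(tab)
  out <- filter_classes(tab, filter_spec(min_proportion = 0.01))
  expect_true(out$report$other_dropped)
  expect_identical(out$report$K_after, 3L)
  expect_identical(out$table$class_names, c("A", "B", "E"))
  expect_equal(rowSums(out$table$values), rep(1, 3), ignore_attr = TRUE)
  # renormalized over {A, B, E} only
  expect_equal(unname(out$table$values[1, ]),
               c(50, 30, 19.5) / 99.5, tolerance = 1e-12)
})

test_that("zero-free table with min_proportion 0 passes through unchanged", {
  tab <- dir_table(2, 5, null_alphas(2, c(2, 3, 4)), seed = 3)
  out <- filter_classes(tab, filter_spec())
  expect_identical(out$report$K_after, out$report$K_before)
  expect_true(out$report$other_dropped)
  expect_equal(out$table$values, tab$values)
})

test_that("degenerate filters error informatively", {
  tab <- dir_table(2, 5, null_alphas(2, c(2, 3, 4)), seed = 3)
  expect_error(filter_classes(tab, filter_spec(min_proportion = 0.99)),
               "no class passes|aggregated")
  expect_error(filter_classes(toy_counts(), filter_spec()), "normalized")

  # only A and B are ever-present; the aggregate {C} carries a zero and
  # is dropped, leaving K_after = 2 -> refuse
  v <- rbind(c(0.6, 0.4, 0), c(0.5, 0.3, 0.2))
  tab2 <- composition_table(v, c("a", "b"), c("A", "B", "C"), c("e", "e"),
                            is_normalized = TRUE)
  expect_error(filter_classes(tab2, filter_spec()), "more than 2 classes")
})

test_that("filter_spec validates its fields", {
  expect_error(filter_spec(min_proportion = 1.5), "min_proportion")
  expect_error(filter_spec(min_proportion = -0.1), "min_proportion")
  expect_error(filter_spec(zero_replacement = 1e-3), "zero_replacement")
  expect_error(filter_spec(zero_replacement = 0), "zero_replacement")
})

test_that("replace_zeros substitutes, renormalizes and warns", {
  v <- rbind(c(0.5, 0.5, 0), c(0.2, 0.3, 0.5))
  tab <- composition_table(v, c("a", "b"), c("x", "y", "z"), c("e", "e"),
                           is_normalized = TRUE)
  expect_warning(out <- replace_zeros(tab, 1e-16), "extreme caution")
  expect_true(all(out$values > 0))
  expect_equal(rowSums(out$values), c(1, 1), ignore_attr = TRUE)
  expect_equal(out$values[1, 3], 1e-16, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(out$values[2, ], tab$values[2, ])  # zero-free row untouched

  tab2 <- dir_table(2, 3, null_alphas(2, c(1, 2, 3)), seed = 1)
  expect_silent(out2 <- replace_zeros(tab2, 1e-16))
  expect_equal(out2$values, tab2$values)

  expect_error(replace_zeros(tab, 0), "positive")
})

test_that("zero_replacement in the spec overrides ever-present filtering", {
  tab <- normalize_composition(toy_counts())
  expect_warning(
    out <- filter_classes(tab, filter_spec(zero_replacement = 1e-16)),
    "extreme caution")
  # D (zero-bearing) is retained because zeros were replaced;
  # C still fails the (absent) threshold? min_proportion = 0, so all kept
  expect_identical(out$report$K_after, 5L)
  expect_true(all(out$table$values > 0))
})
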