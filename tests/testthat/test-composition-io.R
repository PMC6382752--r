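test_that("CSV round-trip preserves values, names and labels", {
  tab <- dir_table(2, 4, null_alphas(2, c(2, 5, 3)), seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_composition(tab, path)
  back <- read_composition(path)
  expect_equal(back$values, tab$values, tolerance = 1e-12)
  expect_identical(back$sample_ids, tab$sample_ids)
  expect_identical(back$class_names, tab$class_names)
  expect_identical(back$environments, tab$environments)
})

test_that("samples-as-columns dialect gives the identical table", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_csv(path)
  rows <- read_composition(path)

  # build the transposed file by hand
  tpath <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("class,s1,s2,s3",
               "environment,winter,winter,summer",
               "A,50,40,45", "B,30,40,30", "C,20,20,25"), tpath)
  cols <- read_composition(tpath, dialect = "samples-as-columns")
  expect_equal(cols$values, rows$values)
  expect_identical(cols$environments, rows$environments)
  expect_identical(cols$class_names, rows$class_names)
})

test_that("validation errors name the offending cell or sample", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,environment,A,B",
               "s1,w,0.5,-0.1",
               "s2,w,0.5,0.5"), path)
  expect_error(read_composition(path), "s1.*B|B.*s1")

  writeLines(c("sample_id,environment,A,B",
               "s1,w,0.5,oops",
               "s2,w,0.5,0.5"), path)
  expect_error(read_composition(path), "non-numeric")

  writeLines(c("sample_id,environment,A,B",
               "s1,,0.5,0.5",
               "s2,w,0.5,0.5"), path)
  expect_error(read_composition(path), "environment")

  writeLines("sample_id,environment,A,B", path)
  expect_error(read_composition(path), "empty")
})

test_that("environment labels can come from a metadata file", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tA\tB\tC", "s1\t1\t2\t3", "s2\t2\t2\t2"), path)
  meta <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,environment", "s1, plot1 ", "s2,plot2"), meta)
  tab <- read_composition(path, metadata = meta)
  expect_identical(tab$environments, c("plot1", "plot2"))  # trimmed

  writeLines(c("sample_id,environment", "s1,plot1"), meta)
  expect_error(read_composition(path, metadata = meta), "s2")
})

test_that("duplicate sample or class names are rejected", {
  v <- matrix(1, 2, 2)
  expect_error(composition_table(v, c("a", "a"), c("x", "y"), c("e", "e")),
               "duplicate sample")
  expect_error(composition_table(v, c("a", "b"), c("x", "x"), c("e", "e")),
               "duplicate class")
})

test_that("normalize is idempotent, scale-invariant, and rejects zero rows", {
  tab <- toy_counts()
  nt <- normalize_composition(tab)
  expect_equal(unname(nt$values["s1", ]), c(0.5, 0.3, 0.005, 0, 0.195))
  expect_true(nt$is_normalized)
  expect_equal(normalize_composition(nt)$values, nt$values)

  # scaling a raw row leaves its normalized image unchanged
  tab2 <- tab
  tab2$values[2, ] <- tab2$values[2, ] * 37.5
  expect_equal(normalize_composition(tab2)$values, nt$values)

  tab3 <- composition_table(rbind(c(1, 1), c(0, 0)), c("a", "b"),
                            c("x", "y"), c("e", "e"))
  expect_error(normalize_composition(tab3), "b")
})

test_that("result objects write text reports and round-trip through JSON", {
  tab <- dir_table(2, 6, list(c(2, 5, 3), c(5, 2, 3)), seed = 9)
  res <- dirichlet_lrt(tab, method = "chi2")
  txt <- withr::local_tempfile(fileext = ".txt")
  write_result(res, txt, "text")
  report <- readLines(txt)
  expect_true(any(grepl("D = ", report)))
  expect_true(any(grepl("degrees of freedom", report)))

  jsn <- withr::local_tempfile(fileext = ".json")
  write_result(res, jsn, "json")
  back <- read_result(jsn)
  expect_equal(back$D, res$D)
  expect_equal(back$alpha_alt, res$alpha_alt)

  pw <- structure(list(group_sizes = c(2L, 4L), power = c(0.25, 0.75),
                       n_sims = 4L, significance = 0.05, method = "chi2",
                       alpha_tilde = list(c(a = 1, b = 2), c(a = 2, b = 1)),
                       seed = 1L),
                  class = "power_result")
  write_result(pw, jsn, "json")
  expect_equal(read_result(jsn), pw)

  g <- gof_test(filter_classes(normalize_composition(tab))$table,
                n_sims = 100, seed = 2)
  write_result(g, jsn, "json")
  expect_equal(read_result(jsn)$T_sim, g$T_sim)
  expect_true(any(grepl("100", utils::capture.output(print(g)))))

  expect_error(write_result(res, "/nonexistent-dir/x/y.json", "json"),
               "cannot write")
})
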