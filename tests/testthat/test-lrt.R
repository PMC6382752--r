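test_that("D is near zero when the environments hold identical samples", {
  set.seed(21)
  x <- rdirichlet(6, c(2, 5, 3))
  tab <- composition_table(rbind(x, x), paste0("s", 1:12),
                           c("A", "B", "C"),
                           rep(c("e1", "e2"), each = 6),
                           is_normalized = TRUE)
  st <- lrt_statistic(tab)
  expect_gte(st$D, 0)
  expect_lt(st$D, 1e-6)
  expect_gte(st$logL1, st$logL0 - 1e-9)
})

test_that("D is invariant under class, sample and label relabelings", {
  tab <- dir_table(2, 8, list(c(2, 5, 3, 1), c(4, 2, 3, 2)), seed = 31)
  D0 <- lrt_statistic(tab)$D

  perm <- c(3, 1, 4, 2)
  t2 <- composition_table(tab$values[, perm], tab$sample_ids,
                          tab$class_names[perm], tab$environments,
                          is_normalized = TRUE)
  expect_equal(lrt_statistic(t2)$D, D0, tolerance = 1e-9)

  # shuffle samples within environments
  ord <- c(sample(1:8), sample(9:16))
  t3 <- composition_table(tab$values[ord, ], tab$sample_ids[ord],
                          tab$class_names, tab$environments[ord],
                          is_normalized = TRUE)
  expect_equal(lrt_statistic(t3)$D, D0, tolerance = 1e-9)

  t4 <- tab
  t4$environments <- ifelse(tab$environments == "E1", "apple", "pear")
  expect_equal(lrt_statistic(t4)$D, D0, tolerance = 1e-12)
})

test_that("lrt_statistic enforces its preconditions", {
  tab <- dir_table(1, 6, list(c(2, 5, 3)), seed = 1)
  expect_error(lrt_statistic(tab), "2 environments")

  tab2 <- dir_table(2, 4, null_alphas(2, c(2, 5, 3)), seed = 2)
  tab2$environments[1:3] <- "E2"
  expect_error(lrt_statistic(tab2), "singleton|fewer than 2")
})

test_that("chi-squared p-value uses df = (m-1)K and the safe upper tail", {
  expect_equal(chi2_pvalue(0, 3, 5), 1)
  expect_equal(chi2_pvalue(stats::qchisq(0.95, df = 10), 3, 5), 0.05)
  # df for the 8-treatment, 8-class design is 56
  expect_equal(chi2_pvalue(1, 8, 8), stats::pchisq(1, 56, lower.tail = FALSE))
  # published-table reference: chi2(0.95, 10) = 18.31
  expect_equal(chi2_pvalue(18.31, 2, 10), 0.05, tolerance = 1e-3)
  # extreme statistics stay representable
  expect_gt(chi2_pvalue(1500, 2, 21), 0)
  expect_lt(chi2_pvalue(1500, 2, 21), 1e-280)
  expect_error(chi2_pvalue(-1, 2, 3), "non-negative")
  expect_error(chi2_pvalue(1, 1, 3), "m >= 2")
})

test_that("method recommendation follows the n versus mK rule", {
  expect_identical(recommend_method(354, 2, 21), "chi2")       # n >> mK
  expect_identical(recommend_method(12, 3, 9), "randomization") # n < mK
  expect_identical(recommend_method(2 * 2 * 5, 2, 5), "chi2")  # boundary
  expect_identical(recommend_method(2 * 2 * 5 - 1, 2, 5), "randomization")
})

test_that("exhaustive randomization equals the brute-force enumeration", {
  tab <- dir_table(2, 2, list(c(2, 6, 3), c(6, 2, 3)), seed = 101)
  ex <- randomization_pvalue(tab, exhaustive = TRUE)
  expect_identical(ex$n_trials, 6L)
  oracle <- oracle_perm_pvalue(tab)
  expect_identical(ex$p_rand, oracle$p)
  expect_gte(ex$p_rand, 1 / 6)  # the observed labeling is always counted

  # a larger design: 3 + 2 samples -> 10 distinct labelings
  tab2 <- dir_table(2, c(3, 2), list(c(2, 6, 3), c(6, 2, 3)), seed = 17)
  ex2 <- randomization_pvalue(tab2, exhaustive = TRUE)
  expect_identical(ex2$n_trials, 10L)
  expect_identical(ex2$p_rand, oracle_perm_pvalue(tab2)$p)
})

test_that("random-trial p-value converges to the enumeration proportion", {
  tab <- dir_table(2, 2, list(c(2, 6, 3), c(6, 2, 3)), seed = 101)
  exact <- randomization_pvalue(tab, exhaustive = TRUE)$p_rand
  set.seed(4)
  mc <- randomization_pvalue(tab, n_trials = 1500)
  expect_equal(mc$p_rand, exact, tolerance = 0.04)
})

test_that("zero exceedances are reported as a bound", {
  tab <- dir_table(2, 6, list(c(20, 5, 3), c(3, 5, 20)), seed = 55)
  set.seed(1)
  rp <- randomization_pvalue(tab, n_trials = 60)
  expect_identical(rp$n_exceed, 0L)
  expect_true(rp$is_bound)
  res <- dirichlet_lrt(tab, method = "randomization", n_trials = 60, seed = 1)
  out <- utils::capture.output(print(res))
  expect_true(any(grepl("< 0.0166", out)))
})

test_that("dirichlet_lrt orchestrates filtering, statistics and both p-values", {
  tab <- dir_table(2, 10, list(c(2, 5, 3), c(5, 2, 3)), seed = 61)
  res <- dirichlet_lrt(tab, method = "both", n_trials = 100, seed = 2)
  expect_s3_class(res, "lrt_result")
  expect_identical(res$method_used, "both")
  expect_false(is.null(res$p_chi2))
  expect_false(is.null(res$p_rand))
  expect_equal(res$D, -2 * (res$logL0 - res$logL1), tolerance = 1e-9)
  expect_identical(res$df, (res$m - 1L) * res$K)
  expect_equal(res$p_rand, res$n_exceed / res$n_rand_trials)
  expect_s3_class(res$filter_report, "filter_report")

  # auto routing: n = 20 >= 2*m*K = 12 -> chi2 only
  auto <- dirichlet_lrt(tab, method = "auto")
  expect_identical(auto$method_used, "chi2")
  expect_null(auto$p_rand)

  # auto routing the other way: n = 8 < 2*m*K
  small <- dir_table(2, 4, list(c(2, 5, 3, 1, 2), c(5, 2, 3, 1, 2)),
                     seed = 62)
  auto2 <- dirichlet_lrt(small, method = "auto", n_trials = 50, seed = 3)
  expect_identical(auto2$method_used, "randomization")
  expect_null(auto2$p_chi2)
})

test_that("counts and proportions give the same test result", {
  tab <- dir_table(2, 6, list(c(2, 5, 3), c(5, 2, 3)), seed = 71)
  counts <- tab
  counts$values <- counts$values * 1e4   # pseudo-counts, row sums 1e4
  counts$is_normalized <- FALSE
  expect_equal(dirichlet_lrt(counts, method = "chi2")$D,
               dirichlet_lrt(tab, method = "chi2")$D, tolerance = 1e-9)
})
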