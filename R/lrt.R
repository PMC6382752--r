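#' Likelihood-ratio statistic for composition differences
#'
#' Fits one pooled Dirichlet distribution to all samples (the null: every
#' environment shares the same composition distribution) and one Dirichlet
#' per environment (the alternative), and returns
#' \eqn{D = -2 \log(L_0/L_1) = 2(\log L_1 - \log L_0)}. Tiny negative
#' values of D from floating-point round-off (within 1e-9) are clamped
#' to 0; nesting guarantees the true value is non-negative.
#'
#' @param table a filtered, normalized [composition_table()] with at least
#'   two environments and at least two samples per environment, free of
#'   zero entries.
#' @return A list: `D`, `logL0`, `logL1`, `alpha_null` (pooled fit),
#'   `alpha_alt` (named list of per-environment fits), `m`, `K`, `n_i`.
#' @seealso [dirichlet_lrt()] for the full pipeline including p-values.
#' @export
lrt_statistic <- function(table) {
  validate_composition_table(table)
  if (!table$is_normalized)
    stop("lrt_statistic expects a normalized table", call. = FALSE)
  lev <- env_levels(table)
  if (length(lev) < 2)
    stop("need at least 2 environments, got ", length(lev), call. = FALSE)
  ns <- env_sizes(table)
  if (any(ns < 2))
    stop("likelihood unbounded for singleton groups; environment(s) with ",
         "fewer than 2 samples: ", paste(lev[ns < 2], collapse = ", "),
         call. = FALSE)
  if (any(table$values <= 0))
    stop("zero entries present; run filter_classes() first", call. = FALSE)

  groups <- split_by_env(table)

  fit0 <- fit_dirichlet(table$values)
  fits1 <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    fits1[[i]] <- tryCatch(
      fit_dirichlet(groups[[i]]),
      error = function(e) stop("fit failed for environment '", lev[i],
                               "': ", conditionMessage(e), call. = FALSE))
  }
  names(fits1) <- lev

  logL0 <- fit0$logLik
  logL1 <- sum(vapply(fits1, function(f) f$logLik, numeric(1)))
  D <- 2 * (logL1 - logL0)
  if (D < 0) {
    if (D > -1e-9) D <- 0
    else stop("negative likelihood-ratio statistic (", format(D),
              "): per-environment fits did not dominate the pooled fit; ",
              "tighten the fit tolerance", call. = FALSE)
  }
  list(D = D, logL0 = logL0, logL1 = logL1,
       alpha_null = fit0$alpha,
       alpha_alt = lapply(fits1, function(f) f$alpha),
       m = length(lev), K = ncol(table$values), n_i = unname(ns))
}

#' Chi-squared p-value for the likelihood-ratio statistic
#'
#' Upper tail of the chi-squared distribution with `(m - 1) * K` degrees
#' of freedom — the number of extra parameters under the alternative.
#' Computed with `lower.tail = FALSE`, which stays accurate for extreme
#' statistics (p-values down to ~1e-300 are representable).
#'
#' This asymptotic reference requires many samples relative to the
#' dimensionality; see [recommend_method()].
#'
#' @param D non-negative test statistic.
#' @param m number of environments (at least 2).
#' @param K number of classes after filtering (at least 2).
#' @return The upper-tail probability.
#' @export
chi2_pvalue <- function(D, m, K) {
  if (!is.numeric(D) || length(D) != 1 || is.na(D) || D < 0)
    stop("D must be a non-negative number", call. = FALSE)
  if (m < 2 || K < 2) stop("need m >= 2 and K >= 2", call. = FALSE)
  df <- (m - 1) * K
  stats::pchisq(D, df = df, lower.tail = FALSE)
}

# all distinct assignments of the multiset of labels to sample positions,
# as a list of character vectors; count is n! / prod(n_i!)
multiset_permutations <- function(labels, cap = 100000L) {
  counts <- table(labels)
  total <- exp(lgamma(length(labels) + 1) - sum(lgamma(counts + 1)))
  if (total > cap)
    stop("too many distinct labelings (", format(total),
         ") for exhaustive enumeration; use random trials", call. = FALSE)
  recurse <- function(remaining) {
    n <- sum(remaining)
    if (n == 0) return(list(character(0)))
    out <- list()
    for (lab in names(remaining)[remaining > 0]) {
      rem <- remaining
      rem[lab] <- rem[lab] - 1L
      for (tail in recurse(rem)) out[[length(out) + 1L]] <- c(lab, tail)
    }
    out
  }
  counts_int <- stats::setNames(as.integer(counts), names(counts))
  recurse(counts_int)
}

#' Randomization p-value for the likelihood-ratio test
#'
#' Builds an empirical null by permuting the environment labels across
#' samples (preserving the group sizes), recomputing D for each
#' permutation, and reporting the proportion of permuted statistics at
#' least as large as the observed one. This is the recommended reference
#' when the sample count is small relative to the dimensionality `m * K`.
#'
#' Ties are counted as exceedances (`>=`), the conservative choice; the
#' observed labeling is not included as a trial. When no permuted
#' statistic reaches `D`, the p-value is stored as 0 and reported as the
#' bound `p < 1/n_trials`. Permutations on which the Dirichlet fit fails
#' (degenerate resampled groups) are redrawn and counted.
#'
#' @param table a filtered, normalized [composition_table()] satisfying
#'   the [lrt_statistic()] preconditions.
#' @param n_trials number of random permutations (default 5000).
#' @param exhaustive enumerate every distinct labeling instead of
#'   sampling (only sensible for small designs; `n_trials` is ignored).
#' @param D_obs optionally supply the observed statistic to avoid
#'   refitting.
#' @return A list: `p_rand`, `n_exceed`, `n_trials`, `n_failed`,
#'   `is_bound` (`TRUE` when `n_exceed == 0` in random mode),
#'   `exhaustive`.
#' @export
randomization_pvalue <- function(table, n_trials = 5000, exhaustive = FALSE,
                                 D_obs = NULL) {
  if (!exhaustive && (!is.numeric(n_trials) || n_trials < 1))
    stop("n_trials must be at least 1", call. = FALSE)
  if (is.null(D_obs)) D_obs <- lrt_statistic(table)$D

  stat_for_labels <- function(labels) {
    t2 <- table
    t2$environments <- labels
    lrt_statistic(t2)$D
  }

  if (exhaustive) {
    perms <- multiset_permutations(table$environments)
    Ds <- vapply(perms, stat_for_labels, numeric(1))
    n_exceed <- sum(Ds >= D_obs)
    n_trials <- length(Ds)
    return(list(p_rand = n_exceed / n_trials, n_exceed = n_exceed,
                n_trials = n_trials, n_failed = 0L, is_bound = FALSE,
                exhaustive = TRUE))
  }

  n_trials <- as.integer(n_trials)
  n_exceed <- 0L
  n_failed <- 0L
  done <- 0L
  max_attempts <- 10L * n_trials
  attempts <- 0L
  while (done < n_trials) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("randomization: too many failed permutation fits (", n_failed,
           " failures in ", attempts, " attempts)", call. = FALSE)
    labels <- sample(table$environments)
    Dr <- tryCatch(stat_for_labels(labels), error = function(e) NA_real_)
    if (is.na(Dr)) { n_failed <- n_failed + 1L; next }
    done <- done + 1L
    if (Dr >= D_obs) n_exceed <- n_exceed + 1L
  }
  list(p_rand = n_exceed / n_trials, n_exceed = n_exceed,
       n_trials = n_trials, n_failed = n_failed,
       is_bound = n_exceed == 0L, exhaustive = FALSE)
}

#' Advise between the chi-squared and randomization references
#'
#' The chi-squared reference for D is asymptotic: it is trustworthy when
#' the total number of samples n is large relative to the dimensionality
#' `m * K`, and anti-conservative (too eager to reject) when n is small.
#' The rule implemented here recommends randomization whenever
#' `n_total < ratio * m * K` (boundary inclusive for chi-squared). This
#' is advisory only — an explicit user choice is never overridden.
#'
#' @param n_total total number of samples across environments.
#' @param m number of environments.
#' @param K number of (post-filter) classes.
#' @param ratio safety multiple on the dimensionality (default 2).
#' @return `"chi2"` or `"randomization"`.
#' @export
recommend_method <- function(n_total, m, K, ratio = 2) {
  if (n_total < 1 || m < 1 || K < 1 || ratio <= 0)
    stop("arguments must be positive", call. = FALSE)
  if (n_total < ratio * m * K) "randomization" else "chi2"
}

#' Dirichlet likelihood-ratio test for composition differences
#'
#' The full pipeline: normalize, apply the class-inclusion filter,
#' compute the likelihood-ratio statistic D comparing a single pooled
#' Dirichlet distribution against one Dirichlet per environment, and
#' attach p-values. With `method = "auto"` the chi-squared reference is
#' used when the sample count dominates the dimensionality and the
#' randomization reference otherwise (see [recommend_method()]);
#' `"both"` computes both.
#'
#' @param table a [composition_table()] (counts or proportions; it is
#'   normalized internally).
#' @param spec a [filter_spec()] with the class-inclusion rules.
#' @param method one of `"auto"`, `"chi2"`, `"randomization"`, `"both"`.
#' @param n_trials number of random permutations for the randomization
#'   reference (default 5000).
#' @param seed optional integer seed for the randomization draws.
#' @return An object of class `lrt_result` with the statistic `D`,
#'   degrees of freedom `df = (m - 1) * K`, p-values (`p_chi2`,
#'   `p_rand` as available), exceedance counts, fitted parameters under
#'   both hypotheses, the filter report, and the design geometry
#'   (`m`, `K`, `n_i`).
#' @export
#' @examples
#' sc <- scenario(m = 2, n_i = 8, alphas = list(c(2, 5, 3), c(5, 2, 3)),
#'                seed = 11)
#' tab <- generate_table(sc)
#' dirichlet_lrt(tab, method = "chi2")
dirichlet_lrt <- function(table, spec = filter_spec(),
                          method = c("auto", "chi2", "randomization", "both"),
                          n_trials = 5000, seed = NULL) {
  method <- match.arg(method)
  table <- normalize_composition(table)
  flt <- filter_classes(table, spec)
  tab <- flt$table

  st <- lrt_statistic(tab)
  if (method == "auto")
    method_used <- recommend_method(sum(st$n_i), st$m, st$K)
  else method_used <- method

  p_chi2 <- NULL
  p_rand <- NULL
  n_exceed <- NA_integer_
  n_rand_trials <- 0L
  rand_is_bound <- FALSE
  if (method_used %in% c("chi2", "both"))
    p_chi2 <- chi2_pvalue(st$D, st$m, st$K)
  if (method_used %in% c("randomization", "both")) {
    if (!is.null(seed)) set.seed(seed)
    rp <- randomization_pvalue(tab, n_trials = n_trials, D_obs = st$D)
    p_rand <- rp$p_rand
    n_exceed <- rp$n_exceed
    n_rand_trials <- rp$n_trials
    rand_is_bound <- rp$is_bound
  }

  structure(list(D = st$D,
                 df = (st$m - 1L) * st$K,
                 p_chi2 = p_chi2,
                 p_rand = p_rand,
                 rand_is_bound = rand_is_bound,
                 n_rand_trials = n_rand_trials,
                 n_exceed = n_exceed,
                 logL0 = st$logL0,
                 logL1 = st$logL1,
                 alpha_null = st$alpha_null,
                 alpha_alt = st$alpha_alt,
                 method_used = method_used,
                 m = st$m, K = st$K, n_i = st$n_i,
                 filter_report = flt$report,
                 seed = seed),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat("Dirichlet likelihood-ratio test\n")
  cat(sprintf("  design: m = %d environments, n_i = (%s), K = %d classes",
              x$m, paste(x$n_i, collapse = ", "), x$K),
      sprintf("(from %d before filtering)\n", x$filter_report$K_before))
  cat(sprintf("  D = %.4f on %d degrees of freedom\n", x$D, x$df))
  if (!is.null(x$p_chi2))
    cat(sprintf("  chi-squared p-value:   %.4g\n", x$p_chi2))
  if (!is.null(x$p_rand)) {
    if (x$rand_is_bound)
      cat(sprintf("  randomization p-value: < %.4g (%d trials, 0 exceedances)\n",
                  1 / x$n_rand_trials, x$n_rand_trials))
    else
      cat(sprintf("  randomization p-value: %.4g (%d of %d trials)\n",
                  x$p_rand, x$n_exceed, x$n_rand_trials))
  }
  cat("  method:", x$method_used,
      if (!is.null(x$seed)) sprintf("(seed %d)", x$seed) else "", "\n")
  invisible(x)
}
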