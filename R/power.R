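#' Estimate the power of a future experiment
#'
#' Assumes the per-environment Dirichlet parameters `alpha_tilde` are the
#' truth, simulates `n` compositions per environment, runs the
#' likelihood-ratio test on the simulated data, and records a success
#' when the p-value falls below `significance`. The proportion of
#' successes over `n_sims` simulations estimates the power of a future
#' experiment with `n` replicates per environment.
#'
#' Simulations in which the Dirichlet fit fails (degenerate resampled
#' data; rare) are redrawn and counted; if more than 10\% of draws fail
#' the estimate is abandoned with an error.
#'
#' Note: this procedure is computationally expensive, especially with
#' `method = "randomization"` (a full permutation test inside every
#' simulation).
#'
#' @param alpha_tilde list of m parameter vectors (m >= 2, equal
#'   lengths K), typically the per-environment fits to pilot data.
#' @param n replicates per environment in the future experiment (>= 2).
#' @param n_sims number of simulated experiments (default 500).
#' @param significance rejection level (default 0.05).
#' @param method inner p-value method, `"chi2"` (default) or
#'   `"randomization"`.
#' @param n_trials permutation count for the randomization inner test
#'   (default 200, deliberately reduced — the cost is quadratic).
#' @param seed optional integer seed; simulations are seeded per
#'   simulation index so runs with different `n` are paired.
#' @return The estimated power (a single proportion), with attributes
#'   `n_failed` (redraw count) and `n_sims`.
#' @export
power_estimate <- function(alpha_tilde, n, n_sims = 500,
                           significance = 0.05,
                           method = c("chi2", "randomization"),
                           n_trials = 200, seed = NULL) {
  method <- match.arg(method)
  if (!is.list(alpha_tilde) || length(alpha_tilde) < 2)
    stop("alpha_tilde must be a list of at least 2 parameter vectors",
         call. = FALSE)
  lapply(alpha_tilde, check_alpha)
  K <- unique(vapply(alpha_tilde, length, integer(1)))
  if (length(K) != 1)
    stop("all alpha_tilde vectors must have the same length", call. = FALSE)
  if (n < 2) stop("n must be at least 2 per environment", call. = FALSE)
  if (significance <= 0 || significance > 1)
    stop("significance must lie in (0, 1]", call. = FALSE)
  m <- length(alpha_tilde)

  successes <- 0L
  n_failed <- 0L
  for (s in seq_len(n_sims)) {
    if (!is.null(seed)) set.seed(sim_seed(seed, s))
    ok <- FALSE
    tries <- 0L
    while (!ok) {
      tries <- tries + 1L
      if (n_failed > 0.1 * n_sims && tries > 1L)
        stop("more than 10% of simulated experiments failed to fit",
             call. = FALSE)
      tab <- simulate_experiment(alpha_tilde, n)
      p <- tryCatch({
        st <- lrt_statistic(tab)
        if (method == "chi2") chi2_pvalue(st$D, st$m, st$K)
        else randomization_pvalue(tab, n_trials = n_trials,
                                  D_obs = st$D)$p_rand
      }, error = function(e) NA_real_)
      if (is.na(p)) { n_failed <- n_failed + 1L; next }
      ok <- TRUE
      if (p < significance) successes <- successes + 1L
    }
  }
  structure(successes / n_sims, n_failed = n_failed, n_sims = n_sims)
}

# deterministic per-simulation sub-seed below 2^31, shared across group
# sizes so power curves use common random numbers
sim_seed <- function(seed, s) {
  (as.integer(seed) %% 1000003L) * 2011L + s * 7919L
}

simulate_experiment <- function(alpha_tilde, n) {
  m <- length(alpha_tilde)
  K <- length(alpha_tilde[[1]])
  vals <- do.call(rbind, lapply(alpha_tilde, function(a) rdirichlet(n, a)))
  composition_table(vals,
                    sample_ids = paste0("sim", seq_len(m * n)),
                    class_names = paste0("C", seq_len(K)),
                    environments = rep(paste0("E", seq_len(m)), each = n),
                    is_normalized = TRUE)
}

#' Power curve over candidate group sizes
#'
#' Fits the per-environment (alternative) Dirichlet model to observed
#' pilot data — normalized and class-filtered first — and calls
#' [power_estimate()] for every group size in `n_range` using paired
#' simulation seeds, so the curve is monotone up to Monte-Carlo noise.
#'
#' @param table a [composition_table()] of pilot data.
#' @param spec a [filter_spec()].
#' @param n_range integer vector of per-environment group sizes.
#' @param n_sims,significance,method,n_trials,seed passed to
#'   [power_estimate()].
#' @return An object of class `power_result`: `group_sizes`, `power`,
#'   `n_sims`, `significance`, `method`, `alpha_tilde`.
#' @export
power_curve <- function(table, spec = filter_spec(), n_range,
                        n_sims = 500, significance = 0.05,
                        method = c("chi2", "randomization"),
                        n_trials = 200, seed = NULL) {
  method <- match.arg(method)
  if (length(n_range) == 0) stop("n_range must be non-empty", call. = FALSE)
  table <- normalize_composition(table)
  tab <- filter_classes(table, spec)$table
  lev <- env_levels(tab)
  groups <- split_by_env(tab)
  alpha_tilde <- lapply(groups, function(g) fit_dirichlet(g)$alpha)
  names(alpha_tilde) <- lev

  pw <- vapply(n_range, function(n)
    as.numeric(power_estimate(alpha_tilde, n, n_sims = n_sims,
                              significance = significance, method = method,
                              n_trials = n_trials, seed = seed)),
    numeric(1))
  structure(list(group_sizes = as.integer(n_range),
                 power = pw,
                 n_sims = as.integer(n_sims),
                 significance = significance,
                 method = method,
                 alpha_tilde = alpha_tilde,
                 seed = seed),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat("Power estimates (Dirichlet likelihood-ratio test)\n")
  cat(sprintf("  significance %.3g, %d simulations per group size, %s method\n",
              x$significance, x$n_sims, x$method))
  df <- data.frame(n_per_group = x$group_sizes, power = x$power)
  print(df, row.names = FALSE)
  invisible(x)
}
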