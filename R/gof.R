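#' Simulation-based goodness-of-fit test for the Dirichlet model
#'
#' The significance test assumes each environment's compositions are
#' Dirichlet distributed. This check compares the log-likelihood of the
#' fitted parameters on the observed data, T0, with the log-likelihoods
#' T_j of the *same* parameters on `n_sims` datasets simulated from them
#' with identical geometry (same K, m and per-environment sample counts).
#' The p-value is the proportion of T_j strictly below T0: if the model
#' fits poorly, the observed data are unusually unlikely under it and T0
#' falls in the lower tail. Small p-values therefore indicate misfit.
#'
#' The parameters are fitted once, on the observed data, and reused for
#' every simulated dataset — there is no per-simulation refit.
#'
#' @param table a filtered, normalized [composition_table()] with no zero
#'   entries and at least two samples per environment.
#' @param model `"alt"` (default) fits one Dirichlet per environment —
#'   the model the significance test actually uses when a difference is
#'   found; `"null"` fits a single pooled Dirichlet.
#' @param n_sims number of simulated datasets (default 10000; at least
#'   100).
#' @param seed optional integer seed.
#' @param params optional list of parameter vectors (one per environment
#'   for `"alt"`, a single-element list for `"null"`) to use instead of
#'   fitting — mainly for calibration studies.
#' @return An object of class `gof_result`: `T0`, `T_sim`, `p_gof`,
#'   `n_sims`, `model_used`.
#' @export
gof_test <- function(table, model = c("alt", "null"), n_sims = 10000,
                     seed = NULL, params = NULL) {
  model <- match.arg(model)
  validate_composition_table(table)
  if (!table$is_normalized)
    stop("gof_test expects a normalized table", call. = FALSE)
  if (any(table$values <= 0))
    stop("zero entries present; run filter_classes() first", call. = FALSE)
  if (!is.numeric(n_sims) || n_sims < 100)
    stop("n_sims must be at least 100", call. = FALSE)
  n_sims <- as.integer(n_sims)
  ns <- env_sizes(table)
  if (any(ns < 2))
    stop("every environment needs at least 2 samples", call. = FALSE)

  groups <- split_by_env(table)
  if (model == "null") {
    groups <- list(table$values)
    ns <- nrow(table$values)
  }
  if (is.null(params)) {
    params <- lapply(groups, function(g) fit_dirichlet(g)$alpha)
  } else {
    if (!is.list(params) || length(params) != length(groups))
      stop("params must supply one alpha vector per fitted group",
           call. = FALSE)
    lapply(params, check_alpha)
  }

  T0 <- dirichlet_loglik(groups, params)

  if (!is.null(seed)) set.seed(seed)
  # sufficient-statistic evaluation keeps the simulation loop cheap
  T_sim <- numeric(n_sims)
  for (j in seq_len(n_sims)) {
    tj <- 0
    for (i in seq_along(groups)) {
      y <- rdirichlet(ns[i], params[[i]])
      tj <- tj + .dir_loglik_suff(colSums(log(y)), ns[i], params[[i]])
    }
    T_sim[j] <- tj
  }
  p_gof <- sum(T_sim < T0) / n_sims

  structure(list(T0 = T0, T_sim = T_sim, p_gof = p_gof, n_sims = n_sims,
                 model_used = if (model == "alt") "alt_fit" else "null_fit",
                 alpha = params, seed = seed),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat("Dirichlet goodness-of-fit (parametric simulation)\n")
  cat(sprintf("  model: %s; simulations: %d\n", x$model_used, x$n_sims))
  cat(sprintf("  T0 = %.4f\n", x$T0))
  cat(sprintf("  p = %.4g  (small p indicates poor fit)\n", x$p_gof))
  invisible(x)
}
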