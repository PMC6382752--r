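# independent oracles used to cross-check the analytic implementations;
# deliberately share no code with the package's fitting path

# generic numerical maximizer of the one-group Dirichlet log-likelihood
# over log(alpha) with analytic gradient; multi-start BFGS
oracle_max_loglik <- function(x, starts = NULL) {
  S <- colSums(log(x))
  n <- nrow(x)
  K <- ncol(x)
  nll <- function(la) {
    a <- exp(la)
    n * (sum(lgamma(a)) - lgamma(sum(a))) - sum((a - 1) * S)
  }
  gr <- function(la) {
    a <- exp(la)
    (n * (digamma(a) - digamma(sum(a))) - S) * a
  }
  if (is.null(starts))
    starts <- list(rep(1, K), rep(5, K), colMeans(x) * 10)
  best <- list(value = Inf)
  for (s in starts) {
    o <- stats::optim(log(s), nll, gr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
    if (o$value < best$value) best <- o
  }
  list(logLik = -best$value, alpha = exp(best$par))
}

# oracle for the likelihood-ratio statistic: direct maximization under
# both hypotheses with the optimizer above
oracle_lrt_D <- function(table) {
  groups <- lapply(unique(table$environments), function(e)
    table$values[table$environments == e, , drop = FALSE])
  l0 <- oracle_max_loglik(table$values)$logLik
  l1 <- sum(vapply(groups, function(g) oracle_max_loglik(g)$logLik,
                   numeric(1)))
  2 * (l1 - l0)
}

# dense 2-parameter grid with repeated zoom refinement (K = 2 only)
oracle_grid2_loglik <- function(x, lo = c(0.05, 0.05), hi = c(60, 60),
                                rounds = 8, pts = 61) {
  stopifnot(ncol(x) == 2)
  S <- colSums(log(x))
  n <- nrow(x)
  ll <- function(a1, a2)
    -n * (lgamma(a1) + lgamma(a2) - lgamma(a1 + a2)) +
      (a1 - 1) * S[1] + (a2 - 1) * S[2]
  a <- c(NA, NA)
  for (r in seq_len(rounds)) {
    g1 <- seq(lo[1], hi[1], length.out = pts)
    g2 <- seq(lo[2], hi[2], length.out = pts)
    M <- outer(g1, g2, ll)
    idx <- which(M == max(M), arr.ind = TRUE)[1, ]
    a <- c(g1[idx[1]], g2[idx[2]])
    w <- c(g1[2] - g1[1], g2[2] - g2[1])
    lo <- pmax(a - 2 * w, 1e-4)
    hi <- a + 2 * w
  }
  list(alpha = a, logLik = ll(a[1], a[2]))
}

# brute-force permutation p-value for a 2-environment design: enumerate
# every choice of which samples carry the first label
oracle_perm_pvalue <- function(table) {
  labs <- table$environments
  lev <- unique(labs)
  stopifnot(length(lev) == 2)
  n <- length(labs)
  n1 <- sum(labs == lev[1])
  D_obs <- lrt_statistic(table)$D
  picks <- utils::combn(n, n1)
  Ds <- apply(picks, 2, function(ix) {
    t2 <- table
    l <- rep(lev[2], n)
    l[ix] <- lev[1]
    t2$environments <- l
    lrt_statistic(t2)$D
  })
  list(p = mean(Ds >= D_obs), n_perm = ncol(picks), Ds = Ds)
}
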