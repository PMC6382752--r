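# shared fixtures built in code

# small raw-count table used across the io/preprocess tests: the rows sum
# to 100 so the normalized proportions are easy to read off
toy_counts <- function() {
  v <- rbind(s1 = c(A = 50, B = 30, C = 0.5, D = 0, E = 19.5),
             s2 = c(A = 60, B = 30, C = 0.4, D = 5, E = 4.6),
             s3 = c(A = 55, B = 30, C = 0.6, D = 5, E = 9.4))
  composition_table(v, rownames(v), colnames(v),
                    c("winter", "spring", "summer"))
}

# seeded Dirichlet table with m environments of n samples each
dir_table <- function(m, n, alphas, seed, ...) {
  generate_table(scenario(m = m, n_i = n, alphas = alphas, seed = seed, ...))
}

null_alphas <- function(m, alpha = c(2, 5, 3, 4, 1.5)) rep(list(alpha), m)

write_toy_csv <- function(path) {
  writeLines(c("sample_id,environment,A,B,C",
               "s1,winter,50,30,20",
               "s2,winter,40,40,20",
               "s3,summer,45,30,25"), path)
  path
}

env_sizes_for_test <- function(tab)
  vapply(unique(tab$environments),
         function(e) sum(tab$environments == e), integer(1),
         USE.NAMES = FALSE)

per_env_alpha_hat <- function(table) {
  groups <- lapply(unique(table$environments), function(e)
    table$values[table$environments == e, , drop = FALSE])
  lapply(groups, function(g) fit_dirichlet(g)$alpha)
}
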