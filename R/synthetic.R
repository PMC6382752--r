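#' Define a synthetic-data scenario
#'
#' A scenario states a known Dirichlet world: m environments, per-
#' environment sample counts, one parameter vector per environment
#' (identical vectors give a null scenario), and a seed. Two optional
#' stress features exist for testing the rest of the package:
#' `contamination` makes each sample a draw from a two-component Dirichlet
#' mixture (violating the single-Dirichlet model, for goodness-of-fit
#' misfit studies), and `rare_class_spec` splices in low-abundance and/or
#' zero-bearing classes (for exercising the class-inclusion filter).
#'
#' @param m number of environments.
#' @param n_i per-environment sample counts; a single value is recycled.
#' @param alphas list of m strictly positive parameter vectors, all of
#'   the same length K > 2.
#' @param seed integer seed; generation is deterministic given the
#'   scenario.
#' @param contamination optional list with elements `alphas2` (list of m
#'   parameter vectors for the second mixture component) and `weight`
#'   (probability of drawing from the second component, default 0.5).
#' @param rare_class_spec optional list of entries, each a list with
#'   `name`, `max_prop` (the class's maximum proportion across samples)
#'   and optional `zero_in` (indices of samples where the class is 0).
#' @return An object of class `scenario`.
#' @export
scenario <- function(m, n_i, alphas, seed, contamination = NULL,
                     rare_class_spec = NULL) {
  if (m < 1) stop("m must be at least 1", call. = FALSE)
  if (length(n_i) == 1) n_i <- rep(n_i, m)
  if (length(n_i) != m) stop("n_i must have length 1 or m", call. = FALSE)
  if (any(n_i < 1)) stop("n_i must be positive", call. = FALSE)
  if (!is.list(alphas) || length(alphas) != m)
    stop("alphas must be a list of m parameter vectors", call. = FALSE)
  lapply(alphas, check_alpha)
  K <- unique(vapply(alphas, length, integer(1)))
  if (length(K) != 1 || K <= 2)
    stop("all alpha vectors must share one length K > 2", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  if (!is.null(contamination)) {
    if (!is.list(contamination$alphas2) ||
        length(contamination$alphas2) != m)
      stop("contamination$alphas2 must be a list of m parameter vectors",
           call. = FALSE)
    lapply(contamination$alphas2, check_alpha)
    contamination$weight <- contamination$weight %||% 0.5
    if (contamination$weight <= 0 || contamination$weight >= 1)
      stop("contamination$weight must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(rare_class_spec)) {
    for (rc in rare_class_spec) {
      if (is.null(rc$name) || is.null(rc$max_prop) || rc$max_prop <= 0 ||
          rc$max_prop >= 1)
        stop("each rare_class_spec entry needs a name and max_prop in (0,1)",
             call. = FALSE)
    }
  }
  structure(list(m = as.integer(m), n_i = as.integer(n_i), alphas = alphas,
                 seed = as.integer(seed), contamination = contamination,
                 rare_class_spec = rare_class_spec),
            class = "scenario")
}

#' Generate a composition table from a scenario
#'
#' Draws `n_i[i]` compositions from Dirichlet(`alphas[[i]]`) for each
#' environment (or from the stated mixture under contamination), splices
#' in any rare classes at their stated proportions with zeros at the
#' stated sample positions, renormalizes rows, and returns a normalized
#' [composition_table()]. Deterministic given the scenario seed.
#'
#' @param sc a [scenario()].
#' @return A normalized [composition_table()] with sample ids `E<i>_s<j>`,
#'   environments `E1..Em` (or the names of `alphas`), and class names
#'   `C1..CK` (or the names of the first alpha vector).
#' @export
generate_table <- function(sc) {
  if (!inherits(sc, "scenario")) stop("sc must be a scenario", call. = FALSE)
  set.seed(sc$seed)
  K <- length(sc$alphas[[1]])
  env_names <- names(sc$alphas) %||% paste0("E", seq_len(sc$m))
  class_names <- names(sc$alphas[[1]]) %||% paste0("C", seq_len(K))

  rows <- vector("list", sc$m)
  for (i in seq_len(sc$m)) {
    n <- sc$n_i[i]
    if (is.null(sc$contamination)) {
      rows[[i]] <- rdirichlet(n, sc$alphas[[i]])
    } else {
      pick <- stats::runif(n) < sc$contamination$weight
      x <- rdirichlet(n, sc$alphas[[i]])
      if (any(pick))
        x[pick, ] <- rdirichlet(sum(pick), sc$contamination$alphas2[[i]])
      rows[[i]] <- x
    }
  }
  vals <- do.call(rbind, rows)
  n_total <- nrow(vals)

  if (!is.null(sc$rare_class_spec)) {
    for (rc in sc$rare_class_spec) {
      col <- stats::runif(n_total, min = 0.1, max = 1) * rc$max_prop
      col[which.max(col)] <- rc$max_prop   # the stated maximum is attained
      if (!is.null(rc$zero_in)) col[rc$zero_in] <- 0
      vals <- cbind(vals, col)
      class_names <- c(class_names, rc$name)
    }
    vals <- vals / rowSums(vals)
  }

  envs <- rep(env_names, times = sc$n_i)
  ids <- unlist(lapply(seq_len(sc$m), function(i)
    paste0(env_names[i], "_s", seq_len(sc$n_i[i]))))
  composition_table(vals, ids, class_names, envs, is_normalized = TRUE)
}

#' Scenarios with the geometries of published ARG/microbiome studies
#'
#' Returns scenarios whose shapes (m environments, per-environment sample
#' counts, K classes) mimic dataset geometries that arise in practice in
#' resistome and microbiome surveys: an 8-treatment soil ARG design
#' (m=8, n_i=3, K=8), the matching soil community design with one sample
#' missing (K=12), a 3-season ARG pilot (m=3, n_i=4, K=9) and its
#' community counterpart (K=5), and a large 2-site rhizosphere survey
#' (n_i = 226 and 128, K=21). The alpha values are synthetic
#' placeholders — no attempt is made to imitate any real dataset's fitted
#' parameters — so these are geometry fixtures, nothing more.
#'
#' @param seed base seed; each scenario offsets it deterministically.
#' @return Named list of [scenario()] objects.
#' @export
survey_geometries <- function(seed = 1) {
  mk_alpha <- function(K, shift = 0) {
    # smoothly varying, moderately concentrated synthetic parameters
    a <- 0.5 + 4 * abs(sin(seq_len(K) + shift))
    names(a) <- paste0("C", seq_len(K))
    a
  }
  geoms <- list(
    soil_arg       = list(m = 8, n_i = 3, K = 8),
    soil_bacteria  = list(m = 8, n_i = c(3, 3, 3, 3, 3, 3, 3, 2), K = 12),
    pilot_arg      = list(m = 3, n_i = 4, K = 9),
    pilot_bacteria = list(m = 3, n_i = 4, K = 5),
    rhizosphere    = list(m = 2, n_i = c(226, 128), K = 21))
  out <- vector("list", length(geoms))
  names(out) <- names(geoms)
  for (i in seq_along(geoms)) {
    g <- geoms[[i]]
    alphas <- lapply(seq_len(g$m), function(j) mk_alpha(g$K, shift = j / 3))
    out[[i]] <- scenario(m = g$m, n_i = g$n_i, alphas = alphas,
                         seed = seed + i)
  }
  out
}

#' Serialize / deserialize a scenario as JSON
#'
#' Round-trips every field at full precision so scenario configs can be
#' checked into a pipeline and replayed (`generate_table()` on the
#' deserialized scenario reproduces the same table byte-for-byte).
#'
#' @param sc a [scenario()].
#' @param path file path.
#' @export
write_scenario <- function(sc, path) {
  if (!inherits(sc, "scenario")) stop("sc must be a scenario", call. = FALSE)
  payload <- unclass(sc)
  # parameter vectors go out as JSON objects so class names survive
  payload$alphas <- lapply(payload$alphas, as.list)
  if (!is.null(payload$contamination))
    payload$contamination$alphas2 <-
      lapply(payload$contamination$alphas2, as.list)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  relist_alpha <- function(a) lapply(a, .named_num)
  contamination <- NULL
  if (!is.null(x$contamination))
    contamination <- list(alphas2 = relist_alpha(x$contamination$alphas2),
                          weight = .num1(x$contamination$weight))
  rare <- NULL
  if (!is.null(x$rare_class_spec) && length(x$rare_class_spec))
    rare <- lapply(x$rare_class_spec, function(rc)
      list(name = .chr1(rc$name), max_prop = .num1(rc$max_prop),
           zero_in = if (length(rc$zero_in))
             as.integer(unlist(rc$zero_in)) else NULL))
  scenario(m = .int1(x$m), n_i = as.integer(unlist(x$n_i)),
           alphas = relist_alpha(x$alphas), seed = .int1(x$seed),
           contamination = contamination, rare_class_spec = rare)
}
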