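#' Class-inclusion filter settings
#'
#' The Dirichlet likelihood is zero whenever any retained class has a zero
#' proportion in any sample, and low-abundance classes add degrees of
#' freedom without adding much information. The filter therefore keeps a
#' class only if it is ever-present (strictly positive in every sample,
#' unless disabled) AND reaches `min_proportion` in at least one sample;
#' everything else is pooled into an aggregate class (default label
#' `"LRT other"`). If the aggregate itself still contains a zero it is
#' deleted and the rows renormalized.
#'
#' @param min_proportion minimum proportion threshold in `[0, 1)`. The
#'   conventional field choice for compositional metagenomics is 0.01
#'   (1\%); the default is 0, i.e. no threshold.
#' @param require_ever_present logical, default `TRUE`.
#' @param other_label name for the aggregate class.
#' @param zero_replacement optional small positive value (at most 1e-6;
#'   about 1e-16 is typical). When set, zeros are replaced by this value
#'   instead of filtering on ever-presence — an escape hatch whose results
#'   should be quoted with extreme caution.
#' @return An object of class `filter_spec`.
#' @seealso [filter_classes()], [replace_zeros()]
#' @export
filter_spec <- function(min_proportion = 0, require_ever_present = TRUE,
                        other_label = "LRT other", zero_replacement = NULL) {
  if (!is.numeric(min_proportion) || length(min_proportion) != 1 ||
      is.na(min_proportion) || min_proportion < 0 || min_proportion >= 1)
    stop("min_proportion must be in [0, 1)", call. = FALSE)
  if (!is.null(zero_replacement)) {
    if (!is.numeric(zero_replacement) || length(zero_replacement) != 1 ||
        is.na(zero_replacement) || zero_replacement <= 0 ||
        zero_replacement > 1e-6)
      stop("zero_replacement must lie in (0, 1e-6]", call. = FALSE)
  }
  structure(list(min_proportion = min_proportion,
                 require_ever_present = isTRUE(require_ever_present),
                 other_label = as.character(other_label),
                 zero_replacement = zero_replacement),
            class = "filter_spec")
}

#' Apply the class-inclusion rules
#'
#' Splits classes into kept and aggregated according to the
#' [filter_spec()]: a class is kept iff it is ever-present (when required)
#' and its maximum proportion across all samples (all environments pooled)
#' reaches `min_proportion`. Aggregated classes are summed column-wise
#' into the `other_label` class; if that aggregate is empty or still
#' carries a zero in some sample it is dropped and every row renormalized
#' so compositions again sum to 1.
#'
#' When `zero_replacement` is set in the spec, [replace_zeros()] is
#' applied first and the ever-present requirement is skipped (the whole
#' point of zero replacement is to retain zero-bearing classes); the
#' minimum-proportion rule still applies.
#'
#' @param table a normalized [composition_table()].
#' @param spec a [filter_spec()].
#' @return A list with elements `table` (the filtered, renormalized
#'   composition table, free of zero entries) and `report` (a
#'   `filter_report`: `kept_classes`, `aggregated_classes`,
#'   `other_dropped`, `K_before`, `K_after`).
#' @export
filter_classes <- function(table, spec = filter_spec()) {
  validate_composition_table(table)
  if (!table$is_normalized)
    stop("filter_classes expects a normalized table; ",
         "call normalize_composition() first", call. = FALSE)
  if (!inherits(spec, "filter_spec")) stop("spec must be a filter_spec")

  if (!is.null(spec$zero_replacement)) {
    table <- replace_zeros(table, spec$zero_replacement)
    ever_ok <- rep(TRUE, ncol(table$values))
  } else if (spec$require_ever_present) {
    ever_ok <- apply(table$values > 0, 2, all)
  } else {
    ever_ok <- rep(TRUE, ncol(table$values))
  }

  v <- table$values
  K_before <- ncol(v)
  max_prop <- apply(v, 2, max)
  keep <- ever_ok & (max_prop >= spec$min_proportion)

  if (!any(keep))
    stop("no class passes the inclusion rules; all would be aggregated",
         call. = FALSE)

  kept_classes <- table$class_names[keep]
  aggregated_classes <- table$class_names[!keep]

  out <- v[, keep, drop = FALSE]
  other_dropped <- TRUE
  if (length(aggregated_classes) > 0) {
    other <- rowSums(v[, !keep, drop = FALSE])
    if (all(other > 0)) {
      out <- cbind(out, other)
      colnames(out)[ncol(out)] <- spec$other_label
      other_dropped <- FALSE
    }
  }
  if (other_dropped) out <- out / rowSums(out)

  K_after <- ncol(out)
  if (K_after < 3)
    stop("only ", K_after, " class(es) survive filtering; the Dirichlet ",
         "test needs more than 2 classes", call. = FALSE)

  res <- composition_table(out, table$sample_ids, colnames(out),
                           table$environments, is_normalized = TRUE)
  report <- structure(list(kept_classes = kept_classes,
                           aggregated_classes = aggregated_classes,
                           other_dropped = other_dropped,
                           other_label = spec$other_label,
                           K_before = K_before,
                           K_after = K_after),
                      class = "filter_report")
  list(table = res, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: K %d -> %d\n", x$K_before, x$K_after))
  cat("  kept:", paste(x$kept_classes, collapse = ", "), "\n")
  if (length(x$aggregated_classes))
    cat(sprintf("  aggregated into '%s'%s: %s\n", x$other_label,
                if (x$other_dropped) " (then dropped, rows renormalized)"
                else "",
                paste(x$aggregated_classes, collapse = ", ")))
  invisible(x)
}

#' Replace zero proportions by a small constant
#'
#' Sets every zero entry to `epsilon` and renormalizes each row to sum
#' to 1. This keeps zero-bearing classes in the analysis, but places
#' extreme mass at the boundary of the simplex: results from tests
#' exercising this option should be quoted with extreme caution (a
#' warning is raised to that effect whenever zeros were actually
#' replaced).
#'
#' @param table a normalized [composition_table()].
#' @param epsilon small positive replacement value, typically about 1e-16.
#' @return The table with zeros replaced and rows renormalized.
#' @export
replace_zeros <- function(table, epsilon = 1e-16) {
  validate_composition_table(table)
  if (!table$is_normalized)
    stop("replace_zeros expects a normalized table", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1 || is.na(epsilon) ||
      epsilon <= 0)
    stop("epsilon must be a positive number", call. = FALSE)
  v <- table$values
  nz <- sum(v == 0)
  if (nz > 0) {
    v[v == 0] <- epsilon
    v <- v / rowSums(v)
    warning(nz, " zero(s) replaced by ", format(epsilon),
            "; results from tests exercising this option should be ",
            "quoted with extreme caution", call. = FALSE)
  }
  table$values <- v
  table
}
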