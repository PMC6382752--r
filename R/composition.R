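#' Construct a composition table
#'
#' A composition table holds a samples-by-classes matrix of non-negative
#' abundances or proportions, together with one environment (treatment,
#' site, season, ...) label per sample. It is the container every
#' statistical function in this package operates on: rows are samples,
#' columns are classes (e.g. ARG drug classes or bacterial phyla).
#'
#' @param values numeric matrix or data frame, one row per sample and one
#'   column per class; all entries must be non-negative and finite.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   row of `values`.
#' @param class_names character vector of unique class labels, one per
#'   column of `values`.
#' @param environments character vector of environment labels, one per
#'   sample. Labels are compared as exact strings after trimming
#'   surrounding whitespace.
#' @param is_normalized logical; set to `TRUE` only when every row of
#'   `values` sums to 1 (checked to within 1e-9). Use
#'   [normalize_composition()] rather than setting this by hand.
#'
#' @return An object of class `composition_table`: a list with elements
#'   `values`, `sample_ids`, `class_names`, `environments`,
#'   `is_normalized`.
#' @seealso [read_composition()], [normalize_composition()],
#'   [filter_classes()], [dirichlet_lrt()]
#' @export
#' @examples
#' v <- rbind(c(50, 30, 20), c(40, 40, 20), c(45, 35, 20), c(55, 25, 20))
#' tab <- composition_table(v, paste0("s", 1:4), c("A", "B", "C"),
#'                          c("ctrl", "ctrl", "trt", "trt"))
#' normalize_composition(tab)
composition_table <- function(values, sample_ids, class_names, environments,
                              is_normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sample_ids <- trimws(as.character(sample_ids))
  class_names <- trimws(as.character(class_names))
  environments <- trimws(as.character(environments))
  rownames(values) <- sample_ids
  colnames(values) <- class_names
  obj <- structure(
    list(values = values,
         sample_ids = sample_ids,
         class_names = class_names,
         environments = environments,
         is_normalized = isTRUE(is_normalized)),
    class = "composition_table")
  validate_composition_table(obj)
  obj
}

validate_composition_table <- function(x) {
  stopifnot(inherits(x, "composition_table"))
  v <- x$values
  if (nrow(v) == 0L || ncol(v) == 0L)
    stop("empty composition table: need at least one sample and one class",
         call. = FALSE)
  if (length(x$sample_ids) != nrow(v))
    stop("number of sample_ids does not match number of rows", call. = FALSE)
  if (length(x$class_names) != ncol(v))
    stop("number of class_names does not match number of columns",
         call. = FALSE)
  if (anyDuplicated(x$sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(x$sample_ids[duplicated(x$sample_ids)]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(x$class_names))
    stop("duplicate class names: ",
         paste(unique(x$class_names[duplicated(x$class_names)]),
               collapse = ", "), call. = FALSE)
  if (length(x$environments) != nrow(v))
    stop("need one environment label per sample", call. = FALSE)
  if (any(!is.finite(v)))
    stop("non-finite values in composition table", call. = FALSE)
  if (any(v < 0)) {
    idx <- which(v < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value %g in sample '%s', class '%s'",
                 v[idx[1], idx[2]], x$sample_ids[idx[1]],
                 x$class_names[idx[2]]), call. = FALSE)
  }
  if (any(is.na(x$environments)) || any(x$environments == ""))
    stop("missing environment label for sample(s): ",
         paste(x$sample_ids[is.na(x$environments) | x$environments == ""],
               collapse = ", "), call. = FALSE)
  if (x$is_normalized && any(abs(rowSums(v) - 1) > 1e-9))
    stop("table flagged normalized but row sums deviate from 1",
         call. = FALSE)
  invisible(x)
}

#' @export
print.composition_table <- function(x, ...) {
  ns <- table(x$environments)
  cat(sprintf("composition_table: %d samples x %d classes, %d environment(s)\n",
              nrow(x$values), ncol(x$values), length(ns)))
  cat("  environments:",
      paste(sprintf("%s (n=%d)", names(ns), as.integer(ns)), collapse = ", "),
      "\n")
  cat("  classes:", paste(utils::head(x$class_names, 8), collapse = ", "),
      if (length(x$class_names) > 8) "..." else "", "\n")
  cat("  normalized:", x$is_normalized, "\n")
  invisible(x)
}

# number of distinct environments / per-group sizes, in order of first
# appearance (the order used for alpha_alt, n_i reporting, etc.)
env_levels <- function(table) unique(table$environments)

env_sizes <- function(table) {
  lev <- env_levels(table)
  vapply(lev, function(e) sum(table$environments == e), integer(1))
}

# list of per-environment row-submatrices, in env_levels() order
split_by_env <- function(table) {
  lev <- env_levels(table)
  lapply(lev, function(e) table$values[table$environments == e, ,
                                       drop = FALSE])
}

#' Normalize a composition table to proportions
#'
#' Divides every row by its own sum so each sample becomes a point on the
#' simplex (x_k = y_k / y_0). Idempotent, and invariant to rescaling any
#' raw row by a positive constant.
#'
#' @param table a [composition_table()].
#' @return The table with every row summing to 1 and `is_normalized = TRUE`.
#' @export
normalize_composition <- function(table) {
  validate_composition_table(table)
  rs <- rowSums(table$values)
  if (any(rs <= 0))
    stop("cannot normalize: all-zero row for sample(s) ",
         paste(table$sample_ids[rs <= 0], collapse = ", "), call. = FALSE)
  table$values <- table$values / rs
  table$is_normalized <- TRUE
  table
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a composition table from CSV/TSV
#'
#' Reads a sample-by-class table plus an environment label per sample.
#' The environment may come from a designated column of the data file or
#' from a separate two-column metadata file (sample_id, environment).
#' The delimiter is auto-detected from the extension (`.tsv` means tab,
#' anything else comma) and can be overridden with `sep`.
#'
#' @param path path to the data file.
#' @param dialect `"samples-as-rows"` (default; rows are samples, columns
#'   are classes) or `"samples-as-columns"` (the transpose: first column
#'   holds class names, remaining columns are samples).
#' @param env_column name of the column (after transposition, if any)
#'   holding the environment label. Ignored when `metadata` is supplied.
#' @param metadata optional path to a two-column delimited file mapping
#'   sample id to environment.
#' @param sep field delimiter override.
#' @param id_column name of the column holding sample ids. Default looks
#'   for a column named `sample_id`; if absent, row order ids `S1..Sn`
#'   are generated.
#' @return An un-normalized [composition_table()] preserving the input
#'   class order.
#' @export
read_composition <- function(path,
                             dialect = c("samples-as-rows",
                                         "samples-as-columns"),
                             env_column = "environment",
                             metadata = NULL,
                             sep = NULL,
                             id_column = "sample_id") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- sep %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) == 0L)
    stop("empty table in ", path, call. = FALSE)

  if (dialect == "samples-as-columns") {
    # first column = class (or metadata-row) names; remaining columns are
    # samples.  Transpose into the samples-as-rows layout and fall through.
    rn <- trimws(as.character(raw[[1]]))
    body <- t(as.matrix(raw[, -1, drop = FALSE]))
    df <- as.data.frame(body, stringsAsFactors = FALSE)
    names(df) <- rn
    df <- cbind(sample_id = colnames(raw)[-1], df, stringsAsFactors = FALSE)
    raw <- df
    id_column <- "sample_id"
  }

  cols <- names(raw)
  if (!is.null(id_column) && id_column %in% cols) {
    sample_ids <- trimws(as.character(raw[[id_column]]))
    raw <- raw[, setdiff(cols, id_column), drop = FALSE]
  } else {
    sample_ids <- paste0("S", seq_len(nrow(raw)))
  }

  envs <- NULL
  if (!is.null(metadata)) {
    msep <- if (grepl("\\.tsv$", metadata, ignore.case = TRUE)) "\t" else ","
    md <- utils::read.table(metadata, header = TRUE, sep = msep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(md) < 2)
      stop("metadata file needs two columns (sample_id, environment)",
           call. = FALSE)
    key <- trimws(as.character(md[[1]]))
    val <- trimws(as.character(md[[2]]))
    envs <- val[match(sample_ids, key)]
    if (any(is.na(envs)))
      stop("no environment label in metadata for sample(s): ",
           paste(sample_ids[is.na(envs)], collapse = ", "), call. = FALSE)
  } else {
    if (!env_column %in% names(raw))
      stop("environment column '", env_column, "' not found in ", path,
           call. = FALSE)
    envs <- trimws(as.character(raw[[env_column]]))
    raw <- raw[, setdiff(names(raw), env_column), drop = FALSE]
  }

  if (ncol(raw) == 0L) stop("no class columns left in ", path, call. = FALSE)
  num <- suppressWarnings(
    vapply(raw, function(col) as.numeric(as.character(col)),
           numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(NULL, names(raw)))
  if (any(is.na(num))) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value in sample '%s', class '%s'",
                 sample_ids[idx[1]], colnames(num)[idx[2]]), call. = FALSE)
  }
  if (any(num < 0)) {
    idx <- which(num < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value %g in sample '%s', class '%s'",
                 num[idx[1], idx[2]], sample_ids[idx[1]],
                 colnames(num)[idx[2]]), call. = FALSE)
  }
  composition_table(num, sample_ids, colnames(num), envs)
}

#' Write a composition table to CSV/TSV
#'
#' Writes a `sample_id` column, an `environment` column and one column per
#' class. [read_composition()] on the result reconstructs the table
#' exactly (values, names and labels).
#'
#' @param table a [composition_table()].
#' @param path output path; extension selects the delimiter unless `sep`
#'   is given.
#' @param sep optional delimiter override.
#' @export
write_composition <- function(table, path, sep = NULL) {
  validate_composition_table(table)
  sep <- sep %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(sample_id = table$sample_ids,
                   environment = table$environments,
                   stringsAsFactors = FALSE, check.names = FALSE)
  vals <- as.data.frame(table$values, stringsAsFactors = FALSE)
  names(vals) <- table$class_names
  df <- cbind(df, vals)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
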