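#' Write a result object to disk
#'
#' `format = "text"` writes the same human-readable report that printing
#' the object shows. `format = "json"` writes a machine-readable record
#' tagged with the result type and a schema version; all numeric fields —
#' including named parameter vectors — round-trip at full precision
#' through [read_result()].
#'
#' @param result an `lrt_result`, `gof_result` or `power_result`.
#' @param path output file path.
#' @param format `"text"` or `"json"`.
#' @export
write_result <- function(result, path, format = c("text", "json")) {
  format <- match.arg(format)
  type <- intersect(class(result),
                    c("lrt_result", "gof_result", "power_result"))
  if (length(type) != 1)
    stop("result must be an lrt_result, gof_result or power_result",
         call. = FALSE)
  if (format == "text") {
    lines <- utils::capture.output(print(result))
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) FALSE,
                   warning = function(w) FALSE)
    if (!ok) stop("cannot write to ", path, call. = FALSE)
    return(invisible(path))
  }
  payload <- unclass(result)
  # jsonlite drops the names of atomic vectors; parameter vectors go out
  # as objects instead so class labels survive the round trip
  for (fld in c("alpha_null", "alpha"))
    if (!is.null(payload[[fld]]) && !is.list(payload[[fld]]))
      payload[[fld]] <- as.list(payload[[fld]])
  for (fld in c("alpha_alt", "alpha_tilde"))
    if (!is.null(payload[[fld]]))
      payload[[fld]] <- lapply(payload[[fld]], as.list)
  if (identical(type, "gof_result") && is.list(result$alpha))
    payload$alpha <- lapply(result$alpha, as.list)
  if (!is.null(payload$filter_report))
    payload$filter_report <- unclass(payload$filter_report)
  payload <- c(list(schema_version = 1L, type = type), payload)
  ok <- tryCatch({
    suppressWarnings(
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

# reconstruction helpers for read_result / read_scenario (JSON parsed
# with simplifyVector = FALSE so nothing is guessed)
.num1 <- function(v) if (is.null(v)) NULL else as.numeric(v[[1]])
.int1 <- function(v) if (is.null(v)) NA_integer_ else as.integer(v[[1]])
.lgl1 <- function(v) isTRUE(v[[1]]) || identical(v, TRUE)
.chr1 <- function(v) if (is.null(v)) NULL else as.character(v[[1]])
.numvec <- function(v) as.numeric(unlist(v))
.chrvec <- function(v) as.character(unlist(v))
.named_num <- function(v) {
  out <- as.numeric(unlist(v))
  names(out) <- names(v)
  out
}

#' Read back a JSON result record
#'
#' Inverse of [write_result()] with `format = "json"`: restores the
#' numeric fields (including named parameter vectors) and the result
#' class.
#'
#' @param path path to a JSON record produced by [write_result()].
#' @return The reconstructed result object.
#' @export
read_result <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  type <- .chr1(x$type)
  out <- switch(
    type %||% "unknown",
    lrt_result = {
      fr <- x$filter_report
      list(D = .num1(x$D), df = .int1(x$df),
           p_chi2 = .num1(x$p_chi2), p_rand = .num1(x$p_rand),
           rand_is_bound = .lgl1(x$rand_is_bound),
           n_rand_trials = .int1(x$n_rand_trials),
           n_exceed = .int1(x$n_exceed),
           logL0 = .num1(x$logL0), logL1 = .num1(x$logL1),
           alpha_null = .named_num(x$alpha_null),
           alpha_alt = lapply(x$alpha_alt, .named_num),
           method_used = .chr1(x$method_used),
           m = .int1(x$m), K = .int1(x$K),
           n_i = as.integer(unlist(x$n_i)),
           filter_report = if (is.null(fr)) NULL else structure(
             list(kept_classes = .chrvec(fr$kept_classes),
                  aggregated_classes = .chrvec(fr$aggregated_classes),
                  other_dropped = .lgl1(fr$other_dropped),
                  other_label = .chr1(fr$other_label),
                  K_before = .int1(fr$K_before),
                  K_after = .int1(fr$K_after)),
             class = "filter_report"),
           seed = if (is.null(x$seed)) NULL else .int1(x$seed))
    },
    gof_result = {
      list(T0 = .num1(x$T0), T_sim = .numvec(x$T_sim),
           p_gof = .num1(x$p_gof), n_sims = .int1(x$n_sims),
           model_used = .chr1(x$model_used),
           alpha = lapply(x$alpha, .named_num),
           seed = if (is.null(x$seed)) NULL else .int1(x$seed))
    },
    power_result = {
      list(group_sizes = as.integer(unlist(x$group_sizes)),
           power = .numvec(x$power), n_sims = .int1(x$n_sims),
           significance = .num1(x$significance),
           method = .chr1(x$method),
           alpha_tilde = lapply(x$alpha_tilde, .named_num),
           seed = if (is.null(x$seed)) NULL else .int1(x$seed))
    },
    stop("unrecognized result type in ", path, call. = FALSE))
  structure(out, class = type)
}
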