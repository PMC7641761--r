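# File formats: traces as TSV (time_s, extension_nm, force_pN) with an
# optional ground-truth JSON sidecar; events and summaries as CSV; fits as
# JSON. Numeric columns are written with 17 significant digits so a
# write/read round trip reproduces doubles exactly.

fmt_num_cols <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  df
}

#' Write / read a tweezer trace as TSV
#'
#' The trace table is written as tab-separated text with header columns
#' `time_s`, `extension_nm`, `force_pN`.  If the trace carries a planted
#' ground-truth event log, it is written to `<path>.truth.json` and
#' restored on read when the sidecar exists.
#'
#' @param trace A `tweezer_trace` (or list with a `data` data.frame).
#' @param path Output TSV path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   list of class `tweezer_trace` with `data` (and `truth` if available).
#' @export
write_trace <- function(trace, path) {
  utils::write.table(fmt_num_cols(trace$data), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(trace$truth))
    jsonlite::write_json(trace$truth, paste0(path, ".truth.json"),
                         digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  out <- list(data = d, truth = NULL)
  sidecar <- paste0(path, ".truth.json")
  if (file.exists(sidecar))
    out$truth <- as.data.frame(jsonlite::read_json(sidecar,
                                                   simplifyVector = TRUE))
  class(out) <- "tweezer_trace"
  out
}

#' Write / read detected events as CSV
#'
#' Columns: `condition`, `cycle_index`, `delta_l_nm`, `t_synapsis_s`,
#' `censored`, `specificity`.
#'
#' @param events An `end_binding_events` data.frame.
#' @param path Output CSV path.
#' @param condition Condition label stored in the first column.
#' @return `write_events` returns `path` invisibly; `read_events` an
#'   `end_binding_events` data.frame (condition kept as a column).
#' @export
write_events <- function(events, path, condition = "") {
  df <- cbind(condition = condition, as.data.frame(events))
  utils::write.csv(fmt_num_cols(df), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("end_binding_events", "data.frame")
  df
}

#' Write fit objects as a JSON record
#'
#' Serializes any mix of `amplitude_fit`, `lifetime_fit` and `binding_fit`
#' objects (given as a named list) to a single JSON file, tagging each
#' record with its fit type.
#'
#' @param fits Named list of fit objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  rec <- lapply(fits, function(f) c(list(fit_type = class(f)[1L]),
                                    unclass(f)))
  jsonlite::write_json(rec, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Write / read a condition summary table as CSV
#'
#' @param summary A `condition_summary` data.frame from [run_pipeline()] or
#'   [summarize_condition()].
#' @param path Output CSV path.
#' @return `write_summary` returns `path` invisibly; `read_summary` the
#'   table with numeric columns restored exactly.
#' @export
write_summary <- function(summary, path) {
  utils::write.csv(fmt_num_cols(as.data.frame(summary)), path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("condition_summary", "data.frame")
  df
}

#' Write / read a binding curve as CSV
#'
#' Columns `concentration_M`, `signal`.
#'
#' @param curve A `binding_curve` data.frame.
#' @param path CSV path.
#' @return `write_binding_curve` returns `path` invisibly;
#'   `read_binding_curve` a `binding_curve` data.frame.
#' @export
write_binding_curve <- function(curve, path) {
  utils::write.csv(fmt_num_cols(as.data.frame(curve)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_binding_curve
#' @export
read_binding_curve <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("concentration_M", "signal") %in% names(df)))
  class(df) <- c("binding_curve", "data.frame")
  df
}
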