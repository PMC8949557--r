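# Structured CSV logging of drying runs.

.log_columns <- c("clock_min", "event", "tx_min", "M_out_wb",
                  "T1", "T2", "T3", "T4", "Te", "AT_set", "AT_realized",
                  "mode", "u", "M_pred", "AT_model")

#' Write / read a drying run log
#'
#' One row per discharge event; stable leading column order
#' `clock_min, event, tx_min, M_out_wb, T1, T2, T3, T4, Te, AT_set,
#' AT_realized, mode` followed by diagnostics. Temperatures are degrees C,
#' moistures percent wet basis at the sensor surface, accumulated
#' temperatures degree-minutes. An empty run writes a header-only file.
#' Writing with `append = TRUE` adds rows without repeating the header.
#'
#' @param x A `drying_run` object or a run log data frame.
#' @param path CSV file path.
#' @param append Append to an existing log instead of overwriting.
#' @return The writer returns `path` invisibly; the reader returns the log
#'   data frame.
#' @export
write_run_log <- function(x, path, append = FALSE) {
  log <- if (inherits(x, "drying_run")) x$log else x
  missing <- setdiff(.log_columns, names(log))
  if (nrow(log) > 0 && length(missing) > 0) {
    stop_eatdry("eatdry_config",
                paste("log is missing columns:", paste(missing, collapse = ", ")))
  }
  if (nrow(log) == 0) log <- as.data.frame(stats::setNames(
    rep(list(numeric(0)), length(.log_columns)), .log_columns))
  utils::write.table(log[.log_columns], path, sep = ",", row.names = FALSE,
                     col.names = !append, append = append, quote = FALSE)
  invisible(path)
}

#' @rdname write_run_log
#' @export
read_run_log <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Recompute the run report from a log
#'
#' @param log A run log data frame or a path to a log CSV.
#' @param cfg The run's [eatdry_config()].
#' @return The [run_summary()] list.
#' @export
run_report <- function(log, cfg = eatdry_config()) {
  if (is.character(log)) log <- read_run_log(log)
  run_summary(log, cfg)
}
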