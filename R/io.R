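#' Read and write traces and schedules as CSV
#'
#' Traces are stored as `time_s,value` CSV; schedules as
#' `label,start_s,end_s`. The trace frame rate is recovered from the time
#' column on reading.
#'
#' @param path file path.
#' @return `read_trace_csv()` returns a trace tibble with an `fps`
#'   attribute; `read_schedule_csv()` returns a [state_schedule()] tibble.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- tibble::as_tibble(df[, c("time_s", "value")])
  attr(out, "fps") <- 1 / stats::median(diff(out$time_s))
  out
}

#' @rdname read_trace_csv
#' @param trace trace tibble.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace[, c("time_s", "value")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_trace_csv
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path)
  state_schedule(df$label, df$start_s, df$end_s)
}

#' @rdname read_trace_csv
#' @param schedule schedule tibble.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(schedule[, c("label", "start_s", "end_s")], path,
                   row.names = FALSE)
  invisible(path)
}
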