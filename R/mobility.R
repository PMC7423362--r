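#' Construct a mobility trace
#'
#' Binarised mobility time series from home-cage video tracking, the input to
#' immobility-defined sleep scoring. Samples are regular; `mobile[i]` covers
#' `[start + (i-1) * dt, start + i * dt)`.
#'
#' @param mobile Logical (or 0/1) vector; `TRUE` = mobile.
#' @param sample_interval_s Sample spacing in seconds (default 1).
#' @param start_clock_s Clock time of the first sample, seconds of day.
#' @param schedule A [light_schedule()].
#' @return An object of class `mobility_trace`.
#' @export
mobility_trace <- function(mobile, sample_interval_s = 1, start_clock_s = 0,
                           schedule = light_schedule()) {
  stopifnot(sample_interval_s > 0, length(mobile) >= 1)
  mobile <- as.logical(mobile)
  if (anyNA(mobile)) stop("mobility trace contains non-binary values")
  structure(
    list(mobile = mobile, sample_interval_s = sample_interval_s,
         start_clock_s = start_clock_s, schedule = schedule),
    class = "mobility_trace"
  )
}

#' Read/write a mobility trace (CSV columns `time_s,mobile`)
#'
#' @param path CSV path.
#' @param schedule,start_clock_s See [mobility_trace()].
#' @return [read_mobility()]: a `mobility_trace`; [write_mobility()]: `path`.
#' @export
read_mobility <- function(path, schedule = light_schedule(),
                          start_clock_s = 0) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "mobile") %in% names(df))) {
    stop("mobility CSV must have columns time_s,mobile: ", path)
  }
  dt <- if (nrow(df) >= 2) df$time_s[2] - df$time_s[1] else 1
  mobility_trace(df$mobile != 0, sample_interval_s = dt,
                 start_clock_s = start_clock_s, schedule = schedule)
}

#' @rdname read_mobility
#' @param trace A [mobility_trace()].
#' @export
write_mobility <- function(trace, path) {
  df <- data.frame(
    time_s = (seq_along(trace$mobile) - 1) * trace$sample_interval_s,
    mobile = as.integer(trace$mobile)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
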