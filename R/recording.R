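#' Multi-channel uniformly sampled time-series recording
#'
#' Container for a field-stimulation or patch-clamp recording: a uniform time
#' grid plus named channels (e.g. `fura_ratio`, `sarcomere_length`,
#' `stimulus`, `membrane_potential`). All channels share the grid.
#'
#' @param time Numeric vector of sample times in seconds, strictly increasing
#'   on a uniform grid.
#' @param channels Named list of numeric vectors, each the same length as
#'   `time`.
#' @param sampling_rate Sampling rate in Hz. If missing it is inferred from
#'   the median time step.
#' @return An object of class `ts_recording` with elements `time`,
#'   `channels`, `sampling_rate`.
#' @export
ts_recording <- function(time, channels, sampling_rate = NULL) {
  stopifnot(is.numeric(time), is.list(channels), length(channels) >= 1L)
  abort_if(is.null(names(channels)) || any(!nzchar(names(channels))),
           "all channels must be named")
  n <- length(time)
  abort_if(n < 2L, "recording needs at least two samples")
  dt <- diff(time)
  abort_if(any(dt <= 0), "time must be strictly increasing")
  abort_if(max(abs(dt - stats::median(dt))) > 1e-6 * stats::median(dt) + 1e-12,
           "time grid is not uniform")
  for (nm in names(channels)) {
    abort_if(length(channels[[nm]]) != n,
             "channel '%s' length (%d) != time length (%d)",
             nm, length(channels[[nm]]), n)
  }
  if (is.null(sampling_rate)) sampling_rate <- 1 / stats::median(dt)
  structure(list(time = as.numeric(time),
                 channels = lapply(channels, as.numeric),
                 sampling_rate = sampling_rate),
            class = "ts_recording")
}

#' @export
print.ts_recording <- function(x, ...) {
  cat(sprintf("<ts_recording> %d samples @ %.6g Hz (%.3f s), channels: %s\n",
              length(x$time), x$sampling_rate,
              x$time[length(x$time)] - x$time[1],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Fetch a channel from a recording
#' @param rec A [ts_recording()].
#' @param name Channel name.
#' @return Numeric vector.
#' @export
get_channel <- function(rec, name) {
  stopifnot(inherits(rec, "ts_recording"))
  abort_if(!name %in% names(rec$channels),
           "channel '%s' not present (have: %s)", name,
           paste(names(rec$channels), collapse = ", "))
  rec$channels[[name]]
}

#' Write a recording to delimited text
#'
#' Tab-separated with a header row: `time_s` followed by the channel names.
#'
#' @param rec A [ts_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(rec, path) {
  stopifnot(inherits(rec, "ts_recording"))
  df <- data.frame(time_s = rec$time, rec$channels, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a recording from delimited text
#'
#' Expects the format written by [write_timeseries()]: a header naming
#' `time_s` and one column per channel.
#'
#' @param path Input file path.
#' @return A [ts_recording()].
#' @export
read_timeseries <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  abort_if(!"time_s" %in% names(df),
           "malformed time-series file '%s': no 'time_s' column", path)
  abort_if(ncol(df) < 2L, "time-series file '%s' has no signal columns", path)
  ch <- as.list(df[setdiff(names(df), "time_s")])
  ts_recording(df$time_s, ch)
}
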