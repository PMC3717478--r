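iso_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")

parse_time <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OS",
                                     tz = "UTC")

#' Read and write raw traces and study tables as CSV
#'
#' Plain-text interchange for the pipeline's objects. Traces use the
#' essential columns of the raw-CSV dialect of waist-worn research
#' accelerometers: `timestamp` (ISO-8601, UTC, millisecond precision),
#' `x`, `y`, `z` in g. Sleep diaries are `child_id,date,bed_time,wake_time`
#' (one morning report per row); affect responses are
#' `child_id,date,occasion,item_id,response`; labelled epochs are
#' `child_id,epoch_start,label`.
#'
#' @param trace,epochs Objects to write.
#' @param path File path.
#' @param child_id,rate Metadata applied when reading a trace.
#' @return The written object (invisibly) or the object read.
#' @name actiflux_io
NULL

#' @rdname actiflux_io
#' @export
write_trace_csv <- function(trace, path) {
  d <- data.frame(timestamp = iso_time(trace$time), x = trace$x, y = trace$y,
                  z = trace$z)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(trace)
}

#' @rdname actiflux_io
#' @export
read_trace_csv <- function(path, child_id = "unknown", rate = 30) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  accel_trace(parse_time(d$timestamp), as.matrix(d[, c("x", "y", "z")]),
              child_id = child_id, rate = rate)
}

#' @rdname actiflux_io
#' @export
write_epochs_csv <- function(epochs, path) {
  d <- data.frame(child_id = epochs$child_id,
                  epoch_start = iso_time(epochs$epoch_start),
                  label = as.character(epochs$label))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(epochs)
}

#' @rdname actiflux_io
#' @export
read_epochs_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  labeled_epochs(d$child_id, parse_time(d$epoch_start), d$label)
}

#' @rdname actiflux_io
#' @param sleep Sleep-diary data.frame.
#' @export
write_sleep_csv <- function(sleep, path) {
  d <- data.frame(child_id = sleep$child_id, date = format(sleep$date),
                  bed_time = iso_time(sleep$bed_time),
                  wake_time = iso_time(sleep$wake_time))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(sleep)
}

#' @rdname actiflux_io
#' @export
read_sleep_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(child_id = d$child_id, date = as.Date(d$date),
             bed_time = parse_time(d$bed_time),
             wake_time = parse_time(d$wake_time))
}

#' @rdname actiflux_io
#' @param responses Affect item responses data.frame.
#' @export
write_affect_csv <- function(responses, path) {
  d <- responses[, c("child_id", "date", "occasion", "item_id", "response")]
  d$date <- format(as.Date(d$date))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(responses)
}

#' @rdname actiflux_io
#' @export
read_affect_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$date <- as.Date(d$date)
  d
}
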