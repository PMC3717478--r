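#' Construct an acceleration trace object
#'
#' A trace is a data.frame with columns `time` (POSIXct), `x`, `y`, `z`
#' (acceleration in g), carrying the child id and the sampling rate as
#' attributes. All samples are clipped to the device range of -6..+6 g.
#'
#' @param time POSIXct sample times, equally spaced at `1/rate` s.
#' @param xyz Numeric matrix with 3 columns (x, y, z) in g.
#' @param child_id Identifier of the child.
#' @param rate Sampling rate in Hz.
#' @return An `accel_trace` data.frame.
#' @export
accel_trace <- function(time, xyz, child_id, rate = 30) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3, length(time) == nrow(xyz))
  xyz <- pmin(pmax(xyz, -6), 6)
  out <- data.frame(time = time, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  attr(out, "child_id") <- child_id
  attr(out, "rate") <- rate
  class(out) <- c("accel_trace", "data.frame")
  out
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> child %s: %d samples at %g Hz (%.1f s)\n",
              attr(x, "child_id"), nrow(x), attr(x, "rate"),
              nrow(x) / attr(x, "rate")))
  if (nrow(x)) {
    cat(sprintf("  start %s\n", format(x$time[1], "%Y-%m-%d %H:%M:%OS1")))
    print.data.frame(utils::head(as.data.frame(x), 3))
  }
  invisible(x)
}

# Raw sample matrix for one activity bout; RNG state is the caller's.
simulate_bout_samples <- function(kind, n, params, rate) {
  p <- params
  g <- if (kind == "non_wear") table_orientations()[[p$table_position]] else p$gravity
  xyz <- matrix(rep(g, each = n), ncol = 3)
  if (p$gait_frequency > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    t <- (seq_len(n) - 1) / rate
    s <- sin(2 * pi * p$gait_frequency * t + phase)
    xyz[, 2] <- xyz[, 2] + p$gait_amplitude * s        # vertical axis
    xyz[, 1] <- xyz[, 1] + p$gait_amplitude / 2 * s    # anterior axis
  }
  if (p$noise_sd > 0) {
    xyz <- xyz + matrix(stats::rnorm(3 * n, sd = p$noise_sd), ncol = 3)
  }
  xyz
}

#' Simulate a raw acceleration trace for one activity
#'
#' Generates a 30 Hz triaxial trace for a single activity class under the
#' package's signal model (see [signal_params()]): gravity orientation plus
#' white noise for postures; an added gait sinusoid for locomotion; a fixed
#' table orientation with minimal noise for non-wear. Samples are clipped to
#' the -6..+6 g device range.
#'
#' @param kind One of [activity_kinds()].
#' @param duration Duration in seconds (> 0).
#' @param params [signal_params()] for the class; defaults to
#'   [default_signal_params()]`[[kind]]`.
#' @param seed Integer seed; identical seeds give identical traces.
#' @param rate Sampling rate in Hz (default 30).
#' @param start_time POSIXct start of the trace.
#' @param child_id Identifier recorded on the trace.
#' @return An [accel_trace()] of `duration * rate` samples.
#' @export
#' @examples
#' tr <- simulate_activity_trace("running", 10, seed = 1)
#' var(tr$y)  # about 0.8^2 / 2 plus noise
simulate_activity_trace <- function(kind, duration,
                                    params = default_signal_params()[[kind]],
                                    seed = NULL, rate = 30,
                                    start_time = as.POSIXct("2012-05-07 08:00:00",
                                                            tz = "UTC"),
                                    child_id = "sim") {
  kind <- match.arg(kind, activity_kinds())
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    stop("duration must be a single positive number of seconds")
  }
  if (is.null(params)) stop("no signal parameters for kind ", kind)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * rate)
  xyz <- simulate_bout_samples(kind, n, params, rate)
  time <- start_time + (seq_len(n) - 1) / rate
  accel_trace(time, xyz, child_id = child_id, rate = rate)
}

#' Simulate a labelled reference session
#'
#' Emulates the reference measurement conducted per class: the child (or the
#' table, for non-wear) performs a pre-defined protocol of activities while
#' the device records, so that it is exactly known which acceleration data
#' corresponds to which activity. Durations must be multiples of the 2.5 s
#' frame length so that no epoch straddles two activities, and the protocol
#' must cover all seven labels so a classifier can be trained on the result.
#'
#' @param child_id Identifier of the child.
#' @param protocol Data.frame with columns `kind` and `duration` (seconds),
#'   or NULL for the default of 60 s per label.
#' @param params_per_kind Named list of [signal_params()] per label.
#' @param seed Integer seed.
#' @param rate Sampling rate in Hz.
#' @param start_time POSIXct start.
#' @param frame_length Epoch length in seconds (default 2.5).
#' @return List with elements `trace` ([accel_trace()]) and `epochs`
#'   ([labeled_epochs()]) holding the ground-truth label per 2.5 s epoch.
#' @export
simulate_reference_session <- function(child_id, protocol = NULL,
                                       params_per_kind = default_signal_params(),
                                       seed = NULL, rate = 30,
                                       start_time = as.POSIXct("2012-05-07 10:00:00",
                                                               tz = "UTC"),
                                       frame_length = 2.5) {
  if (is.null(protocol)) {
    protocol <- data.frame(kind = activity_kinds(), duration = 60)
  }
  stopifnot(all(c("kind", "duration") %in% names(protocol)))
  protocol$kind <- as.character(protocol$kind)
  missing_kinds <- setdiff(activity_kinds(), protocol$kind)
  if (length(missing_kinds)) {
    stop("protocol missing label(s): ", paste(missing_kinds, collapse = ", "))
  }
  off <- abs(protocol$duration / frame_length -
               round(protocol$duration / frame_length)) > 1e-9
  if (any(off)) {
    stop("protocol durations must be multiples of the ", frame_length,
         " s frame length")
  }
  if (!is.null(seed)) set.seed(seed)
  xyz <- vector("list", nrow(protocol))
  labels <- character(0)
  for (i in seq_len(nrow(protocol))) {
    kind <- protocol$kind[i]
    n <- round(protocol$duration[i] * rate)
    xyz[[i]] <- simulate_bout_samples(kind, n, params_per_kind[[kind]], rate)
    labels <- c(labels, rep(kind, round(protocol$duration[i] / frame_length)))
  }
  xyz <- do.call(rbind, xyz)
  time <- start_time + (seq_len(nrow(xyz)) - 1) / rate
  trace <- accel_trace(time, xyz, child_id = child_id, rate = rate)
  epoch_start <- start_time + (seq_along(labels) - 1) * frame_length
  epochs <- labeled_epochs(child_id, epoch_start, labels,
                           epoch_seconds = frame_length)
  list(trace = trace, epochs = epochs)
}

#' Construct a labelled-epoch object
#'
#' Epochs sit on a contiguous fixed-length grid; labels come from the
#' seven-class set of [activity_kinds()].
#'
#' @param child_id Identifier (recycled).
#' @param epoch_start POSIXct start times on the epoch grid.
#' @param labels Activity labels, one per epoch.
#' @param epoch_seconds Grid step in seconds (default 2.5).
#' @return A `labeled_epochs` data.frame with columns `child_id`,
#'   `epoch_start`, `label`.
#' @export
labeled_epochs <- function(child_id, epoch_start, labels, epoch_seconds = 2.5) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), activity_kinds())
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  out <- data.frame(child_id = rep_len(child_id, length(labels)),
                    epoch_start = epoch_start,
                    label = factor(labels, levels = activity_kinds()))
  attr(out, "epoch_seconds") <- epoch_seconds
  class(out) <- c("labeled_epochs", "data.frame")
  out
}

#' @export
print.labeled_epochs <- function(x, ...) {
  cat(sprintf("<labeled_epochs> %d epochs of %g s\n", nrow(x),
              attr(x, "epoch_seconds")))
  print(table(x$label))
  invisible(x)
}

# Grid step of an epoch object, from the attribute or the time stamps.
epoch_step <- function(epochs) {
  s <- attr(epochs, "epoch_seconds")
  if (!is.null(s)) return(s)
  if (nrow(epochs) < 2) stop("cannot infer epoch length from a single epoch")
  as.numeric(stats::median(diff(as.numeric(epochs$epoch_start))))
}

# Stops unless epoch_start is a contiguous grid at the declared step.
check_epoch_grid <- function(epochs) {
  step <- epoch_step(epochs)
  if (nrow(epochs) > 1) {
    d <- diff(as.numeric(epochs$epoch_start))
    if (any(abs(d - step) > 1e-6)) stop("gap in the epoch grid")
  }
  step
}
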