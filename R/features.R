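#' Segment a trace into non-overlapping frames
#'
#' Cuts a raw trace into consecutive frames of `frame_length` seconds
#' (default 2.5 s, i.e. 75 samples at 30 Hz — short enough to resolve the
#' brief activity bouts typical of children's movement). A trailing partial
#' frame is discarded.
#'
#' @param trace An [accel_trace()].
#' @param frame_length Frame length in seconds; `rate * frame_length` must
#'   be an integer.
#' @return List with `x`, `y`, `z`: matrices of `samples_per_frame` rows by
#'   `n_frames` columns; plus `start_time` (POSIXct per frame), `rate` and
#'   `frame_length`.
#' @export
segment_frames <- function(trace, frame_length = 2.5) {
  rate <- attr(trace, "rate")
  spf <- rate * frame_length
  if (abs(spf - round(spf)) > 1e-9) {
    stop("rate * frame_length must be an integer number of samples")
  }
  spf <- as.integer(round(spf))
  n_frames <- nrow(trace) %/% spf
  keep <- seq_len(n_frames * spf)
  out <- list(
    x = matrix(trace$x[keep], nrow = spf),
    y = matrix(trace$y[keep], nrow = spf),
    z = matrix(trace$z[keep], nrow = spf),
    start_time = trace$time[seq(1, by = spf, length.out = n_frames)],
    rate = rate, frame_length = frame_length,
    child_id = attr(trace, "child_id")
  )
  class(out) <- "accel_frames"
  out
}

# Spectral energy per frame: sum of squared DFT magnitudes excluding the
# DC component, under the length-normalized transform; by Parseval this
# equals the frame's mean squared deviation-from-mean power.
frame_energy <- function(m) {
  n <- nrow(m)
  sp <- Mod(stats::mvfft(m))^2
  (colSums(sp) - sp[1, ]) / n^2
}

# Population (1/n) variance and cross-moments per column.
frame_var <- function(m) colMeans(m^2) - colMeans(m)^2
frame_cov <- function(a, b) colMeans(a * b) - colMeans(a) * colMeans(b)

# Correlation with the zero-variance convention: a constant axis (e.g. a
# device at rest on a table) correlates 0 with everything.
safe_corr <- function(cab, va, vb) {
  denom <- sqrt(va * vb)
  r <- ifelse(denom > 0, cab / denom, 0)
  pmin(pmax(r, -1), 1)
}

#' Compute the 12 key-values of each frame
#'
#' For every frame: per-axis mean and (population) variance, the three
#' pairwise inter-axis correlations, and the per-axis spectral energy
#' (squared Fourier magnitudes, DC excluded, length-normalized so that a
#' pure sinusoid of amplitude a yields a^2/2). Twelve values per frame.
#' A constant axis gets correlation 0 by convention.
#'
#' @param frames Output of [segment_frames()], or an [accel_trace()] (which
#'   is segmented first with the default frame length).
#' @return A `frame_features` data.frame: `frame_index`, `start_time`, and
#'   the 12 feature columns `mean_x`, `mean_y`, `mean_z`, `var_x`, `var_y`,
#'   `var_z`, `corr_xy`, `corr_xz`, `corr_yz`, `energy_x`, `energy_y`,
#'   `energy_z`.
#' @export
#' @examples
#' tr <- simulate_activity_trace("standing", 10, seed = 1)
#' compute_features(tr)[1, ]
compute_features <- function(frames) {
  if (inherits(frames, "accel_trace")) frames <- segment_frames(frames)
  stopifnot(inherits(frames, "accel_frames"))
  if (nrow(frames$x) < 2) stop("frames must contain at least 2 samples")
  vx <- frame_var(frames$x); vy <- frame_var(frames$y); vz <- frame_var(frames$z)
  out <- data.frame(
    frame_index = seq_along(frames$start_time),
    start_time = frames$start_time,
    mean_x = colMeans(frames$x), mean_y = colMeans(frames$y),
    mean_z = colMeans(frames$z),
    var_x = vx, var_y = vy, var_z = vz,
    corr_xy = safe_corr(frame_cov(frames$x, frames$y), vx, vy),
    corr_xz = safe_corr(frame_cov(frames$x, frames$z), vx, vz),
    corr_yz = safe_corr(frame_cov(frames$y, frames$z), vy, vz),
    energy_x = frame_energy(frames$x), energy_y = frame_energy(frames$y),
    energy_z = frame_energy(frames$z)
  )
  attr(out, "child_id") <- frames$child_id
  attr(out, "frame_length") <- frames$frame_length
  class(out) <- c("frame_features", "data.frame")
  rownames(out) <- NULL
  out
}

#' Names of the 12 frame features, in canonical order
#' @return Character vector of length 12.
#' @export
feature_names <- function() {
  c("mean_x", "mean_y", "mean_z", "var_x", "var_y", "var_z",
    "corr_xy", "corr_xz", "corr_yz", "energy_x", "energy_y", "energy_z")
}
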