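#' Activity classes of the reference protocol
#'
#' The seven labels the classifier distinguishes: the six activities of the
#' reference-measurement protocol (conducted in a physical-education lesson
#' and recorded with the device worn on the waist) plus `non_wear`, the state
#' of a recording device lying on a table. The label set and its order are
#' fixed; every labelled-epoch object in the package uses a factor with
#' exactly these levels.
#'
#' @return Character vector of the seven labels, in canonical order.
#' @export
#' @examples
#' activity_kinds()
activity_kinds <- function() {
  c("lying", "sitting", "standing", "walk_slow", "walk_fast", "running",
    "non_wear")
}

#' Behaviour categories of the activity labels
#'
#' Maps activity labels onto the standard behaviour categories used for the
#' daily summaries: lying and sitting are sedentary behaviour, standing is
#' inactive behaviour, slow and fast walking are moderate-to-vigorous
#' physical activity (MVPA), and running is very vigorous activity.
#' `non_wear` maps to itself.
#'
#' @param labels Character vector or factor of activity labels (see
#'   [activity_kinds()]).
#' @return Factor with levels `sedentary`, `inactive`, `mvpa`,
#'   `very_vigorous`, `non_wear`.
#' @export
#' @examples
#' behavior_category(c("sitting", "running", "walk_fast"))
behavior_category <- function(labels) {
  map <- c(lying = "sedentary", sitting = "sedentary", standing = "inactive",
           walk_slow = "mvpa", walk_fast = "mvpa", running = "very_vigorous",
           non_wear = "non_wear")
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), names(map))
  if (length(bad)) {
    stop("unknown activity label(s): ", paste(bad, collapse = ", "))
  }
  factor(unname(map[labels]), levels = behavior_categories())
}

#' @rdname behavior_category
#' @export
behavior_categories <- function() {
  c("sedentary", "inactive", "mvpa", "very_vigorous", "non_wear")
}

#' Signal-model parameters for one activity class
#'
#' The generator's signal model: at rest an accelerometer on the body reads
#' the gravity vector in device coordinates plus sensor/body noise; during
#' locomotion a gait oscillation rides on top of gravity, modelled as a
#' sinusoid of `gait_frequency` and `gait_amplitude` on the vertical device
#' axis with half that amplitude, in phase, on the anterior axis. Non-wear
#' is a device at rest on a table in one of three plausible resting
#' orientations with minimal sensor noise.
#'
#' @param gravity Numeric length-3 unit vector: mean orientation of the
#'   device (g per axis).
#' @param gait_frequency Step frequency in Hz; 0 for postures and non-wear.
#' @param gait_amplitude Peak amplitude of the gait sinusoid in g; must be 0
#'   when `gait_frequency` is 0.
#' @param noise_sd Standard deviation of the white measurement noise in g.
#' @param table_position Integer 1..3 selecting the resting orientation;
#'   only used for `non_wear`.
#' @return An object of class `signal_params`.
#' @export
signal_params <- function(gravity, gait_frequency = 0, gait_amplitude = 0,
                          noise_sd = 0, table_position = 1L) {
  gravity <- as.numeric(gravity)
  stopifnot(length(gravity) == 3, all(is.finite(gravity)))
  if (abs(sqrt(sum(gravity^2)) - 1) > 1e-9) {
    stop("gravity must be a unit vector (|norm - 1| <= 1e-9)")
  }
  if (gait_frequency < 0) stop("gait_frequency must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (gait_frequency == 0 && gait_amplitude != 0) {
    stop("gait_amplitude must be 0 when gait_frequency is 0")
  }
  if (!table_position %in% 1:3) stop("table_position must be 1, 2 or 3")
  structure(list(gravity = gravity, gait_frequency = gait_frequency,
                 gait_amplitude = gait_amplitude, noise_sd = noise_sd,
                 table_position = as.integer(table_position)),
            class = "signal_params")
}

# Resting orientations of a device lying on a flat surface (unit vectors).
table_orientations <- function() {
  list(c(0, 0, -1), c(1, 0, 0), c(-1, 0, 0))
}

#' Default signal parameters per activity class
#'
#' Axis convention: y is the vertical (superior-inferior) device axis when
#' the child is upright, x anterior-posterior, z medio-lateral. Postures
#' differ by mean orientation (sitting tilts the trunk ~15 degrees back;
#' lying puts gravity on z); the three gaits share the upright orientation
#' and differ by step frequency and amplitude. Defaults keep the six
#' activity classes separable in frame-feature space at noise SDs up to
#' about 0.05 g.
#'
#' @param noise_sd Measurement-noise SD in g applied to the six worn
#'   classes (non-wear always uses 0.001 g). Default 0.03.
#' @return Named list of [signal_params()], one per label of
#'   [activity_kinds()].
#' @export
default_signal_params <- function(noise_sd = 0.03) {
  tilt <- 15 * pi / 180
  list(
    lying     = signal_params(c(0, 0, 1), noise_sd = noise_sd),
    sitting   = signal_params(c(sin(tilt), cos(tilt), 0), noise_sd = noise_sd),
    standing  = signal_params(c(0, 1, 0), noise_sd = noise_sd),
    walk_slow = signal_params(c(0, 1, 0), 1.6, 0.25, noise_sd = noise_sd),
    walk_fast = signal_params(c(0, 1, 0), 2.2, 0.45, noise_sd = noise_sd),
    running   = signal_params(c(0, 1, 0), 3.0, 0.80, noise_sd = noise_sd),
    non_wear  = signal_params(table_orientations()[[1]], noise_sd = 0.001,
                              table_position = 1L)
  )
}
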