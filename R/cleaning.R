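#' @importFrom stats median sd setNames predict
NULL

flag_levels <- function() {
  c("original", "reclassified_to_nonwear", "reclassified_to_sedentary",
    "outside_wake_window")
}

# Promote labelled epochs to the cleaned representation (provenance flag +
# retention indicator) without changing anything.
as_cleaned <- function(epochs) {
  if (inherits(epochs, "cleaned_epochs")) return(epochs)
  epochs$flag <- factor("original", levels = flag_levels())
  epochs$retained <- TRUE
  class(epochs) <- c("cleaned_epochs", class(epochs))
  epochs
}

#' @export
print.cleaned_epochs <- function(x, ...) {
  cat(sprintf("<cleaned_epochs> %d epochs of %g s (%d retained)\n", nrow(x),
              attr(x, "epoch_seconds"), sum(x$retained)))
  print(table(flag = x$flag))
  invisible(x)
}

#' Consolidate non-wear time
#'
#' First of the three cleaning steps applied to classified epochs. Short
#' bursts of apparent activity embedded in long stretches of non-wear are
#' spurious (e.g. the device being nudged on the table) and are
#' re-classified as non-wear; conversely, short isolated runs of non-wear
#' are very steady sedentary behaviour and are re-classified as sitting.
#'
#' Formally, an activity epoch becomes non-wear if and only if it lies in
#' some interval whose two endpoints are non-wear epochs, in which every
#' embedded activity burst lasts at most `tolerance` minutes, the embedded
#' activity totals at most `tolerance` minutes, and the non-wear content is
#' at least `window` minutes. After this merge, any remaining maximal
#' non-wear run shorter than `window` minutes becomes sitting. Epoch count
#' and timing are never changed, and every re-classification is flagged.
#'
#' @param epochs A [labeled_epochs()] (or already-cleaned) object on a
#'   contiguous epoch grid.
#' @param window Minimum length of a consolidated non-wear block, minutes
#'   (default 60).
#' @param tolerance Maximum embedded activity, per burst and in total,
#'   minutes (default 5).
#' @return A `cleaned_epochs` object with updated labels and provenance
#'   flags.
#' @export
consolidate_nonwear <- function(epochs, window = 60, tolerance = 5) {
  out <- as_cleaned(epochs)
  step <- check_epoch_grid(out)
  window_sec <- window * 60
  tol_sec <- tolerance * 60
  lab <- as.character(out$label)
  if (!length(lab)) return(out)

  r <- rle(lab == "non_wear")
  n_runs <- length(r$lengths)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  run_dur <- r$lengths * step
  spurious_run <- logical(n_runs)

  nw_idx <- which(r$values)
  for (ai in seq_along(nw_idx)) {
    a <- nw_idx[ai]
    act_sum <- 0
    nw_sum <- run_dur[a]
    bi <- ai
    repeat {
      if (nw_sum >= window_sec && bi > ai) {
        spurious_run[seq(a + 1L, nw_idx[bi] - 1L)] <- TRUE
      }
      if (bi == length(nw_idx)) break
      gap <- seq(nw_idx[bi] + 1L, nw_idx[bi + 1L] - 1L)
      gap_dur <- sum(run_dur[gap])
      if (gap_dur > tol_sec || act_sum + gap_dur > tol_sec) break
      act_sum <- act_sum + gap_dur
      bi <- bi + 1L
      nw_sum <- nw_sum + run_dur[nw_idx[bi]]
    }
  }
  # step (a): spurious activity becomes non-wear
  for (k in which(spurious_run)) {
    ix <- run_start[k]:run_end[k]
    lab[ix] <- "non_wear"
    out$flag[ix] <- "reclassified_to_nonwear"
  }
  # step (b): remaining short non-wear runs become sedentary (sitting)
  r2 <- rle(lab == "non_wear")
  end2 <- cumsum(r2$lengths)
  start2 <- end2 - r2$lengths + 1L
  for (k in which(r2$values & r2$lengths * step < window_sec)) {
    ix <- start2[k]:end2[k]
    lab[ix] <- "sitting"
    out$flag[ix] <- "reclassified_to_sedentary"
  }
  out$label <- factor(lab, levels = activity_kinds())
  out
}

#' Restrict epochs to the self-reported wake window
#'
#' Second cleaning step: each morning the child reports when they went to
#' bed the night before and when they woke up; only epochs inside the
#' resulting wake interval of each day are analysed further. A day's window
#' is `[wake, bed)`: the wake time from that date's morning report, the bed
#' time from the following morning's report. A day missing either report
#' has no usable window and every epoch of that date is excluded.
#'
#' @param epochs A [labeled_epochs()] or `cleaned_epochs` object of one
#'   child.
#' @param sleep Sleep-diary data.frame with columns `child_id`, `date`,
#'   `bed_time`, `wake_time` (one morning report per row; `bed_time` refers
#'   to the night before `date`).
#' @return A `cleaned_epochs` object in which epochs outside the wake
#'   window are flagged `outside_wake_window` and not retained.
#' @export
restrict_to_wake_window <- function(epochs, sleep) {
  out <- as_cleaned(epochs)
  if (!nrow(out)) return(out)
  child <- unique(as.character(out$child_id))
  stopifnot(length(child) == 1)
  sl <- sleep[as.character(sleep$child_id) == child, ]
  dates <- as.Date(out$epoch_start, tz = "UTC")
  keep <- logical(nrow(out))
  for (d in as.list(unique(dates))) {
    ix <- which(dates == d)
    wake <- sl$wake_time[sl$date == d]
    bed <- sl$bed_time[sl$date == d + 1]
    if (length(wake) == 1 && length(bed) == 1 && !is.na(wake) && !is.na(bed)) {
      keep[ix] <- out$epoch_start[ix] >= wake & out$epoch_start[ix] < bed
    }
  }
  out$flag[!keep] <- "outside_wake_window"
  out$retained <- out$retained & keep
  out
}

#' Daily wear time and valid-day screening
#'
#' Third cleaning step: wear time of a day is 2.5 s times the number of
#' retained wake-window epochs not labelled non-wear; a day is valid when
#' the device was worn at least `min_hours` (default 6) hours. Only valid
#' days enter the daily summaries and models.
#'
#' @param epochs A `cleaned_epochs` object of one child (any number of
#'   days).
#' @param min_hours Valid-day threshold in hours, inclusive.
#' @return Data.frame with one row per calendar date: `child_id`, `date`,
#'   `wear_hours`, `valid`.
#' @export
summarize_wear <- function(epochs, min_hours = 6) {
  stopifnot(inherits(epochs, "cleaned_epochs"))
  step <- epoch_step(epochs)
  dates <- as.Date(epochs$epoch_start, tz = "UTC")
  child <- as.character(epochs$child_id)
  worn <- epochs$retained & epochs$label != "non_wear"
  agg <- stats::aggregate(worn, by = list(child_id = child, date = dates), sum)
  out <- data.frame(child_id = agg$child_id, date = agg$date,
                    wear_hours = agg$x * step / 3600)
  out$valid <- out$wear_hours >= min_hours
  out[order(out$child_id, out$date), , drop = FALSE]
}
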