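# Shared fixtures and independent oracles, built in code at test time.

t0 <- function() as.POSIXct("2012-05-07 00:00:00", tz = "UTC")

# Epoch object from a label vector on a regular grid.
make_epochs <- function(labels, step = 2.5, start = t0() + 7 * 3600,
                        child_id = "C01") {
  labeled_epochs(child_id, start + (seq_along(labels) - 1) * step, labels,
                 epoch_seconds = step)
}

# Literal O(n^2) enumeration of the non-wear consolidation rule, the
# independent oracle for consolidate_nonwear(): an activity epoch is
# spurious iff some interval with non-wear endpoints contains it with every
# embedded activity run <= tol, total embedded activity <= tol and non-wear
# content >= window; afterwards short non-wear runs become sitting.
oracle_consolidate <- function(labels, step, window = 60, tolerance = 5) {
  n <- length(labels)
  nw <- labels == "non_wear"
  win_s <- window * 60; tol_s <- tolerance * 60
  spurious <- logical(n)
  for (i in seq_len(n)) {
    if (!nw[i]) next
    for (j in i:n) {
      if (!nw[j]) next
      seg <- nw[i:j]
      r <- rle(seg)
      act_runs <- r$lengths[!r$values] * step
      if ((length(act_runs) == 0 ||
           (max(act_runs) <= tol_s && sum(act_runs) <= tol_s)) &&
          sum(seg) * step >= win_s) {
        spurious[(i:j)[!seg]] <- TRUE
      }
    }
  }
  out <- labels
  out[spurious] <- "non_wear"
  r <- rle(out == "non_wear")
  ends <- cumsum(r$lengths)
  for (k in which(r$values & r$lengths * step < win_s)) {
    out[(ends[k] - r$lengths[k] + 1):ends[k]] <- "sitting"
  }
  out
}

# All label sequences of a given length over {non_wear, sitting}.
all_nw_sequences <- function(len) {
  grid <- expand.grid(rep(list(c("non_wear", "sitting")), len),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, ], use.names = FALSE))
}

# Zero-noise signal parameters: disjoint class supports in feature space.
zero_noise_params <- function() {
  p <- default_signal_params(noise_sd = 0)
  p$non_wear <- signal_params(table_orientations()[[1]], noise_sd = 0,
                              table_position = 1L)
  p
}

table_orientations <- actiflux:::table_orientations

# Balanced one-way panel with known variance components.
vc_panel <- function(n_children, n_days, var_between, var_within, seed) {
  set.seed(seed)
  child <- rep(sprintf("C%03d", seq_len(n_children)), each = n_days)
  u <- rep(stats::rnorm(n_children, sd = sqrt(var_between)), each = n_days)
  data.frame(child_id = child,
             date = as.Date("2012-05-07") + rep(seq_len(n_days) - 1,
                                                n_children),
             y = u + stats::rnorm(n_children * n_days, sd = sqrt(var_within)))
}
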