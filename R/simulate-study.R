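#' Parameters of the daily-affect data-generating process
#'
#' The two-level model that generates (and is later fitted to) daily affect:
#' for child i on day t,
#' \deqn{Affect_{ti} = \beta_{0i} + \beta_{1i} Trend_{ti} + \beta_{2i} PA_i +
#'   \beta_{3i} PA_{ti} + \epsilon_{ti}}
#' with \eqn{\beta_{0i} = \gamma_{00} + \sigma_{0i}},
#' \eqn{\beta_{1i} = \gamma_{10} + \sigma_{1i}},
#' \eqn{\beta_{2i} = \gamma_{20}},
#' \eqn{\beta_{3i} = \gamma_{30} + \sigma_{3i}}, where `PA_i` is the child's
#' average activity over the study, `PA_ti` the day's deviation from that
#' average, and `Trend_ti` the day index (0 on each child's first study day).
#' The random intercept and random trend are correlated
#' (`cov_sigma0_sigma1`); the random daily-activity slope is independent of
#' both.
#'
#' @param gamma00,gamma10,gamma20,gamma30 Fixed effects (affect-scale units;
#'   `gamma10` per day; `gamma20`, `gamma30` per unit of the activity
#'   proportion).
#' @param var_sigma0,var_sigma1,var_sigma3 Random-effect variances (>= 0).
#' @param cov_sigma0_sigma1 Covariance of random intercept and random trend;
#'   the implied 2x2 matrix must be positive semidefinite.
#' @param var_epsilon Day-level residual variance (>= 0).
#' @return An object of class `affect_dgp`.
#' @export
affect_dgp <- function(gamma00, gamma10, gamma20, gamma30,
                       var_sigma0, var_sigma1, var_sigma3,
                       cov_sigma0_sigma1 = 0, var_epsilon = 0.3) {
  if (var_sigma0 < 0 || var_sigma1 < 0 || var_sigma3 < 0 || var_epsilon < 0) {
    stop("variances must be >= 0")
  }
  if (cov_sigma0_sigma1^2 > var_sigma0 * var_sigma1 + 1e-12) {
    stop("intercept/trend covariance matrix is not positive semidefinite")
  }
  structure(list(gamma00 = gamma00, gamma10 = gamma10, gamma20 = gamma20,
                 gamma30 = gamma30, var_sigma0 = var_sigma0,
                 var_sigma1 = var_sigma1, var_sigma3 = var_sigma3,
                 cov_sigma0_sigma1 = cov_sigma0_sigma1,
                 var_epsilon = var_epsilon),
            class = "affect_dgp")
}

#' Default affect data-generating parameters, one set per factor
#'
#' Fixed effects and variance components chosen to emulate a cohort of
#' 3rd/4th graders rating affect on 1-5 Likert items: the two positive
#' dimensions (pleasantness, activation) sit high on the scale, the two
#' negative ones (unpleasantness, deactivation) low; between-child intercept
#' spread is substantial, day-to-day trends are small and slightly negative
#' for positive affect, and daily activity has at most a weak, unreliable
#' effect on any dimension. The intercept-trend correlation is fixed at
#' -0.3.
#'
#' @return Named list of four [affect_dgp()] objects
#'   (`pleasantness`, `unpleasantness`, `activation`, `deactivation`).
#' @export
default_affect_dgp <- function() {
  mk <- function(g00, g10, g20, g30, v0, v1, v3, ve) {
    affect_dgp(g00, g10, g20, g30, v0, v1, v3,
               cov_sigma0_sigma1 = -0.3 * sqrt(v0 * v1), var_epsilon = ve)
  }
  list(
    pleasantness   = mk(3.982, -0.012,  0.970,  0.054, 0.380, 0.0009, 0.000, 0.297),
    unpleasantness = mk(1.530,  0.008, -0.855, -0.231, 0.233, 0.0007, 0.229, 0.157),
    activation     = mk(3.977, -0.018, -0.552,  0.112, 0.826, 0.0010, 0.000, 0.274),
    deactivation   = mk(1.738, -0.002, -0.640, -0.258, 0.321, 0.0008, 0.000, 0.214)
  )
}

#' Assignment of the 12 affect items to the four factors
#'
#' Three items per factor, in the fixed order pleasantness (items 1-3),
#' unpleasantness (4-6), activation (7-9), deactivation (10-12).
#'
#' @return Data.frame with columns `item_id` and `factor`.
#' @export
default_item_map <- function() {
  data.frame(item_id = 1:12,
             factor = rep(c("pleasantness", "unpleasantness", "activation",
                            "deactivation"), each = 3))
}

# Bivariate normal draws given a 2x2 PSD covariance matrix.
rmvnorm2 <- function(n, sigma) {
  ev <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  L <- ev$vectors %*% diag(sqrt(lam), 2)
  t(L %*% matrix(stats::rnorm(2 * n), nrow = 2))
}

#' Simulate a child-day affect panel from the two-level model
#'
#' Draws a balanced panel directly at the day level: per-child random
#' intercept, trend and daily-activity slope, plus day residuals, around the
#' fixed effects of `dgp`. The activity covariate is drawn per child-day
#' from `pa_sampler` and entered exactly as in the fitted models: the
#' realized person mean (`pa_between`) and the daily deviation from it
#' (`pa_within`). No Likert discretization is applied; this is the
#' continuous outcome the day-level models assume.
#'
#' @param n_children,n_days Panel dimensions (each >= 2).
#' @param dgp An [affect_dgp()].
#' @param pa_sampler Function of `n` returning daily activity proportions;
#'   the default draws Beta(3, 17) values (mean 0.15, SD about 0.08).
#' @param seed Optional integer seed.
#' @return Data.frame with one row per child-day: `child_id`, `day`,
#'   `trend`, `pa`, `pa_between`, `pa_within`, `mu` (latent day mean) and
#'   `affect`; the per-child random effects are attached as the
#'   `"children"` attribute.
#' @export
simulate_affect_panel <- function(n_children, n_days, dgp,
                                  pa_sampler = function(n) stats::rbeta(n, 3, 17),
                                  seed = NULL) {
  stopifnot(inherits(dgp, "affect_dgp"), n_children >= 2, n_days >= 2)
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("C%03d", seq_len(n_children))
  re01 <- rmvnorm2(n_children,
                   matrix(c(dgp$var_sigma0, dgp$cov_sigma0_sigma1,
                            dgp$cov_sigma0_sigma1, dgp$var_sigma1), 2))
  s3 <- stats::rnorm(n_children, sd = sqrt(dgp$var_sigma3))
  pa <- matrix(pa_sampler(n_children * n_days), nrow = n_children)
  pa_bar <- rowMeans(pa)
  day <- rep(seq_len(n_days) - 1L, times = n_children)
  child <- rep(seq_len(n_children), each = n_days)
  pa_t <- as.vector(t(pa))
  pa_w <- pa_t - pa_bar[child]
  mu <- dgp$gamma00 + re01[child, 1] +
    (dgp$gamma10 + re01[child, 2]) * day +
    dgp$gamma20 * pa_bar[child] +
    (dgp$gamma30 + s3[child]) * pa_w
  affect <- mu + stats::rnorm(length(mu), sd = sqrt(dgp$var_epsilon))
  out <- data.frame(child_id = ids[child], day = day, trend = day,
                    pa = pa_t, pa_between = pa_bar[child], pa_within = pa_w,
                    mu = mu, affect = affect)
  attr(out, "children") <- data.frame(child_id = ids, sigma0 = re01[, 1],
                                      sigma1 = re01[, 2], sigma3 = s3)
  out
}

# Default bout mixture of a child's waking day. Probabilities and mean bout
# durations (minutes) give roughly 13% of worn time active with roughly a
# quarter of active time spent running.
default_bout_mix <- function() {
  data.frame(
    kind = c("lying", "sitting", "standing", "walk_slow", "walk_fast",
             "running", "non_wear"),
    prob = c(0.05, 0.33, 0.22, 0.15, 0.10, 0.08, 0.07),
    mean_min = c(15, 15, 5, 3.5, 2.5, 3, 30)
  )
}

# Random bout schedule filling duration_sec; durations are exponential with
# the mixture means, rounded up to the 2.5 s epoch grid, truncated to fit.
draw_schedule <- function(duration_sec, mix = default_bout_mix(),
                          frame_length = 2.5) {
  kinds <- character(0); durs <- numeric(0); left <- duration_sec
  while (left > 0) {
    k <- sample(mix$kind, 1, prob = mix$prob)
    d <- stats::rexp(1, rate = 1 / (60 * mix$mean_min[mix$kind == k]))
    d <- max(frame_length, round(d / frame_length) * frame_length)
    d <- min(d, left)
    kinds <- c(kinds, k); durs <- c(durs, d); left <- left - d
  }
  data.frame(kind = kinds, duration = durs)
}

#' Simulate a complete ambulatory study
#'
#' Generates every input the analysis chain consumes, for `n_children`
#' children observed over `n_days` consecutive days: per-child-day activity
#' schedules inside a self-reported wake window (7:00 +/- 30 min to 21:00
#' +/- 30 min), a sleep diary of morning reports (each giving that
#' morning's wake time and the previous night's bed time, so `n_days + 1`
#' reports cover every study day), 12 Likert items at 4 occasions per day
#' generated from the two-level affect model with the schedule-derived
#' daily activity as predictor, and ground-truth day tables. Raw 30 Hz
#' traces are not materialized here; [realize_trace()] builds the trace of
#' any child-day reproducibly from stored per-day seeds.
#'
#' Each day's schedule is flanked by 65 min of device-on-table non-wear
#' before wake and after bed, so the overnight non-wear edge is present in
#' every realized trace.
#'
#' @param n_children,n_days Study dimensions (each >= 2).
#' @param dgp A single [affect_dgp()] applied to all four affect factors, or
#'   a named list with one element per factor (default
#'   [default_affect_dgp()]).
#' @param seed Integer seed driving all randomness.
#' @param start_date First study date.
#' @param schedule_generator Function `(duration_sec)` returning a
#'   data.frame of `kind`/`duration` bouts; default [draw_schedule()] with
#'   the standard mixture.
#' @param reference_fraction Share of children who take part in the
#'   reference measurement (the rest are classified with the pooled model).
#' @param item_noise_sd SD of the item-level Gaussian noise added to the
#'   day's latent factor mean before rounding/clipping to the 1-5 scale.
#' @param params_per_kind Signal parameters per activity class.
#' @param rate Sampling rate in Hz.
#' @return An object of class `actiflux_study`: a list with elements
#'   `children`, `sleep`, `schedule`, `affect_items`, `truth_days`,
#'   `truth_children`, and `params`.
#' @export
simulate_study <- function(n_children, n_days, dgp = default_affect_dgp(),
                           seed = 1, start_date = as.Date("2012-05-07"),
                           schedule_generator = NULL,
                           reference_fraction = 0.8, item_noise_sd = 0.4,
                           params_per_kind = default_signal_params(),
                           rate = 30) {
  stopifnot(n_children >= 2, n_days >= 2)
  if (inherits(dgp, "affect_dgp")) {
    dgp <- stats::setNames(rep(list(dgp), 4), default_item_map()$factor[c(1, 4, 7, 10)])
  }
  stopifnot(all(c("pleasantness", "unpleasantness", "activation",
                  "deactivation") %in% names(dgp)))
  for (d in dgp) stopifnot(inherits(d, "affect_dgp"))
  if (is.null(schedule_generator)) schedule_generator <- draw_schedule
  set.seed(seed)
  ids <- sprintf("C%02d", seq_len(n_children))
  dates <- start_date + seq_len(n_days) - 1
  n_ref <- max(2L, round(reference_fraction * n_children))
  ref_ids <- sort(sample(seq_len(n_children), min(n_ref, n_children)))
  children <- data.frame(
    child_id = ids,
    has_reference = seq_len(n_children) %in% ref_ids,
    ref_seed = sample.int(.Machine$integer.max - 1L, n_children)
  )

  # Wake windows and sleep diary (n_days + 1 morning reports per child).
  mins <- function(n) stats::runif(n, -30, 30) * 60
  sleep <- list(); sched <- list(); truth <- list()
  pa_true <- matrix(NA_real_, n_children, n_days)
  day_seed <- matrix(sample.int(.Machine$integer.max - 1L,
                                n_children * n_days),
                     n_children, n_days)
  pad <- 65 * 60  # device-on-table flank, seconds
  for (i in seq_len(n_children)) {
    wake <- as.POSIXct(paste(dates, "07:00:00"), tz = "UTC") + mins(n_days)
    bed <- as.POSIXct(paste(dates, "21:00:00"), tz = "UTC") + mins(n_days)
    bed_prev <- as.POSIXct(paste(start_date - 1, "21:00:00"), tz = "UTC") +
      mins(1)
    sleep[[i]] <- data.frame(
      child_id = ids[i],
      date = c(dates, dates[n_days] + 1),
      bed_time = c(bed_prev, bed),
      wake_time = c(wake, as.POSIXct(paste(dates[n_days] + 1, "07:00:00"),
                                     tz = "UTC"))
    )
    for (t in seq_len(n_days)) {
      window <- as.numeric(bed[t]) - as.numeric(wake[t])
      window <- floor(window / 2.5) * 2.5
      sc <- schedule_generator(window)
      sc <- rbind(data.frame(kind = "non_wear", duration = pad), sc,
                  data.frame(kind = "non_wear", duration = pad))
      sc$child_id <- ids[i]
      sc$date <- dates[t]
      sc$start_time <- wake[t] - pad + c(0, cumsum(sc$duration[-nrow(sc)]))
      sched[[length(sched) + 1L]] <- sc
      bout_end <- as.numeric(sc$start_time) + sc$duration
      overlap <- pmax(0, pmin(bout_end, as.numeric(bed[t])) -
                        pmax(as.numeric(sc$start_time), as.numeric(wake[t])))
      cat_min <- tapply(overlap / 60, behavior_category(sc$kind), sum,
                        default = 0)
      cat_min[is.na(cat_min)] <- 0
      wear <- sum(cat_min[c("sedentary", "inactive", "mvpa", "very_vigorous")])
      active <- sum(cat_min[c("mvpa", "very_vigorous")])
      pa_true[i, t] <- if (wear > 0) active / wear else 0
      truth[[length(truth) + 1L]] <- data.frame(
        child_id = ids[i], date = dates[t], day_index = t - 1L,
        sedentary_min = cat_min[["sedentary"]],
        inactive_min = cat_min[["inactive"]],
        mvpa_min = cat_min[["mvpa"]],
        vigorous_min = cat_min[["very_vigorous"]],
        nonwear_min = cat_min[["non_wear"]],
        wear_min = wear, pa_true = pa_true[i, t],
        vigorous_share_true = if (active > 0) cat_min[["very_vigorous"]] / active else 0,
        trace_seed = day_seed[i, t]
      )
    }
  }
  sleep <- do.call(rbind, sleep)
  sched <- do.call(rbind, sched)
  truth <- do.call(rbind, truth)

  # Daily affect from the two-level model, per factor, then item responses.
  pa_bar <- rowMeans(pa_true)
  child_ix <- match(truth$child_id, ids)
  truth_children <- data.frame(child_id = ids, pa_between_true = pa_bar)
  items <- default_item_map()
  resp <- list()
  for (f in names(dgp)) {
    p <- dgp[[f]]
    re01 <- rmvnorm2(n_children,
                     matrix(c(p$var_sigma0, p$cov_sigma0_sigma1,
                              p$cov_sigma0_sigma1, p$var_sigma1), 2))
    s3 <- stats::rnorm(n_children, sd = sqrt(p$var_sigma3))
    mu <- p$gamma00 + re01[child_ix, 1] +
      (p$gamma10 + re01[child_ix, 2]) * truth$day_index +
      p$gamma20 * pa_bar[child_ix] +
      (p$gamma30 + s3[child_ix]) * (truth$pa_true - pa_bar[child_ix])
    eps <- stats::rnorm(nrow(truth), sd = sqrt(p$var_epsilon))
    truth[[paste0(f, "_true")]] <- mu + eps
    truth_children[[paste0("sigma0_", f)]] <- re01[, 1]
    item_ids <- items$item_id[items$factor == f]
    n_rows <- nrow(truth) * 4L * 3L
    r <- data.frame(
      child_id = rep(truth$child_id, each = 12L),
      date = rep(truth$date, each = 12L),
      occasion = rep(rep(1:4, each = 3L), times = nrow(truth)),
      item_id = rep(item_ids, times = nrow(truth) * 4L)
    )
    raw <- rep(truth[[paste0(f, "_true")]], each = 12L) +
      stats::rnorm(n_rows, sd = item_noise_sd)
    r$response <- pmin(pmax(round(raw), 1L), 5L)
    resp[[f]] <- r
  }
  affect_items <- do.call(rbind, resp)
  affect_items <- affect_items[order(affect_items$child_id, affect_items$date,
                                     affect_items$occasion,
                                     affect_items$item_id), ]
  rownames(affect_items) <- NULL
  rownames(truth) <- NULL

  structure(list(children = children, sleep = sleep, schedule = sched,
                 affect_items = affect_items, truth_days = truth,
                 truth_children = truth_children,
                 params = list(rate = rate, frame_length = 2.5,
                               params_per_kind = params_per_kind, dgp = dgp,
                               item_map = items, seed = seed,
                               item_noise_sd = item_noise_sd, pad = pad)),
            class = "actiflux_study")
}

#' @export
print.actiflux_study <- function(x, ...) {
  cat(sprintf("<actiflux_study> %d children x %d days (seed %d)\n",
              nrow(x$children), length(unique(x$truth_days$date)),
              x$params$seed))
  cat(sprintf("  %d with reference sessions; %d affect item responses\n",
              sum(x$children$has_reference), nrow(x$affect_items)))
  invisible(x)
}

#' Materialize the raw trace of one child-day
#'
#' Rebuilds the 30 Hz triaxial trace of a simulated child-day from the
#' study's stored schedule and per-day seed; the same `(study, child, date)`
#' always yields the identical trace.
#'
#' @param study An [simulate_study()] result.
#' @param child_id Child identifier.
#' @param date Study date (coercible to `Date`).
#' @return An [accel_trace()] covering the scheduled day, including the
#'   device-on-table flanks before wake and after bed.
#' @export
realize_trace <- function(study, child_id, date) {
  date <- as.Date(date)
  sc <- study$schedule[study$schedule$child_id == child_id &
                         study$schedule$date == date, ]
  if (!nrow(sc)) stop("no schedule for ", child_id, " on ", format(date))
  tr <- study$truth_days[study$truth_days$child_id == child_id &
                           study$truth_days$date == date, ]
  set.seed(tr$trace_seed)
  rate <- study$params$rate
  pk <- study$params$params_per_kind
  xyz <- vector("list", nrow(sc))
  for (b in seq_len(nrow(sc))) {
    n <- round(sc$duration[b] * rate)
    xyz[[b]] <- simulate_bout_samples(sc$kind[b], n, pk[[sc$kind[b]]], rate)
  }
  xyz <- do.call(rbind, xyz)
  time <- sc$start_time[1] + (seq_len(nrow(xyz)) - 1) / rate
  accel_trace(time, xyz, child_id = child_id, rate = rate)
}

#' Ground-truth epoch labels of one simulated child-day
#'
#' Expands the stored bout schedule to the 2.5 s epoch grid, giving the
#' labels a perfect classifier would produce on [realize_trace()] output.
#'
#' @inheritParams realize_trace
#' @return A [labeled_epochs()] object.
#' @export
true_epochs <- function(study, child_id, date) {
  date <- as.Date(date)
  sc <- study$schedule[study$schedule$child_id == child_id &
                         study$schedule$date == date, ]
  if (!nrow(sc)) stop("no schedule for ", child_id, " on ", format(date))
  fl <- study$params$frame_length
  n_ep <- round(sc$duration / fl)
  labels <- rep(sc$kind, n_ep)
  epoch_start <- sc$start_time[1] + (seq_along(labels) - 1) * fl
  labeled_epochs(child_id, epoch_start, labels, epoch_seconds = fl)
}
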