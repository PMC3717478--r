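test_that("consolidation matches the brute-force rule on coarse sequences", {
  # 10-minute epochs; tolerance 15 min lets single-epoch bursts be absorbed,
  # tolerance 5 min lets none - both settings must match the enumeration
  for (tol in c(15, 5)) {
    for (len in c(1:8)) {
      for (labs in all_nw_sequences(len)) {
        got <- consolidate_nonwear(make_epochs(labs, step = 600),
                                   window = 60, tolerance = tol)
        want <- oracle_consolidate(labs, step = 600, window = 60,
                                   tolerance = tol)
        expect_equal(as.character(got$label), want,
                     label = paste(tol, paste(labs, collapse = ",")))
      }
    }
  }
})

test_that("consolidation matches the oracle on mixed random days", {
  set.seed(99)
  kinds <- activity_kinds()
  for (rep in 1:60) {
    labs <- sample(kinds, 12, replace = TRUE,
                   prob = c(rep(0.1, 6), 0.4))
    got <- consolidate_nonwear(make_epochs(labs, step = 600),
                               window = 60, tolerance = 15)
    want <- oracle_consolidate(labs, step = 600, window = 60, tolerance = 15)
    expect_equal(as.character(got$label), want)
  }
})

test_that("short activity bursts inside an hour of non-wear are absorbed", {
  # 70 min non-wear with a 4 min walking burst inside -> all 74 min non-wear
  labs <- c(rep("non_wear", 40 * 24), rep("walk_slow", 4 * 24),
            rep("non_wear", 30 * 24))
  out <- consolidate_nonwear(make_epochs(labs))
  expect_true(all(out$label == "non_wear"))
  expect_equal(sum(out$flag == "reclassified_to_nonwear"), 4 * 24)
  # a 6 min burst exceeds the tolerance and survives
  labs2 <- c(rep("non_wear", 40 * 24), rep("walk_slow", 6 * 24),
             rep("non_wear", 30 * 24))
  out2 <- consolidate_nonwear(make_epochs(labs2))
  expect_equal(sum(out2$label == "walk_slow"), 6 * 24)
})

test_that("short isolated non-wear becomes sedentary sitting", {
  labs <- c(rep("sitting", 240), rep("non_wear", 30 * 24), rep("sitting", 240))
  out <- consolidate_nonwear(make_epochs(labs))
  expect_true(all(out$label == "sitting"))
  expect_equal(sum(out$flag == "reclassified_to_sedentary"), 30 * 24)
})

test_that("a day without non-wear labels is a fixpoint", {
  labs <- rep(c("sitting", "walk_fast", "standing"), 100)
  out <- consolidate_nonwear(make_epochs(labs))
  expect_equal(as.character(out$label), labs)
  expect_true(all(out$flag == "original"))
})

test_that("consolidation conserves epochs and is idempotent", {
  set.seed(5)
  for (rep in 1:40) {
    labs <- sample(activity_kinds(), 150, replace = TRUE,
                   prob = c(0.05, 0.3, 0.1, 0.05, 0.05, 0.05, 0.4))
    ep <- make_epochs(labs, step = 60)  # 1-min epochs, fast but non-trivial
    once <- consolidate_nonwear(ep)
    expect_equal(nrow(once), length(labs))
    expect_identical(once$epoch_start, ep$epoch_start)
    twice <- consolidate_nonwear(once)
    expect_equal(as.character(twice$label), as.character(once$label))
  }
})

test_that("turning wear into non-wear never increases wear duration", {
  set.seed(8)
  sleep_all <- data.frame(child_id = "C01",
                          date = as.Date(c("2012-05-07", "2012-05-08")),
                          bed_time = as.POSIXct(c("2012-05-06 21:00:00",
                                                  "2012-05-07 23:59:00"),
                                                tz = "UTC"),
                          wake_time = as.POSIXct(c("2012-05-07 00:00:00",
                                                   "2012-05-08 07:00:00"),
                                                 tz = "UTC"))
  for (rep in 1:20) {
    labs <- sample(activity_kinds(), 200, replace = TRUE,
                   prob = c(0.05, 0.3, 0.1, 0.05, 0.05, 0.05, 0.4))
    wear_of <- function(l) {
      cl <- restrict_to_wake_window(consolidate_nonwear(
        make_epochs(l, step = 60, start = t0())), sleep_all)
      summarize_wear(cl)$wear_hours
    }
    base <- wear_of(labs)
    flip <- labs
    flip[sample(which(labs != "non_wear"), 1)] <- "non_wear"
    expect_lte(wear_of(flip), base)
  }
})

test_that("the wake window is half-open and diary-defined", {
  # full day of sitting at 2.5 s; wake 07:00, bed 21:00 -> 20160 epochs
  labs <- rep("sitting", 34560)
  ep <- make_epochs(labs, step = 2.5, start = t0())
  sleep <- data.frame(child_id = "C01", date = as.Date(c("2012-05-07",
                                                         "2012-05-08")),
                      bed_time = as.POSIXct(c("2012-05-06 21:30:00",
                                              "2012-05-07 21:00:00"),
                                            tz = "UTC"),
                      wake_time = as.POSIXct(c("2012-05-07 07:00:00",
                                               "2012-05-08 07:15:00"),
                                             tz = "UTC"))
  out <- restrict_to_wake_window(ep, sleep)
  expect_equal(sum(out$retained), 14 * 3600 / 2.5)
  ret <- out$epoch_start[out$retained]
  expect_equal(min(ret), as.POSIXct("2012-05-07 07:00:00", tz = "UTC"))
  expect_equal(max(ret), as.POSIXct("2012-05-07 20:59:57.5", tz = "UTC"))
  expect_true(all(out$flag[!out$retained] == "outside_wake_window"))
})

test_that("a day without a sleep report keeps no epochs and is invalid", {
  labs <- rep("walk_slow", 5760)  # 4 h
  ep <- make_epochs(labs, step = 2.5, start = t0() + 8 * 3600)
  out <- restrict_to_wake_window(ep, data.frame(
    child_id = "C01", date = as.Date("2012-05-09"),
    bed_time = as.POSIXct("2012-05-08 21:00:00", tz = "UTC"),
    wake_time = as.POSIXct("2012-05-09 07:00:00", tz = "UTC")))
  expect_equal(sum(out$retained), 0)
  ws <- summarize_wear(out)
  expect_false(ws$valid)
  expect_equal(ws$wear_hours, 0)
})

test_that("the 6 h valid-day bound is inclusive", {
  day_of <- function(hours) {
    labs <- rep("standing", round(hours * 3600 / 2.5))
    as_cl <- restrict_to_wake_window(
      make_epochs(labs, step = 2.5, start = t0() + 7 * 3600),
      data.frame(child_id = "C01",
                 date = as.Date(c("2012-05-07", "2012-05-08")),
                 bed_time = as.POSIXct(c("2012-05-06 21:00:00",
                                         "2012-05-07 21:00:00"), tz = "UTC"),
                 wake_time = as.POSIXct(c("2012-05-07 07:00:00",
                                          "2012-05-08 07:00:00"), tz = "UTC")))
    summarize_wear(as_cl)
  }
  expect_true(day_of(11.5)$valid)            # a typical compliant day
  expect_true(day_of(6)$valid)               # exactly 6.0 h counts
  expect_false(day_of(5 + 59 / 60)$valid)    # 5 h 59 min does not
})
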