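test_that("zero-noise postures reproduce the gravity orientation exactly", {
  p <- signal_params(c(0, 1, 0))
  tr <- simulate_activity_trace("standing", 2.5, params = p, seed = 1)
  expect_equal(nrow(tr), 75)
  expect_true(all(tr$x == 0 & tr$y == 1 & tr$z == 0))
})

test_that("gait sinusoid has the closed-form vertical variance", {
  # population variance of a sinusoid of amplitude a sampled over an
  # integer number of cycles is a^2/2; brute-force sum as cross-check
  p <- signal_params(c(0, 1, 0), gait_frequency = 3, gait_amplitude = 0.8)
  tr <- simulate_activity_trace("running", 60, params = p, seed = 4)
  v_pop <- mean(tr$y^2) - mean(tr$y)^2
  expect_equal(v_pop, 0.8^2 / 2, tolerance = 1e-10)
  # anterior axis carries half the amplitude
  expect_equal(mean(tr$x^2) - mean(tr$x)^2, 0.4^2 / 2, tolerance = 1e-10)
})

test_that("a device at rest on the table is almost motionless", {
  tr <- simulate_activity_trace("non_wear", 10,
                                params = default_signal_params()$non_wear,
                                seed = 2)
  expect_lt(max(sd(tr$x), sd(tr$y), sd(tr$z)), 0.01)
})

test_that("traces are clipped to the -6..+6 g device range", {
  p <- signal_params(c(0, 1, 0), noise_sd = 5)
  tr <- simulate_activity_trace("standing", 30, params = p, seed = 3)
  expect_true(all(abs(as.matrix(tr[, c("x", "y", "z")])) <= 6))
  expect_gt(max(tr$y), 5.9)  # clipping actually engaged
})

test_that("trace simulation is deterministic in the seed", {
  a <- simulate_activity_trace("walk_fast", 20, seed = 11)
  b <- simulate_activity_trace("walk_fast", 20, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a$y,
                         simulate_activity_trace("walk_fast", 20, seed = 12)$y))
})

test_that("trace simulation rejects bad input", {
  expect_error(simulate_activity_trace("flying", 10), "arg")
  expect_error(simulate_activity_trace("standing", -1), "positive")
  expect_error(signal_params(c(0, 2, 0)), "unit vector")
  expect_error(signal_params(c(0, 1, 0), gait_amplitude = 0.5), "gait_amplitude")
})

test_that("reference sessions align labels to the 2.5 s epoch grid", {
  ses <- simulate_reference_session("C01", seed = 5)
  expect_equal(nrow(ses$trace), 420 * 30)
  expect_equal(nrow(ses$epochs), 168)
  expect_setequal(as.character(unique(ses$epochs$label)), activity_kinds())
  # same seed twice: bit-identical
  expect_identical(ses, simulate_reference_session("C01", seed = 5))
  expect_error(
    simulate_reference_session("C01",
      protocol = data.frame(kind = activity_kinds()[-7], duration = 60)),
    "missing label")
  expect_error(
    simulate_reference_session("C01",
      protocol = data.frame(kind = activity_kinds(), duration = 61)),
    "multiples")
})

test_that("a deterministic affect DGP reduces to its fixed part", {
  dgp <- affect_dgp(3, 0.1, 2, 0, 0, 0, 0, 0, var_epsilon = 0)
  pan <- simulate_affect_panel(4, 5, dgp, seed = 9)
  expect_equal(pan$mu, 3 + 0.1 * pan$trend + 2 * pan$pa_between,
               tolerance = 1e-12)
  expect_equal(pan$affect, pan$mu)
})

test_that("degenerate DGP parameters are rejected", {
  expect_error(affect_dgp(3, 0, 0, 0, -0.1, 0, 0, 0), "variances")
  expect_error(affect_dgp(3, 0, 0, 0, 0.1, 0.001, 0, 0.5), "semidefinite")
})

test_that("simulated person intercepts match the requested variance", {
  dgp <- affect_dgp(3.9, -0.01, 0.5, 0.2, var_sigma0 = 0.4,
                    var_sigma1 = 0.001, var_sigma3 = 0.02,
                    cov_sigma0_sigma1 = -0.005, var_epsilon = 0.3)
  pan <- simulate_affect_panel(600, 5, dgp, seed = 21)
  kids <- attr(pan, "children")
  expect_lt(abs(var(kids$sigma0) - 0.4) / 0.4, 0.1)
})

test_that("a full study emits consistent diaries, items and ground truth", {
  st <- simulate_study(2, 2, seed = 17)
  # 2 children x 2 days x 4 occasions x 12 items
  expect_equal(nrow(st$affect_items), 2 * 2 * 4 * 12)
  expect_true(all(st$affect_items$response %in% 1:5))
  # one morning report per study day plus the morning after the last day
  expect_equal(nrow(st$sleep), 2 * 3)
  expect_true(all(st$sleep$bed_time < st$sleep$wake_time))
  expect_true(all(st$truth_days$pa_true >= 0 & st$truth_days$pa_true <= 1))
  expect_identical(st, simulate_study(2, 2, seed = 17))
  expect_error(simulate_study(1, 5), "n_children")
})

test_that("realized traces are reproducible and match their schedule", {
  st <- simulate_study(2, 2, seed = 23)
  d <- st$truth_days$date[1]
  tr1 <- realize_trace(st, "C01", d)
  expect_identical(tr1, realize_trace(st, "C01", d))
  ep <- true_epochs(st, "C01", d)
  expect_equal(nrow(tr1), nrow(ep) * 75)
  expect_true(all(abs(as.matrix(tr1[, c("x", "y", "z")])) <= 6))
})
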