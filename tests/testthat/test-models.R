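panel_design <- function(n_children = 40, n_days = 10, seed = 1,
                         g30 = 0.5, v3 = 0.02) {
  dgp <- affect_dgp(3.9, -0.012, 0.97, g30, 0.38, 0.0009, v3, -0.005, 0.297)
  pan <- simulate_affect_panel(n_children, n_days, dgp, seed = seed)
  pan$date <- as.Date("2012-05-07") + pan$day
  pan$pa_fraction <- pan$pa
  build_design(pan, "affect", "pa_fraction")
}

test_that("person-mean centering splits PA into between and within parts", {
  days <- data.frame(child_id = rep(c("A", "B"), each = 3),
                     date = rep(as.Date("2012-05-07") + 0:2, 2),
                     y = rnorm(6),
                     pa_fraction = c(0.1, 0.2, 0.3, 0.4, 0.4, 0.4))
  d <- build_design(days, "y", "pa_fraction")
  a <- d[d$child_id == "A", ]
  expect_equal(unique(a$pa_between), 0.2)
  expect_equal(a$pa_within, c(-0.1, 0, 0.1))
  expect_equal(a$trend, c(0, 1, 2))
  # every child's within deviations average to zero
  expect_lt(max(abs(tapply(d$pa_within, d$child_id, mean))), 1e-10)
})

test_that("degenerate and undersized designs are flagged", {
  days <- data.frame(child_id = rep(c("A", "B"), each = 3),
                     date = rep(as.Date("2012-05-07") + 0:2, 2),
                     y = rnorm(6), pa_fraction = 0.2)
  expect_warning(d <- build_design(days, "y", "pa_fraction"), "inestimable")
  expect_true(attr(d, "degenerate"))
  expect_error(fit_hlm(d, "fixed_and_random"), "degenerate")
  expect_error(build_design(days[days$child_id == "A", ], "y", "pa_fraction"),
               "at least 2 children")
})

test_that("missing outcomes are dropped listwise before centering", {
  days <- data.frame(child_id = rep(c("A", "B"), each = 4),
                     date = rep(as.Date("2012-05-07") + 0:3, 2),
                     y = c(1, NA, 3, 4, 2, 2, NA, 2),
                     pa_fraction = c(0.1, 0.5, 0.2, 0.3, 0.2, 0.3, 0.9, 0.4))
  d <- build_design(days, "y", "pa_fraction")
  expect_equal(nrow(d), 6)
  expect_equal(unique(d$pa_between[d$child_id == "A"]), mean(c(0.1, 0.2, 0.3)))
})

test_that("the empty model recovers between and within variance", {
  pan <- vc_panel(200, 10, var_between = 0.6, var_within = 0.4, seed = 13)
  names(pan)[names(pan) == "y"] <- "affect"
  pan$pa_fraction <- 0.1 + 0.05 * rnorm(nrow(pan))
  d <- build_design(pan, "affect", "pa_fraction")
  f <- fit_hlm(d, "empty", variance_se = FALSE)
  v <- setNames(f$random$variance, f$random$component)
  expect_lt(abs(v[["var0"]] - 0.6), 0.1)
  expect_lt(abs(v[["var_e"]] - 0.4), 0.03)
})

test_that("with variances forced to zero the fit is ordinary least squares", {
  d <- panel_design(20, 8, seed = 5)
  f0 <- fit_hlm(d, "fixed_and_random", force_zero_random = TRUE)
  ols <- lm(affect ~ trend + pa_between + pa_within, data = d)
  expect_equal(f0$fixed$estimate, unname(coef(ols)), tolerance = 1e-6)
  expect_equal(f0$fixed$se, unname(sqrt(diag(vcov(ols)))), tolerance = 1e-6)
})

test_that("a zero random slope is reported at the boundary with NA SE", {
  d <- panel_design(80, 12, seed = 42, g30 = 0.2, v3 = 0)
  f <- fit_hlm(d, "fixed_and_random")
  v3 <- f$random$variance[f$random$component == "var3"]
  expect_lt(v3, 1e-6)
  expect_true(is.na(f$random$se[f$random$component == "var3"]))
  # the other components still get curvature-based SEs
  expect_false(is.na(f$random$se[f$random$component == "var0"]))
})

test_that("the model sequence runs in order with comparable ML deviances", {
  d <- panel_design(30, 8, seed = 7)
  fits <- model_sequence(d, variance_se = FALSE)
  expect_equal(names(fits), c("empty", "trend_only", "fixed_only",
                              "fixed_and_random"))
  expect_equal(unname(sapply(fits, `[[`, "model_tag")), names(fits))
  # adding the random slope cannot worsen the ML likelihood (nesting)
  expect_lte(fits$fixed_and_random$neg2loglik_ml,
             fits$fixed_only$neg2loglik_ml + 1e-6)
})

test_that("estimates are invariant to shifting PA by a constant", {
  d1 <- panel_design(30, 8, seed = 11)
  pan <- as.data.frame(d1)
  pan$pa_fraction <- pan$pa + 0.37
  pan$affect <- d1$affect
  d2 <- build_design(pan, "affect", "pa_fraction")
  # the restricted likelihood itself is exactly shift-invariant (the
  # intercept absorbs the shift); check it at several parameter points
  for (s in 1:3) {
    pars <- c(var0 = 0.3 * s, var1 = 0.001 * s, cov01 = -0.004,
              var3 = 0.01 * s, var_e = 0.3)
    expect_equal(hlm_deviance(d1, "fixed_and_random", pars),
                 hlm_deviance(d2, "fixed_and_random", pars),
                 tolerance = 1e-8)
  }
  # and the fitted optima agree to optimizer reproducibility
  f1 <- fit_hlm(d1, "fixed_and_random", variance_se = FALSE)
  f2 <- fit_hlm(d2, "fixed_and_random", variance_se = FALSE)
  g30_1 <- f1$fixed$estimate[f1$fixed$term == "pa_within"]
  g30_2 <- f2$fixed$estimate[f2$fixed$term == "pa_within"]
  expect_equal(g30_1, g30_2, tolerance = 1e-6)
  expect_equal(f1$random$variance[f1$random$component == "var3"],
               f2$random$variance[f2$random$component == "var3"],
               tolerance = 1e-5)
})

test_that("the exact block-wise REML deviance matches the fitted model", {
  for (tag in hlm_tags()) {
    d <- panel_design(25, 6, seed = 19)
    f <- fit_hlm(d, tag, variance_se = FALSE)
    pars <- setNames(f$random$variance, f$random$component)
    expect_equal(hlm_deviance(d, tag, pars, reml = TRUE), f$neg2loglik,
                 tolerance = 1e-6)
    fm <- fit_hlm(d, tag, reml = FALSE, variance_se = FALSE)
    pars_ml <- setNames(fm$random$variance, fm$random$component)
    expect_equal(hlm_deviance(d, tag, pars_ml, reml = FALSE), fm$neg2loglik,
                 tolerance = 1e-6)
    # the fit sits at a local minimum of the exact deviance
    up <- pars
    up["var0"] <- pars[["var0"]] * 1.25 + 0.01
    expect_gt(hlm_deviance(d, tag, up), f$neg2loglik)
  }
})

test_that("eight designs cover the outcome by PA-variable grid", {
  st <- simulate_study(6, 6, seed = 3)
  days <- st$truth_days
  names(days)[names(days) == "pa_true"] <- "pa_fraction"
  names(days)[names(days) == "vigorous_share_true"] <- "vigorous_share"
  for (f in c("pleasantness", "unpleasantness", "activation", "deactivation")) {
    names(days)[names(days) == paste0(f, "_true")] <- f
  }
  designs <- list()
  for (oc in c("pleasantness", "unpleasantness", "activation", "deactivation")) {
    for (pv in c("pa_fraction", "vigorous_share")) {
      designs[[paste(oc, pv)]] <- build_design(days, oc, pv)
    }
  }
  expect_length(designs, 8)
  expect_true(all(sapply(designs, inherits, "hlm_design")))
})
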