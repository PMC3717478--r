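#' Build the two-level model design for one outcome and one PA variable
#'
#' Assembles the child-day design of the affect models: the affect outcome,
#' the linear trend (days since the child's first included day, 0-origin),
#' and the person-mean-centered activity variable split into its stable
#' between-person part `pa_between` (the child's average over the study)
#' and the fluctuating within-person part `pa_within` (the day's deviation
#' from that average). Days with a missing outcome or activity value are
#' dropped listwise before centering.
#'
#' @param day_table Child-day table with columns `child_id`, `date`, the
#'   outcome, and the activity variable.
#' @param outcome Name of the affect outcome column.
#' @param pa_variable Name of the activity column (`"pa_fraction"` or
#'   `"vigorous_share"`).
#' @return An `hlm_design` data.frame with columns `child_id`, `date`,
#'   `trend`, `affect`, `pa`, `pa_between`, `pa_within`. The attribute
#'   `degenerate` is TRUE when every within-person deviation is 0 (the
#'   daily-activity effect is then inestimable).
#' @export
build_design <- function(day_table, outcome,
                         pa_variable = c("pa_fraction", "vigorous_share")) {
  pa_variable <- if (length(pa_variable) > 1) pa_variable[1] else pa_variable
  stopifnot(all(c("child_id", "date", outcome, pa_variable) %in%
                  names(day_table)))
  d <- day_table[!is.na(day_table[[outcome]]) &
                   !is.na(day_table[[pa_variable]]), , drop = FALSE]
  n_days <- table(d$child_id)
  d <- d[d$child_id %in% names(n_days)[n_days >= 2], , drop = FALSE]
  if (length(unique(d$child_id)) < 2) {
    stop("need at least 2 children with at least 2 valid days each")
  }
  d <- d[order(d$child_id, d$date), , drop = FALSE]
  first <- tapply(as.numeric(as.Date(d$date)), d$child_id, min)
  trend <- as.numeric(as.Date(d$date)) - first[as.character(d$child_id)]
  pa <- d[[pa_variable]]
  pa_bar <- tapply(pa, d$child_id, mean)
  pa_between <- pa_bar[as.character(d$child_id)]
  out <- data.frame(child_id = as.character(d$child_id),
                    date = as.Date(d$date), trend = as.numeric(trend),
                    affect = d[[outcome]], pa = pa,
                    pa_between = as.numeric(pa_between),
                    pa_within = pa - as.numeric(pa_between))
  rownames(out) <- NULL
  degenerate <- all(abs(out$pa_within) < 1e-12)
  if (degenerate) {
    warning("all within-person activity deviations are 0; ",
            "the daily-activity effect is inestimable")
  }
  attr(out, "outcome") <- outcome
  attr(out, "pa_variable") <- pa_variable
  attr(out, "degenerate") <- degenerate
  class(out) <- c("hlm_design", "data.frame")
  out
}

hlm_tags <- function() c("empty", "trend_only", "fixed_only", "fixed_and_random")

hlm_formula <- function(model_tag) {
  switch(model_tag,
    empty = affect ~ 1 + (1 | child_id),
    trend_only = affect ~ trend + (1 + trend | child_id),
    fixed_only = affect ~ trend + pa_between + pa_within +
      (1 + trend | child_id),
    fixed_and_random = affect ~ trend + pa_between + pa_within +
      (1 + trend | child_id) + (0 + pa_within | child_id),
    stop("unknown model_tag: ", model_tag))
}

# Fixed-effect design matrix and random-effect column sets per model tag.
hlm_matrices <- function(design, model_tag) {
  X <- switch(model_tag,
    empty = cbind(`(Intercept)` = rep(1, nrow(design))),
    trend_only = cbind(`(Intercept)` = 1, trend = design$trend),
    cbind(`(Intercept)` = 1, trend = design$trend,
          pa_between = design$pa_between, pa_within = design$pa_within))
  z_it <- if (model_tag == "empty") cbind(rep(1, nrow(design))) else
    cbind(1, design$trend)
  z_pa <- if (model_tag == "fixed_and_random") cbind(design$pa_within) else NULL
  list(X = X, z_it = z_it, z_pa = z_pa)
}

#' Exact two-level (restricted) log-likelihood deviance
#'
#' Direct evaluation of -2 times the (restricted) log-likelihood of the
#' affect models by per-child block computation of
#' V_i = Z_i G Z_i' + sigma^2 I, independent of the fitting routine. Used
#' as an oracle for the mixed-model fits and for curvature-based standard
#' errors of the variance components.
#'
#' @param design An [build_design()] result.
#' @param model_tag One of `"empty"`, `"trend_only"`, `"fixed_only"`,
#'   `"fixed_and_random"`.
#' @param pars Named numeric vector: `var0` and `var_e` always; `var1` and
#'   `cov01` for models with a random trend; `var3` for the final model.
#' @param reml If TRUE (default) the REML criterion, else the profiled ML
#'   deviance.
#' @return -2 log (restricted) likelihood, comparable to `-2 * logLik()` of
#'   the corresponding fitted model.
#' @export
hlm_deviance <- function(design, model_tag, pars, reml = TRUE) {
  m <- hlm_matrices(design, model_tag)
  y <- design$affect
  child <- factor(design$child_id)
  p <- ncol(m$X)
  n <- length(y)
  G_it <- if (model_tag == "empty") matrix(pars[["var0"]], 1, 1) else
    matrix(c(pars[["var0"]], pars[["cov01"]], pars[["cov01"]],
             pars[["var1"]]), 2, 2)
  ve <- pars[["var_e"]]
  if (ve <= 0) return(Inf)
  logdetV <- 0
  XtVX <- matrix(0, p, p)
  XtVy <- numeric(p)
  ytVy <- 0
  for (ix in split(seq_len(n), child)) {
    Zi <- m$z_it[ix, , drop = FALSE]
    Vi <- Zi %*% G_it %*% t(Zi)
    if (!is.null(m$z_pa)) {
      Vi <- Vi + pars[["var3"]] * tcrossprod(m$z_pa[ix, , drop = FALSE])
    }
    diag(Vi) <- diag(Vi) + ve
    ch <- tryCatch(chol(Vi), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    logdetV <- logdetV + 2 * sum(log(diag(ch)))
    Xi <- m$X[ix, , drop = FALSE]
    yi <- y[ix]
    Vx <- backsolve(ch, forwardsolve(t(ch), Xi))
    Vy <- backsolve(ch, forwardsolve(t(ch), yi))
    XtVX <- XtVX + crossprod(Xi, Vx)
    XtVy <- XtVy + crossprod(Xi, Vy)
    ytVy <- ytVy + sum(yi * Vy)
  }
  beta <- solve(XtVX, XtVy)
  quad <- ytVy - sum(beta * XtVy)
  if (reml) {
    logdetV + determinant(XtVX, logarithm = TRUE)$modulus[1] + quad +
      (n - p) * log(2 * pi)
  } else {
    logdetV + quad + n * log(2 * pi)
  }
}

# Variance-component vector (named, in hlm_deviance order) from an lmer fit.
varcomp_from_fit <- function(fit, model_tag) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  g <- function(grp, v1, v2 = NA) {
    r <- vc[vc$grp == grp &
              (is.na(v2) & vc$var1 == v1 & is.na(vc$var2) |
                 !is.na(v2) & vc$var1 == v1 & !is.na(vc$var2) & vc$var2 == v2), ]
    if (nrow(r)) r$vcov[1] else NA_real_
  }
  out <- c(var0 = g("child_id", "(Intercept)"),
           var_e = vc$vcov[vc$grp == "Residual"])
  if (model_tag != "empty") {
    out <- c(out, var1 = g("child_id", "trend"),
             cov01 = g("child_id", "(Intercept)", "trend"))
  }
  if (model_tag == "fixed_and_random") {
    out <- c(out, var3 = g("child_id.1", "pa_within"))
  }
  out
}

# Curvature-based SEs of the variance components: central-difference
# Hessian of the exact REML deviance at the estimate, free parameters only.
# Components at the non-negativity boundary get SE = NA (the usual
# "0.00 (NA)" report).
varcomp_se <- function(design, model_tag, pars, boundary_tol = 1e-7) {
  free <- names(pars)
  at_bound <- names(pars)[grepl("^var", names(pars)) & pars < boundary_tol]
  if ("var1" %in% at_bound) at_bound <- union(at_bound, "cov01")
  free <- setdiff(free, at_bound)
  se <- stats::setNames(rep(NA_real_, length(pars)), names(pars))
  if (!length(free)) return(se)
  f <- function(theta) {
    p <- pars
    p[free] <- theta
    hlm_deviance(design, model_tag, p, reml = TRUE)
  }
  th <- pars[free]
  h <- pmax(abs(th) * 1e-3, 1e-7)
  h <- ifelse(grepl("^var", free), pmin(h, pmax(th / 2, 1e-10)), h)
  k <- length(free)
  H <- matrix(NA_real_, k, k)
  fx <- f(th)
  ok <- tryCatch({
    for (i in seq_len(k)) {
      ei <- replace(numeric(k), i, h[i])
      H[i, i] <- (f(th + ei) - 2 * fx + f(th - ei)) / h[i]^2
      if (i > 1) for (j in seq_len(i - 1)) {
        ej <- replace(numeric(k), j, h[j])
        H[i, j] <- H[j, i] <-
          (f(th + ei + ej) - f(th + ei - ej) - f(th - ei + ej) +
             f(th - ei - ej)) / (4 * h[i] * h[j])
      }
    }
    TRUE
  }, error = function(e) FALSE)
  if (ok && all(is.finite(H))) {
    cov <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(cov)) {
      d <- diag(cov)
      se[free] <- ifelse(d > 0, sqrt(d), NA_real_)
    }
  }
  se
}

#' Fit one two-level model of daily affect
#'
#' Fits the requested model of the sequence empty, trend-only, fixed
#' effects only, fixed and random effects, by restricted maximum
#' likelihood (via \pkg{lme4}). The final model carries a random intercept,
#' random trend (correlated with the intercept) and an independent random
#' daily-activity slope; variances are constrained non-negative, and a
#' variance estimated at the boundary is reported as 0 with a missing
#' standard error. Fixed effects get Wald z tests (no small-sample df
#' correction). The ML deviance is also computed (by refit) since restricted
#' likelihoods are not comparable across fixed-effect structures.
#'
#' @param design An [build_design()] result.
#' @param model_tag One of [hlm_tags()].
#' @param reml Use REML (default TRUE) for the reported estimates.
#' @param variance_se Compute curvature-based SEs for the variance
#'   components (default TRUE; slightly costly).
#' @param force_zero_random If TRUE, fix all random-effect variances to 0,
#'   reducing the fit to ordinary least squares on the same design.
#' @return An `hlm_fit` list: `model_tag`, `fixed` (estimate, se, z, p per
#'   term), `random` (variance components with SEs), `neg2loglik`,
#'   `neg2loglik_ml`, `converged`, `messages`, `n_obs`, `n_children`.
#' @export
fit_hlm <- function(design, model_tag = "fixed_and_random", reml = TRUE,
                    variance_se = TRUE, force_zero_random = FALSE) {
  model_tag <- match.arg(model_tag, hlm_tags())
  stopifnot(inherits(design, "hlm_design"))
  if (model_tag %in% c("fixed_only", "fixed_and_random") &&
      isTRUE(attr(design, "degenerate"))) {
    stop("degenerate design: no within-person activity variation")
  }
  if (force_zero_random) {
    m <- hlm_matrices(design, model_tag)
    ols <- stats::lm.fit(m$X, design$affect)
    s2 <- sum(ols$residuals^2) / ols$df.residual
    covb <- s2 * chol2inv(chol(crossprod(m$X)))
    fixed <- data.frame(term = colnames(m$X), estimate = ols$coefficients,
                        se = sqrt(diag(covb)))
    fixed$z <- fixed$estimate / fixed$se
    fixed$p <- 2 * stats::pnorm(-abs(fixed$z))
    out <- list(model_tag = model_tag, fixed = fixed,
                random = data.frame(component = "var_e", variance = s2,
                                    se = NA_real_),
                neg2loglik = NA_real_, neg2loglik_ml = NA_real_,
                converged = TRUE, messages = character(0),
                n_obs = nrow(design),
                n_children = length(unique(design$child_id)))
    class(out) <- "hlm_fit"
    return(out)
  }
  msgs <- character(0)
  fml <- hlm_formula(model_tag)
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = design, REML = reml,
               control = lme4::lmerControl(optimizer = "bobyqa",
                                           optCtrl = list(rhoend = 1e-10),
                                           check.conv.singular = "ignore")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  conv_msgs <- unlist(fit@optinfo$conv$lme4$messages)
  if (length(conv_msgs)) msgs <- c(msgs, conv_msgs)
  converged <- fit@optinfo$conv$opt == 0 &&
    !any(grepl("failed to converge", msgs))
  if (!converged) {
    warning("model '", model_tag, "' did not converge cleanly: ",
            paste(unique(msgs), collapse = "; "))
  }
  co <- summary(fit)$coefficients
  fixed <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                      se = co[, "Std. Error"])
  fixed$z <- fixed$estimate / fixed$se
  fixed$p <- 2 * stats::pnorm(-abs(fixed$z))
  rownames(fixed) <- NULL
  pars <- varcomp_from_fit(fit, model_tag)
  se <- if (variance_se) varcomp_se(design, model_tag, pars) else
    stats::setNames(rep(NA_real_, length(pars)), names(pars))
  random <- data.frame(component = names(pars), variance = unname(pars),
                       se = unname(se[names(pars)]))
  ml_dev <- if (reml) -2 * as.numeric(stats::logLik(lme4::refitML(fit))) else
    -2 * as.numeric(stats::logLik(fit))
  out <- list(model_tag = model_tag, fixed = fixed, random = random,
              neg2loglik = -2 * as.numeric(stats::logLik(fit)),
              neg2loglik_ml = ml_dev, converged = converged, messages = msgs,
              n_obs = nrow(design),
              n_children = length(unique(design$child_id)))
  class(out) <- "hlm_fit"
  out
}

#' @export
print.hlm_fit <- function(x, ...) {
  cat(sprintf("<hlm_fit> %s model: %d days in %d children, -2LL(REML) %.1f\n",
              x$model_tag, x$n_obs, x$n_children, x$neg2loglik))
  cat("Fixed effects (Wald z):\n")
  for (i in seq_len(nrow(x$fixed))) {
    cat(sprintf("  %-12s %8.4f (%.4f)%s\n", x$fixed$term[i],
                x$fixed$estimate[i], x$fixed$se[i],
                ifelse(x$fixed$p[i] < 0.05, " *", "")))
  }
  cat("Variance components:\n")
  for (i in seq_len(nrow(x$random))) {
    cat(sprintf("  %-12s %8.4f (%s)\n", x$random$component[i],
                x$random$variance[i],
                ifelse(is.na(x$random$se[i]), "NA",
                       sprintf("%.4f", x$random$se[i]))))
  }
  invisible(x)
}

#' Fit the full model-building sequence
#'
#' Fits, in order, the empty model, the trend-only model, the model with
#' all fixed effects, and the final model adding the random
#' daily-activity slope. Estimates are REML; each fit also carries its ML
#' deviance so nested models can be compared on the likelihood scale.
#'
#' @param design An [build_design()] result.
#' @param ... Passed to [fit_hlm()].
#' @return Named list of four `hlm_fit` objects in sequence order.
#' @export
model_sequence <- function(design, ...) {
  stats::setNames(lapply(hlm_tags(), function(tag) fit_hlm(design, tag, ...)),
                  hlm_tags())
}

#' Fit all affect-outcome by activity-variable model sequences
#'
#' Runs [build_design()] and [model_sequence()] for every combination of
#' the four affect dimensions and the two activity variables (eight model
#' sequences in total).
#'
#' @param day_table Child-day table containing the four affect scores,
#'   `pa_fraction` and `vigorous_share`.
#' @param outcomes Affect outcome columns (default the four factors).
#' @param pa_variables Activity columns (default both).
#' @param ... Passed to [fit_hlm()].
#' @return Nested named list: `fits[[outcome]][[pa_variable]]` is a
#'   [model_sequence()] result.
#' @export
fit_all_models <- function(day_table,
                           outcomes = c("pleasantness", "unpleasantness",
                                        "activation", "deactivation"),
                           pa_variables = c("pa_fraction", "vigorous_share"),
                           ...) {
  out <- lapply(outcomes, function(oc) {
    stats::setNames(lapply(pa_variables, function(pv) {
      model_sequence(build_design(day_table, oc, pv), ...)
    }), pa_variables)
  })
  stats::setNames(out, outcomes)
}

fmt_est <- function(est, se, p = NA) {
  if (is.na(est)) return("")
  star <- if (!is.na(p) && p < 0.05) "*" else ""
  se_s <- if (is.na(se)) "NA" else formatC(se, format = "fg", digits = 2)
  paste0(formatC(est, format = "fg", digits = 3), star, " (", se_s, ")")
}

#' Tabulate one outcome's model sequences
#'
#' Arranges the fits of one affect dimension in the conventional layout:
#' rows are the fixed effects (intercept, trend, average activity, daily
#' activity), the variance components (random intercept, daily-activity
#' slope, trend, residual) and the -2 log-likelihood; columns are the six
#' model variants (empty, trend only, and fixed / fixed-and-random for each
#' activity variable). Entries are "estimate (SE)" with `*` marking Wald
#' p < 0.05.
#'
#' @param fits_by_pa The `fits[[outcome]]` element of [fit_all_models()]:
#'   a named list of two [model_sequence()] results.
#' @return Character data.frame with a `row` column and six model columns.
#' @export
results_table <- function(fits_by_pa) {
  cols <- list(
    `Empty model` = fits_by_pa[[1]]$empty,
    `Trend only` = fits_by_pa[[1]]$trend_only,
    `Total activity: fixed` = fits_by_pa[[1]]$fixed_only,
    `Total activity: fixed and random` = fits_by_pa[[1]]$fixed_and_random,
    `Vigorous activity: fixed` = fits_by_pa[[2]]$fixed_only,
    `Vigorous activity: fixed and random` = fits_by_pa[[2]]$fixed_and_random
  )
  rows <- c("Fixed intercept" = "(Intercept)", "Trend (time)" = "trend",
            "Average activity" = "pa_between", "Daily activity" = "pa_within")
  vrows <- c("Random intercept" = "var0", "Variance daily activity" = "var3",
             "Variance trend" = "var1", "Residual variance" = "var_e")
  tab <- data.frame(row = c(names(rows), names(vrows), "-2 Log-Likelihood"))
  for (cn in names(cols)) {
    f <- cols[[cn]]
    col <- character(0)
    for (term in rows) {
      i <- match(term, f$fixed$term)
      col <- c(col, if (is.na(i)) "" else
        fmt_est(f$fixed$estimate[i], f$fixed$se[i], f$fixed$p[i]))
    }
    for (vc in vrows) {
      i <- match(vc, f$random$component)
      col <- c(col, if (is.na(i)) "" else
        fmt_est(f$random$variance[i], f$random$se[i]))
    }
    col <- c(col, formatC(f$neg2loglik, format = "f", digits = 1))
    tab[[cn]] <- col
  }
  tab
}
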