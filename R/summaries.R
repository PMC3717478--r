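#' Daily physical-activity summary of one child-day
#'
#' Collapses the cleaned epochs of a valid day into behaviour-category
#' durations and the two activity measures used as model predictors:
#' `pa_fraction`, the share of worn time spent active (MVPA plus very
#' vigorous activity), and `vigorous_share`, the share of that active time
#' spent very vigorously (0 by convention on days without active time).
#'
#' @param epochs A `cleaned_epochs` object restricted to one child-date.
#' @param require_valid If TRUE (default), error when the day has less than
#'   `min_hours` of wear.
#' @param min_hours Valid-day threshold in hours.
#' @return A one-row data.frame: `child_id`, `date`, minutes per category
#'   (`sedentary_min`, `inactive_min`, `mvpa_min`, `vigorous_min`,
#'   `nonwear_min`), `wear_min`, `active_min`, `pa_fraction`,
#'   `vigorous_share`.
#' @export
#' @examples
#' # 8 h sitting + 90 min walking + 30 min running:
#' lab <- rep(c("sitting", "walk_slow", "running"),
#'            c(8 * 1440, 90 * 24, 30 * 24))
#' ep <- labeled_epochs("C01", as.POSIXct("2012-05-07 08:00", tz = "UTC") +
#'                        2.5 * (seq_along(lab) - 1), lab)
#' summarize_day(ep)[, c("pa_fraction", "vigorous_share")]  # 0.20, 0.25
summarize_day <- function(epochs, require_valid = TRUE, min_hours = 6) {
  epochs <- as_cleaned(epochs)
  step <- epoch_step(epochs)
  kept <- epochs[epochs$retained, , drop = FALSE]
  child <- unique(as.character(epochs$child_id))
  date <- unique(as.Date(epochs$epoch_start, tz = "UTC"))
  stopifnot(length(child) == 1, length(date) == 1)
  cat_min <- tapply(rep(step / 60, nrow(kept)), behavior_category(kept$label),
                    sum, default = 0)
  cat_min[is.na(cat_min)] <- 0
  wear <- sum(cat_min[c("sedentary", "inactive", "mvpa", "very_vigorous")])
  if (require_valid && wear < min_hours * 60) {
    stop(sprintf("not a valid day: %.2f h of wear (< %g h)", wear / 60,
                 min_hours))
  }
  active <- cat_min[["mvpa"]] + cat_min[["very_vigorous"]]
  data.frame(
    child_id = child, date = date,
    sedentary_min = cat_min[["sedentary"]], inactive_min = cat_min[["inactive"]],
    mvpa_min = cat_min[["mvpa"]], vigorous_min = cat_min[["very_vigorous"]],
    nonwear_min = cat_min[["non_wear"]], wear_min = wear, active_min = active,
    pa_fraction = if (wear > 0) active / wear else 0,
    vigorous_share = if (active > 0) cat_min[["very_vigorous"]] / active else 0
  )
}

#' Daily affect composite scores
#'
#' Affect is rated on 12 five-point Likert items, three per factor
#' (pleasantness, unpleasantness, activation, deactivation), at four
#' occasions a day. Per occasion the factor composite is the mean of its
#' three items (an occasion counts only when all three were answered); the
#' day score is the mean of the available occasion composites, with the
#' number of occasions used recorded per factor.
#'
#' @param responses Data.frame with columns `child_id`, `date`, `occasion`,
#'   `item_id`, `response` (integers 1-5).
#' @param item_map Item-to-factor assignment (default [default_item_map()]).
#' @return Data.frame with one row per child-day: the four factor scores
#'   (NA when no occasion had complete data) and
#'   `n_occasions_<factor>` counts.
#' @export
affect_day_scores <- function(responses, item_map = default_item_map()) {
  stopifnot(all(c("child_id", "date", "occasion", "item_id", "response") %in%
                  names(responses)))
  if (any(!responses$response %in% 1:5)) {
    stop("responses must be integers on the 1-5 Likert scale")
  }
  responses$factor <- item_map$factor[match(responses$item_id,
                                            item_map$item_id)]
  if (anyNA(responses$factor)) stop("item_id not covered by item_map")
  key <- interaction(responses$child_id, responses$date, drop = TRUE)
  factors <- unique(item_map$factor)
  rows <- lapply(split(responses, key), function(d) {
    out <- data.frame(child_id = d$child_id[1], date = as.Date(d$date[1]))
    for (f in factors) {
      df <- d[d$factor == f, ]
      comp <- tapply(df$response, df$occasion, function(v) {
        if (length(v) == 3) mean(v) else NA_real_
      })
      comp <- comp[!is.na(comp)]
      out[[f]] <- if (length(comp)) mean(comp) else NA_real_
      out[[paste0("n_occasions_", f)]] <- length(comp)
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$child_id, out$date), , drop = FALSE]
}

# Method-of-moments (one-way ANOVA) variance components of a balanced or
# unbalanced child-day panel; used as the ICC cross-check.
icc_moments <- function(values, child) {
  keep <- !is.na(values)
  values <- values[keep]; child <- factor(child[keep])
  n_i <- tabulate(child)
  k <- nlevels(child)
  n <- length(values)
  gm <- mean(values)
  m_i <- tapply(values, child, mean)
  ssb <- sum(n_i * (m_i - gm)^2)
  ssw <- sum((values - m_i[child])^2)
  msw <- ssw / (n - k)
  msb <- ssb / (k - 1)
  n0 <- (n - sum(n_i^2) / n) / (k - 1)
  vb <- max(0, (msb - msw) / n0)
  vb / (vb + msw)
}

#' Descriptive statistics of a child-day panel
#'
#' For each requested variable: the grand mean and SD over all child-days,
#' the average intra-individual SD (each child's own across-day SD,
#' averaged over children), and the intraclass correlation. The ICC is the
#' between-child share of total variance, estimated from the empty
#' two-level model (random-intercept REML); one minus the ICC is the
#' within-child share. With a single child the ICC is undefined and
#' reported NA.
#'
#' @param panel Data.frame with a `child_id` column and the variables.
#' @param variables Character vector of column names to describe.
#' @param method `"reml"` (empty mixed model, default) or `"moments"`
#'   (one-way method-of-moments estimator).
#' @return A `descriptive_table` data.frame: `variable`, `mean`, `sd`,
#'   `average_isd`, `icc`.
#' @export
descriptives <- function(panel, variables, method = c("reml", "moments")) {
  method <- match.arg(method)
  stopifnot("child_id" %in% names(panel), all(variables %in% names(panel)))
  rows <- lapply(variables, function(v) {
    x <- panel[[v]]
    child <- factor(panel$child_id)
    isd <- tapply(x, child, stats::sd, na.rm = TRUE)
    icc <- if (nlevels(droplevels(child[!is.na(x)])) < 2) NA_real_
    else if (method == "moments") icc_moments(x, child)
    else {
      fit <- lme4::lmer(x ~ 1 + (1 | child),
                        data = data.frame(x = x, child = child),
                        REML = TRUE,
                        control = lme4::lmerControl(calc.derivs = FALSE))
      vc <- as.data.frame(lme4::VarCorr(fit))
      vb <- vc$vcov[vc$grp == "child"]
      vw <- vc$vcov[vc$grp == "Residual"]
      vb / (vb + vw)
    }
    data.frame(variable = v, mean = mean(x, na.rm = TRUE),
               sd = stats::sd(x, na.rm = TRUE),
               average_isd = mean(isd, na.rm = TRUE), icc = icc)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("descriptive_table", "data.frame")
  out
}

#' @export
print.descriptive_table <- function(x, digits = 2, ...) {
  cat("Variable            Mean (SD)      Average ISD   ICC\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-18s %6.2f (%.2f)   %6.2f      %5.2f\n", x$variable[i],
                x$mean[i], x$sd[i], x$average_isd[i], x$icc[i]))
  }
  invisible(x)
}
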