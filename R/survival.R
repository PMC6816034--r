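#' Kaplan-Meier survival curve for one cohort
#'
#' Product-limit estimator of overall survival from event flags (1 = death,
#' 0 = censored) and follow-up times in days. Censoring reduces the risk
#' set without a survival drop.
#'
#' @param records A tibble with columns `event` and `time_days` (one
#'   cohort's rows of a clinical table); a `cohort` column, if present, is
#'   carried along.
#' @return A `km_curve`: list with `times` (distinct event/censoring
#'   times), `survival`, `n_risk`, `n_event`, `cohort`, and the underlying
#'   [survival::survfit] object as `fit`.
#' @export
km_curve <- function(records) {
  if (nrow(records) == 0) ne_abort("empty cohort: no survival records", "precondition_error")
  fit <- survival::survfit(
    survival::Surv(records$time_days, records$event) ~ 1,
    conf.type = "none"
  )
  structure(list(times = fit$time,
                 survival = fit$surv,
                 n_risk = fit$n.risk,
                 n_event = fit$n.event,
                 cohort = if ("cohort" %in% names(records)) records$cohort[1] else NA_character_,
                 n = nrow(records),
                 fit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %s: n = %d, %d distinct times, S(last) = %.3f\n",
              x$cohort %||% "?", x$n, length(x$times), tail_or(x$survival, 1)))
  invisible(x)
}

tail_or <- function(v, default) if (length(v)) v[length(v)] else default

#' @export
tidy.km_curve <- function(x, ...) {
  tibble(time = x$times, n_risk = x$n_risk, n_event = x$n_event,
         survival = x$survival)
}

#' Survival rate (percent) at a time point
#'
#' Right-continuous step lookup of the Kaplan-Meier curve: `100 * S(t)`.
#' Before the first recorded time the rate is 100; beyond the last time
#' the last estimate carries forward. Serves both the cohort 5-year rate
#' (`t_days = 1825`) and the per-patient lookup at each patient's own
#' days-to-death/last-follow-up.
#'
#' @param curve A `km_curve`.
#' @param t_days Positive time(s) in days (vectorized).
#' @return Numeric percentage(s) in `[0, 100]`.
#' @export
survival_rate_at <- function(curve, t_days) {
  if (any(t_days <= 0)) ne_abort("t_days must be positive", "precondition_error")
  idx <- findInterval(t_days, curve$times)
  100 * ifelse(idx == 0, 1, curve$survival[pmax(idx, 1)])
}

#' Regress subnetwork entropy on 5-year survival
#'
#' Ordinary least squares of mean entropy (bits, Y) on 5-year survival rate
#' (percent, X) across cohorts, with Pearson correlation, the two-sided
#' t-test for a nonzero slope, and a 95% confidence interval on the slope
#' (t distribution, n - 2 df).
#'
#' @param points A tibble/data.frame with columns `survival` (percent) and
#'   `entropy` (bits), one row per cohort (or per survival-rate interval).
#' @return An `entropy_regression`: list with `slope`, `intercept`, `r`,
#'   `p_value`, `slope_ci_low`, `slope_ci_high`, `n`, and the `lm` fit.
#' @export
entropy_survival_regression <- function(points) {
  points <- as_tibble(points)
  if (nrow(points) < 3) ne_abort("at least 3 points are required", "precondition_error")
  if (length(unique(points$survival)) < 2) {
    ne_abort("all survival values identical: regression is degenerate", "degenerate_error")
  }
  fit <- lm(entropy ~ survival, data = points)
  # collinear input is legitimate (an exact line is a valid fit); silence
  # summary.lm's perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(confint(fit, "survival", level = 0.95))
  structure(list(slope = unname(coef(fit)[["survival"]]),
                 intercept = unname(coef(fit)[["(Intercept)"]]),
                 r = suppressWarnings(cor(points$survival, points$entropy)),
                 p_value = unname(sm$coefficients["survival", "Pr(>|t|)"]),
                 slope_ci_low = ci[1, 1],
                 slope_ci_high = ci[1, 2],
                 n = nrow(points),
                 data = points,
                 fit = fit),
            class = "entropy_regression")
}

#' @export
print.entropy_regression <- function(x, ...) {
  cat(sprintf("<entropy_regression> Y = %.4g X + %.4g  (r = %.3f, p = %.3g, n = %d)\n",
              x$slope, x$intercept, x$r, x$p_value, x$n))
  invisible(x)
}

#' @export
tidy.entropy_regression <- function(x, ...) {
  tibble(term = c("(Intercept)", "survival"),
         estimate = c(x$intercept, x$slope),
         conf.low = c(NA_real_, x$slope_ci_low),
         conf.high = c(NA_real_, x$slope_ci_high),
         p.value = c(NA_real_, x$p_value))
}

#' @export
glance.entropy_regression <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r = x$r,
         p.value = x$p_value, slope_ci_low = x$slope_ci_low,
         slope_ci_high = x$slope_ci_high, n = x$n)
}

#' @exportS3Method ggplot2::autoplot
autoplot.entropy_regression <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$survival, y = .data$entropy)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "firebrick") +
    ggplot2::labs(x = "5-year survival rate (%)", y = "mean subnetwork entropy (bits)",
                  subtitle = sprintf("Y = %.4gX + %.4g;  r = %.2f, p = %.3g",
                                     object$slope, object$intercept, object$r,
                                     object$p_value)) +
    ggplot2::theme_minimal()
}

#' Kruskal-Wallis test across cohorts
#'
#' Rank-based test (with tie correction) of the hypothesis that all cohorts
#' share the same location of the supplied values (entropies or target
#' counts). Degrees of freedom = number of groups - 1.
#'
#' @param values Numeric vector.
#' @param groups Group label for each value.
#' @return List with `kw_statistic`, `kw_df`, `kw_p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  sizes <- table(groups)
  if (length(sizes) < 2) ne_abort("at least 2 groups are required", "precondition_error")
  if (any(sizes < 2)) {
    ne_abort(sprintf("group '%s' has fewer than 2 values", names(sizes)[sizes < 2][1]),
             "precondition_error")
  }
  kt <- kruskal.test(values, groups)
  list(kw_statistic = unname(kt$statistic),
       kw_df = as.integer(unname(kt$parameter)),
       kw_p = kt$p.value)
}

#' Pairwise two-sided rank-sum tests with multiplicity correction
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test for every unordered pair
#' of cohorts, with Holm correction by default; `correction = "none"`
#' returns raw p-values (heat-map style output). A paired signed-rank mode
#' is available for designs where groups index the same subjects.
#'
#' @param values Numeric vector.
#' @param groups Group label for each value.
#' @param correction A [stats::p.adjust] method name (default `"holm"`).
#' @param paired Use the signed-rank test on equal-length groups.
#' @return A symmetric matrix of corrected p-values (diagonal `NA`).
#' @export
pairwise_rank_tests <- function(values, groups, correction = "holm", paired = FALSE) {
  if (!correction %in% p.adjust.methods) {
    ne_abort(sprintf("unknown correction '%s'", correction), "precondition_error")
  }
  groups <- as.factor(as.character(groups))
  labs <- levels(groups)
  if (length(labs) < 2) ne_abort("at least 2 groups are required", "precondition_error")
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  raw <- vapply(pairs, function(pr) {
    suppressWarnings(wilcox.test(values[groups == pr[1]], values[groups == pr[2]],
                                 paired = paired, exact = FALSE))$p.value
  }, numeric(1))
  adj <- p.adjust(raw, method = correction)
  m <- matrix(NA_real_, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_along(pairs)) {
    m[pairs[[i]][1], pairs[[i]][2]] <- adj[i]
    m[pairs[[i]][2], pairs[[i]][1]] <- adj[i]
  }
  m
}

#' Compare a per-patient quantity across cohorts
#'
#' Convenience wrapper combining [kruskal_wallis()] and
#' [pairwise_rank_tests()] into one `group_comparison` object.
#'
#' @inheritParams pairwise_rank_tests
#' @return A `group_comparison`: list with `kw_statistic`, `kw_df`, `kw_p`,
#'   `pairwise_p` (symmetric matrix), `correction`.
#' @export
compare_groups <- function(values, groups, correction = "holm") {
  kw <- kruskal_wallis(values, groups)
  structure(c(kw, list(pairwise_p = pairwise_rank_tests(values, groups, correction),
                       correction = correction)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> Kruskal-Wallis chi-squared = %.3f, df = %d, p = %.3g; pairwise %s-corrected\n",
              x$kw_statistic, x$kw_df, x$kw_p, x$correction))
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) {
  m <- x$pairwise_p
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble(group1 = rownames(m)[idx[, 1]],
         group2 = colnames(m)[idx[, 2]],
         p.value = m[idx])
}

#' @export
glance.group_comparison <- function(x, ...) {
  tibble(kw_statistic = x$kw_statistic, kw_df = x$kw_df, kw_p = x$kw_p)
}

#' Bin patients into survival-rate intervals
#'
#' Assigns each patient's survival rate (percent, in `(0, 100]`) to one of
#' the standard 20-point intervals: `[81, 100]`, `[61, 81)`, `[41, 61)`,
#' `[21, 41)`, `(0, 21)` by default (labels name the spanned whole
#' percentages, e.g. `"100%-81%"`). Intervals with fewer than 3 patients
#' are flagged ineligible for interval-level averaging.
#'
#' @param patients A tibble with columns `patient_id` and `survival`
#'   (percent).
#' @param lower_bounds Decreasing lower bounds of the intervals (default
#'   `c(81, 61, 41, 21, 0)`), a partition of `(0, 100]`.
#' @return A list with `assignments` (the input plus an `interval` column)
#'   and `intervals` (per-interval `n` and `eligible` flag).
#' @export
bin_patients_by_survival <- function(patients, lower_bounds = c(81, 61, 41, 21, 0)) {
  patients <- as_tibble(patients)
  if (nrow(patients) > 0 &&
      (any(patients$survival <= 0) || any(patients$survival > 100))) {
    ne_abort("survival rates must lie in (0, 100]", "validation_error")
  }
  lb <- sort(unique(lower_bounds), decreasing = TRUE)
  ub <- c(100, lb[-length(lb)] - 1)
  labels <- sprintf("%d%%-%d%%", ub, pmax(lb, 1))
  bin_of <- function(s) labels[length(lb) + 1 - findInterval(s, rev(lb))]
  assignments <- dplyr::mutate(
    patients,
    interval = factor(if (nrow(patients)) bin_of(.data$survival) else character(0),
                      levels = labels)
  )
  counts <- dplyr::count(assignments, .data$interval, .drop = FALSE)
  intervals <- tibble(interval = labels,
                      n = counts$n[match(labels, as.character(counts$interval))])
  intervals$eligible <- intervals$n >= 3
  list(assignments = assignments, intervals = intervals)
}
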