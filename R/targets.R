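#' Entropy goal associated with 100% five-year survival
#'
#' Evaluates the fitted entropy-survival line at a survival rate of 100%,
#' `intercept + slope * 100`: the subnetwork entropy a patient's tumor
#' should be driven to (or below) by hub inactivation. A non-negative slope
#' triggers a warning because the goal may then exceed every baseline,
#' making every target count 0.
#'
#' @param reg An `entropy_regression` from [entropy_survival_regression()],
#'   or a list with `slope` and `intercept`.
#' @return The goal entropy in bits.
#' @export
entropy_goal_full_survival <- function(reg) {
  if (reg$slope >= 0) {
    ne_warn("regression slope is non-negative: 100%-survival goal may exceed all baselines",
            "nonnegative_slope_warning")
  }
  reg$intercept + reg$slope * 100
}

#' Count the hubs whose cumulative removal reaches the entropy goal
#'
#' Freezes the baseline top-`max_n` hub ranking, removes the first n ranked
#' hubs cumulatively for n = 1..`max_n`, and records the entropy of each
#' reduced subnetwork (0 when emptied). The prescribed target count is the
#' smallest n whose entropy is at or below `h_goal`; 0 when the baseline
#' entropy is already at or below the goal; `"unreached"` when no n up to
#' `max_n` suffices.
#'
#' @param sub A subnetwork (igraph).
#' @param h_goal Goal entropy in bits (see [entropy_goal_full_survival()]).
#' @param max_n Largest number of hubs considered (default 20).
#' @return A `target_plan`: list with `patient_id`, `h_goal`, `baseline_h`,
#'   `trajectory` (tibble: `n_removed`, `entropy`, `emptied`), `n_required`
#'   (integer, `NA` when unreached), `reached`, `targets` (accessions,
#'   length `n_required`).
#' @export
targets_needed <- function(sub, h_goal, max_n = 20) {
  if (max_n < 1) ne_abort("max_n must be at least 1", "precondition_error")
  if (igraph::vcount(sub) == 0) ne_abort("empty subnetwork", "precondition_error")
  baseline_h <- shannon_entropy(sub)$H
  ranking <- rank_hubs(sub, max_n)
  steps <- nrow(ranking)
  entropy <- numeric(max_n)
  emptied <- logical(max_n)
  for (n in seq_len(max_n)) {
    k <- min(n, steps)
    left <- remove_nodes(sub, ranking$accession[seq_len(k)])
    emptied[n] <- igraph::vcount(left) == 0
    entropy[n] <- if (emptied[n]) 0 else shannon_entropy(left)$H
  }
  trajectory <- tibble(n_removed = seq_len(max_n), entropy = entropy,
                       emptied = emptied)
  if (baseline_h <= h_goal) {
    n_required <- 0L; reached <- TRUE
  } else {
    hit <- which(entropy <= h_goal)
    if (length(hit) == 0) {
      n_required <- NA_integer_; reached <- FALSE
    } else {
      n_required <- as.integer(hit[1]); reached <- TRUE
    }
  }
  structure(list(patient_id = sub$patient_id %||% NA_character_,
                 h_goal = h_goal,
                 baseline_h = baseline_h,
                 trajectory = trajectory,
                 n_required = n_required,
                 reached = reached,
                 targets = if (reached && n_required > 0)
                   ranking$accession[seq_len(n_required)] else character(0),
                 ranking = ranking,
                 max_n = max_n),
            class = "target_plan")
}

#' @export
print.target_plan <- function(x, ...) {
  status <- if (!x$reached) "unreached" else as.character(x$n_required)
  cat(sprintf("<target_plan> %s: baseline H = %.4f, goal = %.4f, targets required = %s\n",
              x$patient_id %||% "?", x$baseline_h, x$h_goal, status))
  invisible(x)
}

#' @export
tidy.target_plan <- function(x, ...) {
  x$trajectory
}

#' @export
glance.target_plan <- function(x, ...) {
  tibble(patient_id = x$patient_id, baseline_h = x$baseline_h,
         h_goal = x$h_goal, n_required = x$n_required, reached = x$reached)
}

#' @exportS3Method ggplot2::autoplot
autoplot.target_plan <- function(object, ...) {
  tr <- dplyr::bind_rows(
    tibble(n_removed = 0L, entropy = object$baseline_h, emptied = FALSE),
    object$trajectory
  )
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$n_removed, y = .data$entropy)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = object$h_goal, linetype = 2, color = "firebrick") +
    ggplot2::labs(x = "top hubs removed (cumulative)", y = "subnetwork entropy (bits)",
                  subtitle = sprintf("goal %.3f bits; required = %s", object$h_goal,
                                     if (object$reached) object$n_required else "unreached")) +
    ggplot2::theme_minimal()
}

#' Cohort-level summary of target counts and its survival regression
#'
#' Averages the prescribed target count per cohort (unreached plans counted
#' at `max_n` and flagged) and regresses the mean count on the cohort
#' 5-year survival rate with the same least-squares machinery used for
#' entropy.
#'
#' @param plans List of `target_plan` objects.
#' @param cohorts Cohort label per plan.
#' @param survival Cohort 5-year survival percent, as a named vector
#'   (names = cohort labels) or one value per plan.
#' @return List with `summary` (tibble: cohort, n patients, mean/sd target
#'   count, n unreached, survival) and `regression` (an
#'   `entropy_regression` of mean count on survival, or `NULL` with a
#'   message when degenerate).
#' @export
cohort_target_summary <- function(plans, cohorts, survival) {
  if (length(plans) != length(cohorts)) {
    ne_abort("plans and cohorts must have equal length", "precondition_error")
  }
  counts <- vapply(plans, function(p) {
    if (p$reached) as.numeric(p$n_required) else as.numeric(p$max_n)
  }, numeric(1))
  unreached <- vapply(plans, function(p) !p$reached, logical(1))
  tb <- tibble(cohort = as.character(cohorts), count = counts, unreached = unreached)
  summary <- dplyr::summarise(
    dplyr::group_by(tb, .data$cohort),
    n = dplyr::n(),
    mean_targets = mean(.data$count),
    sd_targets = stats::sd(.data$count),
    n_unreached = sum(.data$unreached),
    .groups = "drop"
  )
  surv <- if (!is.null(names(survival))) {
    unname(survival[summary$cohort])
  } else {
    tb$survival <- as.numeric(survival)
    vapply(summary$cohort, function(cc) tb$survival[tb$cohort == cc][1], numeric(1))
  }
  summary$survival <- surv
  if (nrow(summary) < 3) {
    ne_abort("at least 3 cohorts are required for the target-survival summary",
             "precondition_error")
  }
  regression <- tryCatch(
    entropy_survival_regression(tibble(survival = summary$survival,
                                       entropy = summary$mean_targets)),
    netentropy_error = function(e) {
      inform(paste("cohort_target_summary: regression skipped -", conditionMessage(e)))
      NULL
    }
  )
  list(summary = summary, regression = regression)
}
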