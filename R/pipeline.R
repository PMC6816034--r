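#' Pipeline run configuration
#'
#' Collects every tunable of the per-patient and per-cohort runs with the
#' study defaults: one-tail significance 0.05, 100 histogram bins, 1,000
#' random-removal replicates of 5 nodes, up to 20 targets, 5 years = 1825
#' days, Holm-corrected pairwise tests. Serializable to a plain-text YAML
#' file via [write_run_config()] / [read_run_config()].
#'
#' @param alpha One-tail up-regulation significance in (0, 0.5).
#' @param n_bins Differential-expression histogram bins (>= 10).
#' @param null_reps Random-removal replicates (>= 1).
#' @param null_remove Nodes removed per replicate.
#' @param max_targets Largest hub count evaluated per patient.
#' @param five_years_days Days representing 5 years.
#' @param correction Multiplicity correction for pairwise tests.
#' @param seed Master seed for every stochastic stage.
#' @param goal_mode `"all-cohort"` (entropy goal from the cross-cohort
#'   regression) or `"within-tissue"` (per-cohort interval regression where
#'   eligible).
#' @param min_cohort_size Paired-patient count under which a cohort is
#'   flagged (default 30).
#' @param paths Optional named list/vector of input paths (`expression`,
#'   `sheet`, `mapping`, `interactome`, `clinical`).
#' @return A validated `run_config` list.
#' @export
run_config <- function(alpha = 0.05, n_bins = 100, null_reps = 1000,
                       null_remove = 5, max_targets = 20,
                       five_years_days = 1825, correction = "holm",
                       seed = 1, goal_mode = c("all-cohort", "within-tissue"),
                       min_cohort_size = 30, paths = list()) {
  goal_mode <- match.arg(goal_mode)
  stopifnot(alpha > 0, alpha < 0.5, n_bins >= 10, null_reps >= 1,
            null_remove >= 1, max_targets >= 1, five_years_days > 0,
            min_cohort_size >= 1)
  if (!correction %in% p.adjust.methods) {
    ne_abort(sprintf("unknown correction '%s'", correction), "precondition_error")
  }
  structure(list(alpha = alpha, n_bins = n_bins, null_reps = null_reps,
                 null_remove = null_remove, max_targets = max_targets,
                 five_years_days = five_years_days, correction = correction,
                 seed = as.integer(seed), goal_mode = goal_mode,
                 min_cohort_size = min_cohort_size,
                 paths = as.list(paths)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path for the YAML serialization.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Run the full per-patient analysis
#'
#' Differential profile, histogram, Gaussian threshold, up-regulated set,
#' induced PPI subnetwork, entropy, top-10/top-20 hub rankings, and the
#' hub-vs-random removal null. Patients whose up-regulated proteins induce
#' no subnetwork are returned flagged, never errored, so cohort runs
#' continue.
#'
#' @param config A `run_config`.
#' @param pair A `patient_pair`.
#' @param interactome The interactome graph.
#' @param map Symbol/accession mapping tibble.
#' @return A `patient_report` list (see fields in the source); inspect
#'   `flag` for `"ok"`, `"no_upregulated"`, `"empty_subnetwork"` or
#'   `"small_subnetwork"`.
#' @export
run_patient <- function(config, pair, interactome, map) {
  profile <- differential_profile(pair)
  report <- list(patient_id = pair$patient_id, flag = "ok",
                 n_upregulated = 0L, n_mapped = 0L,
                 mu = NA_real_, sigma = NA_real_, threshold = NA_real_,
                 converged = NA, n_nodes = NA_integer_, n_edges = NA_integer_,
                 entropy = NA_real_, top10 = NULL, top20 = NULL,
                 null = NULL, empirical_p = NA_real_, subnetwork = NULL)
  hist <- tryCatch(build_histogram(profile, config$n_bins),
                   degenerate_error = function(e) NULL)
  if (is.null(hist)) {
    # e.g. tumor identical to control: nothing can be called up-regulated
    report$flag <- "no_upregulated"
    return(structure(report, class = "patient_report"))
  }
  fit <- fit_gaussian_threshold(hist, config$alpha)
  report[c("mu", "sigma", "threshold", "converged")] <-
    list(fit$mu, fit$sigma, fit$threshold, fit$converged)
  up <- select_upregulated(profile, fit, map)
  report$n_upregulated <- length(up$genes)
  report$n_mapped <- length(up$proteins)
  if (length(up$proteins) == 0) {
    report$flag <- "no_upregulated"
    return(structure(report, class = "patient_report"))
  }
  sub <- tryCatch(
    induce_subnetwork(interactome, up$proteins, pair$patient_id),
    empty_subnetwork_error = function(e) NULL
  )
  if (is.null(sub)) {
    report$flag <- "empty_subnetwork"
    return(structure(report, class = "patient_report"))
  }
  report$subnetwork <- sub
  report$n_nodes <- igraph::vcount(sub)
  report$n_edges <- igraph::ecount(sub)
  report$entropy <- shannon_entropy(sub)$H
  report$top10 <- rank_hubs(sub, 10)
  report$top20 <- rank_hubs(sub, 20)
  if (igraph::vcount(sub) > config$null_remove) {
    report$null <- random_removal_null(sub, config$null_remove,
                                       config$null_reps, config$seed)
    report$empirical_p <- report$null$empirical_p
  } else {
    report$flag <- "small_subnetwork"
  }
  structure(report, class = "patient_report")
}

#' @export
print.patient_report <- function(x, ...) {
  cat(sprintf("<patient_report> %s [%s]: %d up-regulated, subnetwork %s nodes, H = %s, null p = %s\n",
              x$patient_id, x$flag, x$n_upregulated,
              x$n_nodes %||% NA, format(x$entropy, digits = 4),
              format(x$empirical_p, digits = 3)))
  invisible(x)
}

#' Flatten patient reports into one tibble
#'
#' @param reports List of `patient_report` objects.
#' @return A tibble, one row per patient, with hub lists semicolon-joined.
#' @export
tidy_patient_reports <- function(reports) {
  purrr::map_dfr(reports, function(p) {
    tibble(patient_id = p$patient_id,
           flag = p$flag,
           n_upregulated = p$n_upregulated,
           n_nodes = p$n_nodes %||% NA_integer_,
           n_edges = p$n_edges %||% NA_integer_,
           mu = p$mu, sigma = p$sigma, threshold = p$threshold,
           converged = p$converged,
           entropy = p$entropy,
           hubs = if (is.null(p$top10)) NA_character_ else
             paste(p$top10$accession, collapse = ";"),
           empirical_p = p$empirical_p,
           n_targets = p$n_targets %||% NA_integer_)
  })
}

#' Run the full cohort analysis
#'
#' Executes [run_patient()] for every pair, then the cohort stages: mean
#' and SD entropy per cancer type, Kaplan-Meier curves and 5-year rates,
#' Kruskal-Wallis plus Holm-corrected pairwise rank-sum tests on entropy,
#' the entropy-survival regression, the 100%-survival entropy goal,
#' per-patient target plans, the target-count summary and its own survival
#' regression, and - for cohorts with at least 3 patients in every
#' populated survival-rate interval - a within-tissue interval regression.
#' Cohorts below `min_cohort_size` paired patients are flagged but still
#' processed; with fewer than 3 cohorts the cross-cohort regression is
#' skipped with an explicit notice.
#'
#' @param config A `run_config`.
#' @param expression Expression tibble from [read_expression_table()].
#' @param sheet_path Path to the sample sheet TSV.
#' @param map Symbol/accession mapping tibble.
#' @param interactome Interactome graph.
#' @param clinical Clinical tibble from [read_clinical_table()].
#' @return A `cohort_report` list: `patients` (tibble), `reports`,
#'   `cohorts` (summary tibble), `comparison`, `regression`, `h_goal`,
#'   `plans`, `target_summary`, `within_tissue`, `notices`.
#' @export
run_cohort <- function(config, expression, sheet_path, map, interactome, clinical) {
  pairs <- read_sample_pairs(expression, sheet_path)
  notices <- character(0)
  reports <- lapply(pairs, run_patient, config = config,
                    interactome = interactome, map = map)
  names(reports) <- vapply(reports, `[[`, character(1), "patient_id")
  patients <- tidy_patient_reports(reports)
  patients <- dplyr::left_join(patients,
                               clinical[c("patient_id", "cohort", "event", "time_days")],
                               by = "patient_id")
  if (anyNA(patients$cohort)) {
    notices <- c(notices, sprintf("%d patient(s) missing from the clinical table",
                                  sum(is.na(patients$cohort))))
  }

  # Per-cohort KM curves and 5-year rates
  clin_split <- split(clinical, clinical$cohort)
  curves <- lapply(clin_split, km_curve)
  five_year <- vapply(curves, survival_rate_at, numeric(1),
                      t_days = config$five_years_days)

  cohorts <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(patients, !is.na(.data$cohort)), .data$cohort),
    n_patients = dplyr::n(),
    mean_entropy = mean(.data$entropy, na.rm = TRUE),
    sd_entropy = stats::sd(.data$entropy, na.rm = TRUE),
    .groups = "drop"
  )
  cohorts$five_year_survival <- unname(five_year[cohorts$cohort])
  cohorts$below_min <- cohorts$n_patients < config$min_cohort_size
  if (any(cohorts$below_min)) {
    notices <- c(notices, sprintf("cohort(s) below %d paired patients: %s",
                                  config$min_cohort_size,
                                  paste(cohorts$cohort[cohorts$below_min], collapse = ", ")))
  }

  ok <- !is.na(patients$entropy) & !is.na(patients$cohort)
  comparison <- if (length(unique(patients$cohort[ok])) >= 2 &&
                    all(table(patients$cohort[ok]) >= 2)) {
    compare_groups(patients$entropy[ok], patients$cohort[ok], config$correction)
  } else NULL

  regression <- NULL
  h_goal <- NA_real_
  if (nrow(cohorts) >= 3) {
    regression <- tryCatch(
      entropy_survival_regression(tibble(survival = cohorts$five_year_survival,
                                         entropy = cohorts$mean_entropy)),
      netentropy_error = function(e) {
        notices <<- c(notices, paste("cross-cohort regression skipped:",
                                     conditionMessage(e)))
        NULL
      })
    if (!is.null(regression)) {
      h_goal <- withCallingHandlers(
        entropy_goal_full_survival(regression),
        nonnegative_slope_warning = function(w) {
          notices <<- c(notices, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }
  } else {
    notices <- c(notices,
                 "fewer than 3 cohorts: cross-cohort regression and entropy goal skipped")
  }

  plans <- list()
  if (!is.na(h_goal)) {
    with_net <- patients$patient_id[patients$flag %in% c("ok", "small_subnetwork")]
    plans <- lapply(reports[with_net], function(p) {
      targets_needed(p$subnetwork, h_goal, config$max_targets)
    })
    for (pid in names(plans)) {
      patients$n_targets[patients$patient_id == pid] <-
        if (plans[[pid]]$reached) plans[[pid]]$n_required else NA_integer_
    }
  }

  target_summary <- NULL
  if (length(plans) >= 1 && nrow(cohorts) >= 3) {
    plan_cohort <- patients$cohort[match(names(plans), patients$patient_id)]
    keep <- !is.na(plan_cohort)
    target_summary <- tryCatch(
      cohort_target_summary(plans[keep], plan_cohort[keep],
                            setNames(cohorts$five_year_survival, cohorts$cohort)),
      netentropy_error = function(e) {
        notices <<- c(notices, paste("target summary skipped:", conditionMessage(e)))
        NULL
      })
  }

  within_tissue <- within_tissue_analysis(patients, curves, config)

  structure(list(patients = patients, reports = reports, cohorts = cohorts,
                 curves = curves, comparison = comparison,
                 regression = regression, h_goal = h_goal, plans = plans,
                 target_summary = target_summary,
                 within_tissue = within_tissue, notices = notices,
                 config = config),
            class = "cohort_report")
}

# Interval analysis inside each cohort: per-patient survival rates looked
# up on the cohort KM curve at each patient's own follow-up time, binned
# into the standard 20-point intervals; a cohort qualifies when every
# populated interval holds >= 3 patients and >= 3 intervals are populated.
within_tissue_analysis <- function(patients, curves, config) {
  out <- list()
  for (cc in names(curves)) {
    rows <- dplyr::filter(patients, .data$cohort == cc, !is.na(.data$entropy),
                          !is.na(.data$time_days))
    if (nrow(rows) == 0) next
    surv <- survival_rate_at(curves[[cc]], rows$time_days)
    surv <- pmin(pmax(surv, 1e-9), 100)
    bins <- bin_patients_by_survival(tibble(patient_id = rows$patient_id,
                                            survival = surv))
    populated <- bins$intervals[bins$intervals$n > 0, ]
    eligible <- nrow(populated) >= 3 && all(populated$eligible)
    interval_means <- dplyr::summarise(
      dplyr::group_by(dplyr::mutate(bins$assignments, entropy = rows$entropy),
                      .data$interval, .drop = TRUE),
      n = dplyr::n(),
      survival = mean(.data$survival),
      entropy = mean(.data$entropy),
      .groups = "drop")
    reg <- NULL
    if (eligible) {
      reg <- tryCatch(
        entropy_survival_regression(interval_means[c("survival", "entropy")]),
        netentropy_error = function(e) NULL)
    }
    out[[cc]] <- list(eligible = eligible, intervals = interval_means,
                      regression = reg)
  }
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d patients in %d cohort(s)\n",
              nrow(x$patients), nrow(x$cohorts)))
  if (!is.null(x$comparison)) print(x$comparison)
  if (!is.null(x$regression)) print(x$regression)
  if (!is.na(x$h_goal)) cat(sprintf("  entropy goal (100%% survival): %.4f bits\n", x$h_goal))
  for (n in x$notices) cat("  note:", n, "\n")
  invisible(x)
}

#' @export
glance.cohort_report <- function(x, ...) {
  tibble(
    n_patients = nrow(x$patients),
    n_cohorts = nrow(x$cohorts),
    kw_statistic = if (is.null(x$comparison)) NA_real_ else x$comparison$kw_statistic,
    kw_df = if (is.null(x$comparison)) NA_integer_ else x$comparison$kw_df,
    slope = if (is.null(x$regression)) NA_real_ else x$regression$slope,
    intercept = if (is.null(x$regression)) NA_real_ else x$regression$intercept,
    r = if (is.null(x$regression)) NA_real_ else x$regression$r,
    p_value = if (is.null(x$regression)) NA_real_ else x$regression$p_value,
    h_goal = x$h_goal
  )
}
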