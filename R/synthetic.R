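#' Specification of a synthetic study
#'
#' Bundles every knob of the synthetic-data generator. All outputs are pure
#' functions of the spec (bit-identical per seed). The defaults describe a
#' desk-scale study: a 2,000-protein scale-free interactome, 9 cohorts of
#' 30 paired patients over 2,000 mapped genes, unit-variance Gaussian
#' differential-expression bulk with planted up-regulation at five standard
#' deviations, and censored exponential survival linked to cohort entropy.
#'
#' @param seed Master integer seed.
#' @param n_proteins Interactome size.
#' @param attachment Preferential-attachment edges per new node.
#' @param n_genes Mapped gene universe size (`<= n_proteins`).
#' @param n_patients_per_cohort,n_cohorts Cohort layout.
#' @param planted_fraction Fraction of genes planted up-regulated per
#'   patient, in (0, 0.2].
#' @param effect_size Mean shift of planted genes (RSEM units).
#' @param bulk_sigma SD of the null differential-expression bulk.
#' @param survival_link `c(slope, intercept)` mapping cohort mean entropy
#'   (bits) to true 5-year survival percent; slope must be negative so
#'   higher-entropy cohorts survive less. The default maps the entropy
#'   scale of default-size synthetic subnetworks (roughly 1 to 2.3 bits
#'   across cohorts) onto 5-year survival rates spanning roughly 35-95%,
#'   the range spanned by real multi-cancer panels.
#' @param censoring_rate Probability a record is censored, in `[0, 1)`.
#' @param planting Either `"degree"` (planted genes sampled with
#'   probability proportional to interactome degree, so planted
#'   subnetworks contain hubs) or `"uniform"`.
#' @param hub_bias_range Range of per-cohort exponents applied to the
#'   degree-proportional planting weights, spread evenly across cohorts so
#'   cohorts differ in subnetwork composition (and hence mean entropy).
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1,
                           n_proteins = 2000,
                           attachment = 2,
                           n_genes = 2000,
                           n_patients_per_cohort = 30,
                           n_cohorts = 9,
                           planted_fraction = 0.05,
                           effect_size = 5,
                           bulk_sigma = 1,
                           survival_link = c(slope = -48, intercept = 143),
                           censoring_rate = 0.3,
                           planting = c("degree", "uniform"),
                           hub_bias_range = c(0.25, 1.75)) {
  planting <- match.arg(planting)
  stopifnot(n_proteins > attachment, attachment >= 1, n_genes >= 1,
            n_patients_per_cohort >= 1, n_cohorts >= 1,
            bulk_sigma > 0, censoring_rate >= 0, censoring_rate < 1)
  if (!(planted_fraction > 0 && planted_fraction <= 0.2)) {
    ne_abort("planted_fraction must lie in (0, 0.2]", "precondition_error")
  }
  if (n_genes > n_proteins) {
    ne_abort("n_genes cannot exceed the number of mappable proteins", "precondition_error")
  }
  structure(list(seed = as.integer(seed), n_proteins = n_proteins,
                 attachment = attachment, n_genes = n_genes,
                 n_patients_per_cohort = n_patients_per_cohort,
                 n_cohorts = n_cohorts, planted_fraction = planted_fraction,
                 effect_size = effect_size, bulk_sigma = bulk_sigma,
                 survival_link = c(slope = unname(survival_link[1]),
                                   intercept = unname(survival_link[2])),
                 censoring_rate = censoring_rate, planting = planting,
                 hub_bias_range = hub_bias_range),
            class = "synthetic_spec")
}

#' Generate a scale-free interactome
#'
#' Preferential attachment in the classic construction: start from
#' `attachment` isolated seed nodes; each subsequent node attaches to
#' `attachment` distinct existing nodes chosen with probability
#' proportional to current degree (seed nodes uniformly while all degrees
#' are zero). The result is a connected simple graph with exactly
#' `attachment * (n_proteins - attachment)` edges and a right-skewed
#' degree distribution. Accessions are `"P000001"`, `"P000002"`, ...
#'
#' @param spec A `synthetic_spec`.
#' @return An undirected simple igraph.
#' @export
generate_interactome <- function(spec) {
  n <- spec$n_proteins
  m <- spec$attachment
  if (n <= m || m < 1) ne_abort("need n_proteins > attachment >= 1", "precondition_error")
  withr::with_seed(derive_seed(spec$seed, "interactome"), {
    n_edges <- m * (n - m)
    from <- integer(n_edges); to <- integer(n_edges)
    # multiset of edge endpoints; uniform draws from it are
    # degree-proportional draws over nodes
    repeated <- integer(2 * n_edges)
    n_rep <- 0L; e <- 0L
    targets <- seq_len(m)
    for (v in (m + 1):n) {
      from[e + seq_len(m)] <- v
      to[e + seq_len(m)] <- targets
      e <- e + m
      repeated[n_rep + seq_len(2 * m)] <- c(targets, rep.int(v, m))
      n_rep <- n_rep + 2L * m
      uniq <- integer(0)
      while (length(uniq) < m) {
        uniq <- unique(c(uniq, repeated[sample.int(n_rep, m)]))
      }
      targets <- uniq[seq_len(m)]
    }
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    igraph::V(g)$name <- sprintf("P%06d", seq_len(n))
    g
  })
}

#' Generate a paired tumor/control expression cohort
#'
#' Control samples draw a log-normal baseline per gene; tumor samples add
#' Gaussian bulk noise (`sd = bulk_sigma`) to every gene and additionally
#' shift a planted per-patient gene set by `effect_size`. Planted genes are
#' sampled with probability proportional to the degree of their mapped
#' interactome protein (raised to a per-cohort exponent), so planted
#' subnetworks contain hubs and cohorts differ in composition. Gene
#' `GENE0001` maps to protein `P000001`, and so on.
#'
#' @param spec A `synthetic_spec`.
#' @param interactome The interactome from [generate_interactome()].
#' @return A list with `expression` (tibble, genes x samples), `sheet`
#'   (tibble: patient_id, tumor_sample, control_sample), `clinical_base`
#'   (tibble: patient_id, cohort), `map` (symbol/accession tibble) and
#'   `truth` (tibble: patient_id, gene planted).
#' @export
generate_paired_cohort <- function(spec, interactome) {
  n_genes <- spec$n_genes
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  accs <- sprintf("P%06d", seq_len(n_genes))
  map <- tibble(symbol = genes, accession = accs)
  n_planted <- max(1L, round(spec$planted_fraction * n_genes))
  if (n_planted > n_genes) ne_abort("planted set larger than gene universe", "precondition_error")
  deg <- igraph::degree(interactome)[accs]
  cohort_labels <- sprintf("C%02d", seq_len(spec$n_cohorts))
  gammas <- if (spec$n_cohorts == 1) mean(spec$hub_bias_range) else
    seq(spec$hub_bias_range[1], spec$hub_bias_range[2], length.out = spec$n_cohorts)

  withr::with_seed(derive_seed(spec$seed, "cohort"), {
    baseline <- rlnorm(n_genes, meanlog = 5, sdlog = 1)
    records <- list(); truth <- list(); cols <- list(); sheet <- list()
    idx <- 1L
    for (ci in seq_len(spec$n_cohorts)) {
      w <- if (spec$planting == "degree") deg^gammas[ci] else rep(1, n_genes)
      for (pi in seq_len(spec$n_patients_per_cohort)) {
        pid <- sprintf("%s-P%03d", cohort_labels[ci], pi)
        control <- baseline + rnorm(n_genes, 0, spec$bulk_sigma / 2)
        planted <- sample.int(n_genes, n_planted, prob = w)
        diffs <- rnorm(n_genes, 0, spec$bulk_sigma)
        diffs[planted] <- diffs[planted] + spec$effect_size
        tumor <- control + diffs
        cols[[paste0(pid, "-N")]] <- pmax(control, 0)
        cols[[paste0(pid, "-T")]] <- pmax(tumor, 0)
        sheet[[idx]] <- tibble(patient_id = pid,
                               tumor_sample = paste0(pid, "-T"),
                               control_sample = paste0(pid, "-N"))
        records[[idx]] <- tibble(patient_id = pid, cohort = cohort_labels[ci])
        truth[[idx]] <- tibble(patient_id = pid, gene = genes[planted])
        idx <- idx + 1L
      }
    }
    list(expression = dplyr::bind_cols(tibble(gene = genes), as_tibble(cols)),
         sheet = dplyr::bind_rows(sheet),
         clinical_base = dplyr::bind_rows(records),
         map = map,
         truth = dplyr::bind_rows(truth))
  })
}

#' Generate censored survival records linked to cohort entropy
#'
#' Event times are exponential with rate chosen so the true five-year
#' survival `S(1825)` equals the entropy-survival link evaluated at the
#' cohort's mean entropy, clamped to (1, 99) percent. Each record is
#' independently censored with probability `censoring_rate`; a censored
#' record reports a uniform time in `(0, T)` and event 0.
#'
#' @param spec A `synthetic_spec` (slope of `survival_link` must be
#'   negative, mirroring lower survival at higher entropy).
#' @param cohort_entropies Numeric vector of cohort mean entropies (bits),
#'   one per cohort; names are used as cohort labels when present.
#' @param patient_ids Optional tibble (`patient_id`, `cohort`) to assign
#'   records to existing patients; defaults to the spec's cohort layout.
#' @return A survival tibble: `patient_id`, `event`, `time_days`, `cohort`.
#' @export
generate_survival_records <- function(spec, cohort_entropies, patient_ids = NULL) {
  if (!(spec$survival_link[["slope"]] < 0)) {
    ne_abort("survival_link slope must be negative", "precondition_error")
  }
  labels <- names(cohort_entropies) %||% sprintf("C%02d", seq_along(cohort_entropies))
  if (is.null(patient_ids)) {
    patient_ids <- tidyr::expand_grid(cohort = labels,
                                      i = seq_len(spec$n_patients_per_cohort))
    patient_ids$patient_id <- sprintf("%s-P%03d", patient_ids$cohort, patient_ids$i)
    patient_ids <- patient_ids[c("patient_id", "cohort")]
  }
  s5 <- spec$survival_link[["slope"]] * cohort_entropies +
    spec$survival_link[["intercept"]]
  s5 <- pmin(pmax(s5, 1), 99) / 100
  rate <- -log(s5) / 1825
  names(rate) <- labels
  withr::with_seed(derive_seed(spec$seed, "survival"), {
    t_event <- rexp(nrow(patient_ids), rate = rate[patient_ids$cohort])
    censored <- runif(nrow(patient_ids)) < spec$censoring_rate
    time <- ifelse(censored, runif(nrow(patient_ids), 0, t_event), t_event)
    tibble(patient_id = patient_ids$patient_id,
           event = as.integer(!censored),
           time_days = pmax(time, 1e-6),
           cohort = patient_ids$cohort)
  })
}

#' Write a complete synthetic dataset in the pipeline's input formats
#'
#' Emits exactly the files the readers consume - expression TSV, sample
#' sheet, symbol/accession mapping, a PSI-MITAB interactome (interactor and
#' taxon columns populated, others `-`) and a clinical TSV - so synthetic
#' runs exercise the real parsers end to end. By default the survival
#' records are linked to the cohort mean subnetwork entropies actually
#' measured by running the up-regulation caller on the generated cohort,
#' so 5-year survival genuinely decreases with subnetwork entropy in the
#' emitted study.
#'
#' @param spec A `synthetic_spec`.
#' @param dir Output directory (created if needed).
#' @param cohort_entropies Optional named entropies (bits, one per cohort)
#'   for [generate_survival_records()]; when `NULL` they are measured from
#'   the generated cohort itself.
#' @return Named character vector of file paths (`expression`, `sheet`,
#'   `mapping`, `interactome`, `clinical`), plus the generated objects as
#'   attribute `objects`.
#' @export
write_synthetic_dataset <- function(spec, dir, cohort_entropies = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  interactome <- generate_interactome(spec)
  cohort <- generate_paired_cohort(spec, interactome)
  if (is.null(cohort_entropies)) {
    cohort_entropies <- measure_cohort_entropies(interactome, cohort)
  }
  clinical <- generate_survival_records(spec, cohort_entropies,
                                        cohort$clinical_base)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             sheet = file.path(dir, "samples.tsv"),
             mapping = file.path(dir, "mapping.tsv"),
             interactome = file.path(dir, "interactome.mitab.txt"),
             clinical = file.path(dir, "clinical.tsv"))
  write_tsv_plain(cohort$expression, paths[["expression"]])
  write_tsv_plain(cohort$sheet, paths[["sheet"]])
  write_tsv_plain(cohort$map, paths[["mapping"]])
  write_mitab_lite(interactome, paths[["interactome"]])
  clin_out <- tibble(patient_id = clinical$patient_id, OS = clinical$event,
                     `OS.time` = clinical$time_days, cohort = clinical$cohort)
  write_tsv_plain(clin_out, paths[["clinical"]])
  structure(paths, objects = list(interactome = interactome, cohort = cohort,
                                  clinical = clinical))
}

# Cohort mean subnetwork entropies of a generated cohort, measured through
# the same calling chain the pipeline uses (no removal nulls).
measure_cohort_entropies <- function(interactome, cohort,
                                     n_bins = 100, alpha = 0.05) {
  ents <- vapply(seq_len(nrow(cohort$sheet)), function(i) {
    pair <- patient_pair(
      cohort$sheet$patient_id[i],
      tumor = setNames(cohort$expression[[cohort$sheet$tumor_sample[i]]],
                       cohort$expression$gene),
      control = setNames(cohort$expression[[cohort$sheet$control_sample[i]]],
                         cohort$expression$gene))
    prof <- differential_profile(pair)
    fit <- tryCatch(fit_gaussian_threshold(build_histogram(prof, n_bins), alpha),
                    netentropy_error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    up <- suppressMessages(select_upregulated(prof, fit, cohort$map))
    sub <- tryCatch(
      suppressMessages(induce_subnetwork(interactome, up$proteins, pair$patient_id)),
      netentropy_error = function(e) NULL)
    if (is.null(sub)) NA_real_ else shannon_entropy(sub)$H
  }, numeric(1))
  out <- tapply(ents, cohort$clinical_base$cohort, mean, na.rm = TRUE)
  out[is.na(out)] <- mean(out, na.rm = TRUE)
  out
}

write_tsv_plain <- function(tb, path) {
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(paste(names(tb), collapse = "\t"), con, useBytes = TRUE)
  chr <- lapply(tb, format_field)
  writeLines(do.call(paste, c(chr, sep = "\t")), con, useBytes = TRUE)
  invisible(path)
}

write_mitab_lite <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  filler <- paste(rep("-", 7), collapse = "\t")
  lines <- paste(paste0("uniprotkb:", el[, 1]),
                 paste0("uniprotkb:", el[, 2]),
                 filler,
                 "taxid:9606(human)", "taxid:9606(human)",
                 "-", "-", "-", "-",
                 sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
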