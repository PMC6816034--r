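test_that("the preferential-attachment interactome has the stated size and shape", {
  spec <- synthetic_spec(seed = 1, n_proteins = 100, attachment = 2, n_genes = 50)
  g <- generate_interactome(spec)
  expect_equal(igraph::vcount(g), 100)
  expect_equal(igraph::ecount(g), 2 * (100 - 2))
  expect_true(igraph::is_simple(g))
  expect_true(igraph::is_connected(g))
  expect_equal(igraph::V(g)$name[1], "P000001")

  tree <- generate_interactome(synthetic_spec(seed = 2, n_proteins = 50,
                                              attachment = 1, n_genes = 10))
  expect_equal(igraph::ecount(tree), 49)

  # determinism per seed
  g2 <- generate_interactome(spec)
  expect_identical(igraph::as_edgelist(g), igraph::as_edgelist(g2))
  g3 <- generate_interactome(synthetic_spec(seed = 99, n_proteins = 100,
                                            attachment = 2, n_genes = 50))
  expect_false(identical(igraph::as_edgelist(g), igraph::as_edgelist(g3)))
})

test_that("generated interactomes are right-skewed (hubs exist)", {
  for (s in 1:5) {
    spec <- synthetic_spec(seed = s, n_proteins = 300, n_genes = 300)
    deg <- igraph::degree(generate_interactome(spec))
    expect_gte(max(deg), 5 * stats::median(deg))
  }
})

test_that("paired cohorts are deterministic and planted truth is recoverable", {
  spec <- small_spec(seed = 3)
  ia <- generate_interactome(spec)
  co1 <- generate_paired_cohort(spec, ia)
  co2 <- generate_paired_cohort(spec, ia)
  expect_identical(co1$expression, co2$expression)
  expect_identical(co1$truth, co2$truth)
  expect_equal(nrow(co1$sheet), 9)       # 3 cohorts x 3 patients
  expect_equal(ncol(co1$expression), 1 + 18)
  expect_true(all(unlist(co1$expression[-1]) >= 0))

  # planted recovery through the real caller at 5-sigma effect
  pid <- co1$sheet$patient_id[1]
  pair <- patient_pair(
    pid,
    tumor = stats::setNames(co1$expression[[co1$sheet$tumor_sample[1]]],
                            co1$expression$gene),
    control = stats::setNames(co1$expression[[co1$sheet$control_sample[1]]],
                              co1$expression$gene))
  prof <- differential_profile(pair)
  fit <- fit_gaussian_threshold(build_histogram(prof, 100))
  up <- select_upregulated(prof, fit, co1$map)
  planted <- co1$truth$gene[co1$truth$patient_id == pid]
  expect_gte(length(intersect(up$genes, planted)) / length(planted), 0.85)
})

test_that("with zero effect size planted genes are indistinguishable from nulls", {
  spec <- small_spec(seed = 4, effect_size = 0)
  ia <- generate_interactome(spec)
  co <- generate_paired_cohort(spec, ia)
  pid <- co$sheet$patient_id[1]
  pair <- patient_pair(
    pid,
    tumor = stats::setNames(co$expression[[co$sheet$tumor_sample[1]]], co$expression$gene),
    control = stats::setNames(co$expression[[co$sheet$control_sample[1]]], co$expression$gene))
  prof <- differential_profile(pair)
  fit <- fit_gaussian_threshold(build_histogram(prof, 100))
  up <- select_upregulated(prof, fit, co$map)
  planted <- co$truth$gene[co$truth$patient_id == pid]
  # recovery should be near the false-positive rate, nowhere near 90%
  expect_lt(length(intersect(up$genes, planted)) / length(planted), 0.5)
})

test_that("survival records honor the entropy link and censoring settings", {
  spec <- synthetic_spec(seed = 5, n_patients_per_cohort = 400, n_cohorts = 2,
                         censoring_rate = 0)
  ents <- c(C01 = 1.2, C02 = 2.1)   # C01 should survive better
  recs <- generate_survival_records(spec, ents)
  expect_equal(nrow(recs), 800)
  expect_true(all(recs$event == 1L))
  s5 <- vapply(split(recs, recs$cohort), function(d) {
    survival_rate_at(km_curve(d), 1825)
  }, numeric(1))
  expect_gt(s5[["C01"]], s5[["C02"]])
  link <- function(h) min(max(spec$survival_link[["slope"]] * h +
                                spec$survival_link[["intercept"]], 1), 99)
  expect_lt(abs(s5[["C01"]] - link(1.2)), 10)
  expect_lt(abs(s5[["C02"]] - link(2.1)), 10)

  censored <- generate_survival_records(
    synthetic_spec(seed = 5, n_patients_per_cohort = 400, n_cohorts = 1,
                   censoring_rate = 0.4), c(C01 = 1.5))
  expect_lt(abs(mean(censored$event == 0L) - 0.4), 0.08)
  expect_true(all(censored$time_days > 0))

  expect_error(generate_survival_records(
    synthetic_spec(seed = 1, survival_link = c(slope = 1, intercept = 0)),
    c(C01 = 2)), class = "precondition_error")
})

test_that("regression on KM rates recovers the negative entropy-survival link", {
  hits <- 0L
  ents <- seq(1.1, 2.1, length.out = 9)
  names(ents) <- sprintf("C%02d", 1:9)
  for (s in 1:20) {
    spec <- synthetic_spec(seed = s, n_patients_per_cohort = 50, n_cohorts = 9)
    recs <- generate_survival_records(spec, ents)
    s5 <- vapply(split(recs, recs$cohort), function(d) {
      survival_rate_at(km_curve(d), 1825)
    }, numeric(1))
    reg <- entropy_survival_regression(
      tibble::tibble(survival = unname(s5[names(ents)]), entropy = unname(ents)))
    if (reg$slope < 0 && reg$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("a written synthetic dataset is read back by the real parsers", {
  spec <- small_spec(seed = 6)
  dir <- withr::local_tempdir()
  paths <- suppressMessages(write_synthetic_dataset(spec, dir))
  expect_true(all(file.exists(paths)))

  expr <- read_expression_table(paths[["expression"]])
  objs <- attr(paths, "objects")
  expect_identical(expr$gene, objs$cohort$expression$gene)
  expect_equal(expr[[2]], objs$cohort$expression[[2]], tolerance = 1e-12)

  map <- suppressMessages(read_id_mapping(paths[["mapping"]]))
  expect_equal(nrow(map), spec$n_genes)

  ia <- suppressMessages(read_interactome_mitab(paths[["interactome"]]))
  expect_equal(igraph::ecount(ia), igraph::ecount(objs$interactome))
  expect_setequal(igraph::V(ia)$name, igraph::V(objs$interactome)$name)

  clin <- read_clinical_table(paths[["clinical"]])
  expect_equal(nrow(clin), 9)
  pairs <- read_sample_pairs(expr, paths[["sheet"]])
  expect_length(pairs, 9)
})
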