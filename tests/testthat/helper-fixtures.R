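# Shared fixtures: tiny named graphs, file writers, and independent oracles.

named_graph <- function(edges) {
  # edges: character vector like c("A-B", "B-C")
  parts <- do.call(rbind, strsplit(edges, "-", fixed = TRUE))
  igraph::graph_from_edgelist(parts, directed = FALSE)
}

star_graph <- function(leaves = 4) {
  named_graph(paste0("C-", "L", seq_len(leaves)))
}

path_abc <- function() named_graph(c("A-B", "B-C"))

ring_graph <- function(n) {
  v <- sprintf("R%02d", seq_len(n))
  named_graph(paste(v, c(v[-1], v[1]), sep = "-"))
}

# Two degree-5 centers joined to each other, each with 4 leaves.
double_star <- function() {
  named_graph(c("A-B", paste0("A-", "a", 1:4), paste0("B-", "b", 1:4)))
}

# Independent brute-force evaluation of the degree-distribution entropy:
# explicit frequency loop, no shared code with the package internals.
oracle_entropy <- function(degrees) {
  degrees <- degrees[degrees > 0]
  if (length(degrees) == 0) return(0)
  H <- 0
  for (k in unique(degrees)) {
    pk <- sum(degrees == k) / length(degrees)
    H <- H - pk * log(pk) / log(2)
  }
  H
}

write_tmp <- function(lines, ext = ".tsv") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# A patient pair whose differentials are exactly `diffs` over genes g1..gn.
pair_from_diffs <- function(diffs, id = "pt1") {
  genes <- paste0("g", seq_along(diffs))
  patient_pair(id,
               tumor = stats::setNames(diffs, genes),
               control = stats::setNames(rep(0, length(diffs)), genes))
}

# Seeded standard-normal differential profile of n genes.
normal_profile <- function(n = 9190, seed = 1, mu = 0, sigma = 1) {
  withr::with_seed(seed, pair_from_diffs(stats::rnorm(n, mu, sigma)))
}

small_spec <- function(seed = 1, ...) {
  synthetic_spec(seed = seed, n_proteins = 300, n_genes = 300,
                 n_patients_per_cohort = 3, n_cohorts = 3, ...)
}

# One planted patient's induced subnetwork over a seeded scale-free
# interactome, produced through the full up-regulation caller.
planted_subnetwork <- function(seed, n = 300, planted_fraction = 0.2) {
  spec <- synthetic_spec(seed = seed, n_proteins = n, n_genes = n,
                         n_patients_per_cohort = 1, n_cohorts = 1,
                         planted_fraction = planted_fraction)
  ia <- generate_interactome(spec)
  co <- generate_paired_cohort(spec, ia)
  pair <- patient_pair(
    co$sheet$patient_id[1],
    tumor = stats::setNames(co$expression[[co$sheet$tumor_sample[1]]],
                            co$expression$gene),
    control = stats::setNames(co$expression[[co$sheet$control_sample[1]]],
                              co$expression$gene))
  prof <- differential_profile(pair)
  fit <- fit_gaussian_threshold(build_histogram(prof, 100))
  up <- select_upregulated(prof, fit, co$map)
  suppressMessages(induce_subnetwork(ia, up$proteins, pair$patient_id))
}
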