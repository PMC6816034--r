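#' Read a normalized gene-expression table
#'
#' Parses a tab-separated expression matrix in the TCGA RNASeqV2 level-3
#' layout: first column gene identifiers, remaining columns one sample each,
#' header row present. Values are RSEM upper-quartile normalized expression
#' and are consumed as given. Gene identifiers of the form
#' `"SYMBOL|ENTREZ"` are truncated at the first `|` to the bare symbol, so
#' both TCGA-style and plain-symbol files are accepted.
#'
#' @param path Path to a UTF-8, tab-separated file.
#' @return A tibble with a `gene` character column followed by one numeric
#'   column per sample. Invariants enforced: no duplicate gene symbols, no
#'   duplicate sample identifiers, all values finite and `>= 0`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tS1\tS2", "TP53|7157\t10\t3.5", "EGFR\t0\t7"), f)
#' read_expression_table(f)
read_expression_table <- function(path) {
  lines <- read_nonempty_lines(path)
  if (length(lines) < 2) {
    ne_abort("expression file must have a header row and at least one gene row",
             "parse_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1]])
  if (width < 2) ne_abort("header must name at least one sample column", "parse_error")
  bad <- which(lengths(fields) != width)
  if (length(bad) > 0) {
    ne_abort(sprintf("malformed row width at line %d: expected %d fields, found %d",
                     bad[1], width, lengths(fields)[bad[1]]),
             "parse_error")
  }
  samples <- fields[[1]][-1]
  if (anyDuplicated(samples)) {
    ne_abort("duplicate sample identifiers in header", "validation_error")
  }
  body <- fields[-1]
  genes <- trim_gene_id(vapply(body, `[[`, character(1), 1L))
  if (anyDuplicated(genes)) {
    ne_abort(sprintf("duplicate gene symbol: %s",
                     genes[duplicated(genes)][1]), "validation_error")
  }
  vals <- matrix(
    suppressWarnings(as.numeric(unlist(lapply(body, `[`, -1L), use.names = FALSE))),
    nrow = length(body), ncol = width - 1, byrow = TRUE
  )
  if (anyNA(vals) || any(!is.finite(vals))) {
    row <- which(apply(vals, 1, function(v) anyNA(v) | any(!is.finite(v))))[1]
    ne_abort(sprintf("non-numeric or non-finite expression value at line %d", row + 1),
             "validation_error")
  }
  if (any(vals < 0)) {
    row <- which(apply(vals, 1, function(v) any(v < 0)))[1]
    ne_abort(sprintf("negative expression value at line %d", row + 1),
             "validation_error")
  }
  colnames(vals) <- samples
  dplyr::bind_cols(tibble(gene = genes), as_tibble(vals))
}

trim_gene_id <- function(x) sub("\\|.*$", "", x)

read_nonempty_lines <- function(path) {
  if (!file.exists(path)) ne_abort(sprintf("cannot read '%s'", path), "io_error")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines[nzchar(lines)]
}

#' Assemble per-patient tumor/control pairs from a sample sheet
#'
#' The sheet makes pairing explicit rather than relying on barcode
#' conventions: one row per patient naming the tumor and the control sample,
#' both of which must be columns of `table`.
#'
#' @param table An expression table from [read_expression_table()].
#' @param sheet Path to a TSV with columns `patient_id`, `tumor_sample`,
#'   `control_sample`.
#' @return A list of `patient_pair` objects, each holding named tumor and
#'   control expression vectors over the identical gene universe.
#' @export
read_sample_pairs <- function(table, sheet) {
  sh <- read_tsv_cols(sheet, c("patient_id", "tumor_sample", "control_sample"))
  missing <- setdiff(unique(c(sh$tumor_sample, sh$control_sample)), names(table))
  if (length(missing) > 0) {
    ne_abort(sprintf("sample identifier(s) absent from expression table: %s",
                     paste(missing, collapse = ", ")),
             "resolution_error")
  }
  purrr::pmap(sh, function(patient_id, tumor_sample, control_sample) {
    patient_pair(
      patient_id = patient_id,
      tumor = setNames(table[[tumor_sample]], table$gene),
      control = setNames(table[[control_sample]], table$gene)
    )
  })
}

#' @rdname read_sample_pairs
#' @param patient_id Patient identifier.
#' @param tumor,control Named numeric expression vectors over the same genes.
#' @export
patient_pair <- function(patient_id, tumor, control) {
  if (!identical(names(tumor), names(control))) {
    ne_abort("tumor and control must index the identical gene list", "validation_error")
  }
  structure(list(patient_id = patient_id, tumor = tumor, control = control),
            class = "patient_pair")
}

#' @export
print.patient_pair <- function(x, ...) {
  cat(sprintf("<patient_pair> %s: %d genes\n", x$patient_id, length(x$tumor)))
  invisible(x)
}

# Header-checked TSV reader used for the small sheet-like inputs.
read_tsv_cols <- function(path, cols) {
  lines <- read_nonempty_lines(path)
  if (length(lines) == 0) ne_abort(sprintf("'%s' is empty", path), "validation_error")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  idx <- match(cols, header)
  if (anyNA(idx)) {
    ne_abort(sprintf("'%s' lacks required column(s): %s",
                     path, paste(cols[is.na(idx)], collapse = ", ")),
             "parse_error")
  }
  body <- fields[-1]
  short <- which(lengths(body) < max(idx))
  if (length(short) > 0) {
    ne_abort(sprintf("malformed row width at line %d", short[1] + 1), "parse_error")
  }
  out <- lapply(idx, function(i) vapply(body, `[[`, character(1), i))
  names(out) <- cols
  as_tibble(out)
}

#' Read a GeneSymbol-to-UniProtKB mapping
#'
#' Two-column TSV (symbol, accession) equivalent to a curated equivalence
#' list. Mapping is one-to-one by first occurrence: later rows repeating a
#' symbol are dropped with a warning so collisions are visible but not fatal.
#'
#' @param path Path to the mapping TSV. A header row is detected (first row
#'   whose second field is literally `accession`) and skipped if present.
#' @return A tibble with columns `symbol`, `accession`.
#' @export
read_id_mapping <- function(path) {
  lines <- read_nonempty_lines(path)
  if (length(lines) == 0) ne_abort("empty mapping file", "validation_error")
  # pad trailing empty fields (strsplit drops them) so "SYM\t" is seen as
  # an empty accession, not a short row
  fields <- strsplit(paste0(lines, "\t\x01"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) f[-length(f)])
  if (length(fields[[1]]) >= 2 && fields[[1]][2] == "accession") fields <- fields[-1]
  if (length(fields) == 0) ne_abort("mapping file has no entries", "validation_error")
  short <- which(lengths(fields) < 2)
  if (length(short) > 0) {
    ne_abort(sprintf("malformed mapping row at line %d", short[1]), "parse_error")
  }
  symbol <- vapply(fields, `[[`, character(1), 1L)
  accession <- vapply(fields, `[[`, character(1), 2L)
  if (any(!nzchar(accession) | !nzchar(symbol))) {
    ne_abort("empty symbol or accession field in mapping", "validation_error")
  }
  dup <- duplicated(symbol)
  if (any(dup)) {
    ne_warn(sprintf("%d duplicate symbol row(s) dropped (first occurrence kept)",
                    sum(dup)), "duplicate_mapping_warning")
  }
  tibble(symbol = symbol[!dup], accession = accession[!dup])
}

#' Read a PSI-MITAB interactome and filter it to a human PPI graph
#'
#' Interprets only the interactor-identifier columns (1 and 2) and the taxon
#' columns (10 and 11) of the PSI-MITAB 2.5/2.7 layout. A row is kept when
#' both interactors carry a `uniprotkb:` accession and both taxa are human
#' (`taxid:9606`). Self-interactions are dropped and duplicate pairs (in
#' either orientation) are collapsed to a single undirected edge.
#'
#' @param path Path to a tab-separated PSI-MITAB file.
#' @return An undirected simple [igraph::graph] whose vertex names are
#'   UniProtKB accessions.
#' @export
read_interactome_mitab <- function(path) {
  lines <- read_nonempty_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_in <- length(fields)
  keep_a <- character(0); keep_b <- character(0)
  skipped <- 0L
  for (f in fields) {
    if (length(f) < 11) { skipped <- skipped + 1L; next }
    a <- mitab_uniprot(f[[1]]); b <- mitab_uniprot(f[[2]])
    if (is.na(a) || is.na(b)) { skipped <- skipped + 1L; next }
    if (!mitab_human(f[[10]]) || !mitab_human(f[[11]])) { skipped <- skipped + 1L; next }
    if (a == b) { skipped <- skipped + 1L; next }
    keep_a <- c(keep_a, a); keep_b <- c(keep_b, b)
  }
  if (skipped > 0) {
    inform(sprintf("read_interactome_mitab: %d of %d row(s) skipped (incomplete, non-uniprotkb, non-human, or self-interaction)",
                   skipped, n_in))
  }
  if (length(keep_a) == 0) {
    ne_abort("no interactions survive filtering (human, uniprotkb-identified, non-self)",
             "validation_error")
  }
  edges_to_graph(keep_a, keep_b)
}

mitab_uniprot <- function(field) {
  m <- regmatches(field, regexpr("uniprotkb:[^|(\t ]+", field))
  if (length(m) == 0) return(NA_character_)
  sub("^uniprotkb:", "", m)
}

mitab_human <- function(field) grepl("taxid:9606\\b", field)

# Canonicalize an edge list into an undirected simple igraph.
edges_to_graph <- function(a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi, sep = "\r")) & lo != hi
  igraph::graph_from_edgelist(cbind(lo[keep], hi[keep]), directed = FALSE)
}

#' Write / read an interactome as a two-column edge list
#'
#' Plain-text round-trip format: one undirected edge per line,
#' tab-separated, endpoints in lexicographic order, lines sorted.
#'
#' @param graph An undirected igraph.
#' @param path Output (or input) path.
#' @return `write_interactome_edgelist()` returns `path` invisibly;
#'   `read_interactome_edgelist()` returns the graph.
#' @export
write_interactome_edgelist <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  lo <- pmin(el[, 1], el[, 2]); hi <- pmax(el[, 1], el[, 2])
  writeLines(sort(paste(lo, hi, sep = "\t")), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_interactome_edgelist
#' @export
read_interactome_edgelist <- function(path) {
  lines <- read_nonempty_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2)) ne_abort("edge list rows must have two fields", "parse_error")
  edges_to_graph(vapply(fields, `[[`, character(1), 1L),
                 vapply(fields, `[[`, character(1), 2L))
}

#' Read a clinical overall-survival table
#'
#' TSV with columns `patient_id`, `OS` (1 = death/event, 0 = censored),
#' `OS.time` (days to death/last follow-up, positive) and `cohort` (cancer
#' type), as curated in clinical data resources.
#'
#' @param path Path to the clinical TSV.
#' @return A tibble with columns `patient_id`, `event` (integer 0/1),
#'   `time_days` (positive numeric), `cohort`.
#' @export
read_clinical_table <- function(path) {
  tb <- read_tsv_cols(path, c("patient_id", "OS", "OS.time", "cohort"))
  event <- suppressWarnings(as.numeric(tb$OS))
  time <- suppressWarnings(as.numeric(tb$OS.time))
  bad_ev <- which(is.na(event) | !(event %in% c(0, 1)))
  if (length(bad_ev) > 0) {
    ne_abort(sprintf("OS must be 0 or 1 (row %d)", bad_ev[1]), "validation_error")
  }
  bad_t <- which(is.na(time) | time <= 0)
  if (length(bad_t) > 0) {
    ne_abort(sprintf("OS.time must be a positive number of days (row %d)", bad_t[1]),
             "validation_error")
  }
  tibble(patient_id = tb$patient_id, event = as.integer(event),
         time_days = time, cohort = tb$cohort)
}

#' Write the per-patient report as TSV plus a JSON sidecar
#'
#' The TSV carries one row per patient (identifier, number of up-regulated
#' genes, subnetwork size, entropy, semicolon-joined top hubs, empirical p
#' of the hub-vs-random null, targets required). The JSON sidecar
#' (`<path>.json`) carries the full hub rankings. Output is deterministic:
#' rewriting the same report yields byte-identical files.
#'
#' @param report A list of `patient_report` objects or a tibble as produced
#'   by [tidy_patient_reports()].
#' @param path Output TSV path.
#' @return Invisibly, the paths written.
#' @export
write_patient_report <- function(report, path) {
  tb <- if (inherits(report, "data.frame")) as_tibble(report) else tidy_patient_reports(report)
  cols <- c("patient_id", "n_upregulated", "n_nodes", "n_edges", "entropy",
            "hubs", "empirical_p", "n_targets")
  for (nm in setdiff(cols, names(tb))) tb[[nm]] <- NA
  tb <- tb[cols]
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(paste(cols, collapse = "\t"), con, useBytes = TRUE)
  if (nrow(tb) > 0) {
    chr <- lapply(tb, format_field)
    writeLines(do.call(paste, c(chr, sep = "\t")), con, useBytes = TRUE)
  }
  sidecar <- paste0(path, ".json")
  rankings <- if (inherits(report, "data.frame")) list() else
    lapply(report, function(p) list(
      patient_id = p$patient_id,
      top20 = if (is.null(p$top20)) list() else as.list(setNames(p$top20$degree, p$top20$accession))
    ))
  jsonlite::write_json(rankings, sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(path, sidecar))
}

format_field <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.numeric(v)) format(v, digits = 15, scientific = FALSE, trim = TRUE)
    else as.character(v)
  }, character(1))
}
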