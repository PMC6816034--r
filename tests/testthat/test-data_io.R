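test_that("expression tables parse, truncate TCGA gene ids, and validate", {
  f <- write_tmp(c("gene\tS1\tS2",
                   "TP53|7157\t10\t3.5",
                   "EGFR\t0\t7",
                   "BRCA1\t2.25\t0.125"))
  tb <- read_expression_table(f)
  expect_equal(names(tb), c("gene", "S1", "S2"))
  expect_equal(tb$gene, c("TP53", "EGFR", "BRCA1"))
  # exact value round-trip, no numeric mangling
  expect_identical(tb$S1, c(10, 0, 2.25))
  expect_identical(tb$S2, c(3.5, 7, 0.125))

  expect_error(read_expression_table(write_tmp(c("gene\tS1", "A\t-1"))),
               class = "validation_error")
  expect_error(read_expression_table(write_tmp(c("gene\tS1\tS2", "A\t1"))),
               regexp = "line 2", class = "parse_error")
  expect_error(read_expression_table(write_tmp(c("gene\tS1\tS1", "A\t1\t2"))),
               class = "validation_error")
  expect_error(read_expression_table(write_tmp(c("gene\tS1", "A\t1", "A\t2"))),
               class = "validation_error")
})

test_that("sample sheets resolve pairs against the expression table", {
  tb <- read_expression_table(write_tmp(c("gene\tT1\tN1\tT2\tN2",
                                          "A\t5\t3\t1\t4",
                                          "B\t2\t2\t0\t0")))
  sheet <- write_tmp(c("patient_id\ttumor_sample\tcontrol_sample",
                       "p1\tT1\tN1",
                       "p2\tT2\tN2"))
  pairs <- read_sample_pairs(tb, sheet)
  expect_length(pairs, 2)
  expect_s3_class(pairs[[1]], "patient_pair")
  expect_equal(pairs[[1]]$tumor, c(A = 5, B = 2))
  expect_equal(pairs[[2]]$control, c(A = 4, B = 0))

  bad <- write_tmp(c("patient_id\ttumor_sample\tcontrol_sample", "p1\tX\tN1"))
  expect_error(read_sample_pairs(tb, bad), regexp = "X", class = "resolution_error")

  empty <- write_tmp("patient_id\ttumor_sample\tcontrol_sample")
  expect_length(read_sample_pairs(tb, empty), 0)
})

test_that("id mapping keeps first occurrence and rejects empty fields", {
  f <- write_tmp(c("TP53\tP04637", "EGFR\tP00533", "MYC\tP01106"))
  m <- read_id_mapping(f)
  expect_equal(nrow(m), 3)

  dup <- write_tmp(c("TP53\tP04637", "TP53\tP99999"))
  expect_warning(m2 <- read_id_mapping(dup), class = "duplicate_mapping_warning")
  expect_equal(nrow(m2), 1)
  expect_equal(m2$accession, "P04637")

  expect_error(read_id_mapping(write_tmp(c("TP53\t"))), class = "validation_error")
  expect_error(read_id_mapping(write_tmp(character(0))), class = "validation_error")
})

test_that("MITAB filtering keeps human uniprotkb pairs, drops self and duplicate edges", {
  filler <- paste(rep("-", 7), collapse = "\t")
  row <- function(a, b, ta, tb) paste(a, b, filler, ta, tb, "-", "-", "-", "-", sep = "\t")
  f <- write_tmp(c(
    row("uniprotkb:A", "uniprotkb:B", "taxid:9606(human)", "taxid:9606(human)"),
    row("uniprotkb:B", "uniprotkb:A", "taxid:9606(human)", "taxid:9606(human)"),
    row("uniprotkb:A", "uniprotkb:A", "taxid:9606(human)", "taxid:9606(human)"),
    row("uniprotkb:A", "uniprotkb:C", "taxid:10090(mouse)", "taxid:9606(human)")
  ), ext = ".txt")
  g <- suppressMessages(read_interactome_mitab(f))
  expect_equal(sort(igraph::V(g)$name), c("A", "B"))
  expect_equal(igraph::ecount(g), 1)

  # row lacking uniprotkb prefix on one interactor is skipped, not fatal
  f2 <- write_tmp(c(
    row("chebi:1234", "uniprotkb:B", "taxid:9606(human)", "taxid:9606(human)"),
    row("uniprotkb:A", "uniprotkb:B", "taxid:9606(human)", "taxid:9606(human)")
  ), ext = ".txt")
  expect_message(g2 <- read_interactome_mitab(f2), regexp = "skipped")
  expect_equal(igraph::ecount(g2), 1)

  only_mouse <- write_tmp(row("uniprotkb:A", "uniprotkb:B",
                              "taxid:10090(mouse)", "taxid:10090(mouse)"),
                          ext = ".txt")
  expect_error(suppressMessages(read_interactome_mitab(only_mouse)),
               class = "validation_error")
})

test_that("MITAB filtering is order-independent and edge lists round-trip", {
  filler <- paste(rep("-", 7), collapse = "\t")
  row <- function(a, b) paste(paste0("uniprotkb:", a), paste0("uniprotkb:", b),
                              filler, "taxid:9606", "taxid:9606",
                              "-", "-", "-", "-", sep = "\t")
  rows <- c(row("A", "B"), row("B", "C"), row("C", "D"), row("D", "A"), row("B", "A"))
  g1 <- suppressMessages(read_interactome_mitab(write_tmp(rows, ext = ".txt")))
  g2 <- suppressMessages(read_interactome_mitab(write_tmp(rev(rows), ext = ".txt")))
  edge_set <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(edge_set(g1), edge_set(g2))

  f <- withr::local_tempfile(fileext = ".tsv")
  write_interactome_edgelist(g1, f)
  g3 <- read_interactome_edgelist(f)
  expect_identical(edge_set(g1), edge_set(g3))
  expect_setequal(igraph::V(g1)$name, igraph::V(g3)$name)
})

test_that("clinical tables validate OS and OS.time row by row", {
  f <- write_tmp(c("patient_id\tOS\tOS.time\tcohort",
                   "p1\t1\t200\tLUAD",
                   "p2\t0\t1900.5\tLUAD"))
  tb <- read_clinical_table(f)
  expect_equal(tb$event, c(1L, 0L))
  expect_equal(tb$time_days, c(200, 1900.5))

  expect_error(read_clinical_table(write_tmp(c("patient_id\tOS\tOS.time\tcohort",
                                               "p1\t2\t200\tLUAD"))),
               class = "validation_error")
  expect_error(read_clinical_table(write_tmp(c("patient_id\tOS\tOS.time\tcohort",
                                               "p1\t1\t0\tLUAD"))),
               class = "validation_error")
})

test_that("patient reports write deterministically with a JSON sidecar", {
  tb <- tibble::tibble(patient_id = "p1", n_upregulated = 12L, n_nodes = 8L,
                       n_edges = 9L, entropy = 1.25, hubs = "A;B",
                       empirical_p = 0.01, n_targets = 2L)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_patient_report(tb, f1)
  write_patient_report(tb, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_length(readLines(f1), 2)
  expect_true(file.exists(paste0(f1, ".json")))

  empty <- tb[0, ]
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_patient_report(empty, f3)
  expect_length(readLines(f3), 1)  # header only
})
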