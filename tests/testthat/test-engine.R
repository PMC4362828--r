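obo <- "http://purl.obolibrary.org/obo/"

test_that("new-classes runs mint consecutive IDs in row order", {
  b <- make_clo_fixture()
  res <- run_new_classes(b$settings, b$table)
  uris <- vapply(res$classes, function(g) g$uri, character(1))
  expect_identical(uris, paste0(obo, c("CLO_0010000", "CLO_0010001", "CLO_0010002")))
  expect_identical(res$report$classes_generated, 3L)
  expect_identical(res$report$rows_read, 3L)
})

test_that("a target ontology holding the first would-be ID shifts allocation", {
  b <- make_clo_fixture()
  target <- make_target_ontology(c(10000), b$settings$id_policy, obo)
  snap <- load_ontology(withr::local_tempfile(fileext = ".owl", lines = target))
  res <- run_new_classes(b$settings, b$table, snapshot = snap)
  uris <- vapply(res$classes, function(g) g$uri, character(1))
  expect_identical(uris, paste0(obo, c("CLO_0010001", "CLO_0010002", "CLO_0010003")))
  # no collision with the scanned set
  expect_length(intersect(uris, paste0(obo, "CLO_0010000")), 0L)
})

test_that("empty tables produce a valid header-only output", {
  b <- make_clo_fixture()
  empty <- data_table(list())
  res <- run_new_classes(b$settings, empty)
  expect_identical(res$report$classes_generated, 0L)
  expect_identical(count_owl_output(res$output$serialization)$class_declarations, 0L)
})

test_that("edit-existing attaches axioms by key column", {
  b <- make_biobank_fixture(5L)
  res <- run_edit_existing(b$settings, b$table)
  expect_identical(res$report$classes_generated, 0L)
  expect_identical(unname(res$report$axioms_by_kind[["annotation"]]), 10L)

  # empty key cells are skipped with a warning
  tab <- b$table
  tab$rows[[2]][1] <- ""
  res2 <- run_edit_existing(b$settings, tab)
  expect_identical(res2$report$rows_processed, 4L)
  expect_match(res2$report$warnings, "empty key cell", all = FALSE)

  # bare local IDs resolve against the URI start portion
  tab2 <- b$table
  tab2$rows[[1]][1] <- "OBIB_9900199"
  res3 <- run_edit_existing(b$settings, tab2)
  expect_identical(res3$classes[[1]]$uri, paste0(obo, "OBIB_9900199"))

  # an explicit URI is used verbatim
  tab3 <- b$table
  tab3$rows[[1]][1] <- "http://purl.obolibrary.org/obo/X_0000001"
  res4 <- run_edit_existing(b$settings, tab3)
  expect_identical(res4$classes[[1]]$uri, "http://purl.obolibrary.org/obo/X_0000001")
})

test_that("empty-cell patterns are skipped and recorded in the report", {
  b <- make_biobank_fixture(2L)
  tab <- b$table
  tab$rows[[1]][4] <- ""   # blank definition source for row 0
  res <- run_edit_existing(b$settings, tab)
  expect_identical(unname(res$report$axioms_by_kind[["annotation"]]), 3L)
  expect_length(res$report$skipped_axioms, 1L)
  expect_identical(res$report$skipped_axioms[[1]]$row, 0L)
})

test_that("report totals equal independently recounted output axioms", {
  for (seed in c(3, 11, 29)) {
    b <- make_random_bundle(seed, rows = 6L)
    res <- run_bundle(b)
    counts <- count_owl_output(res$output$serialization)
    expect_identical(counts$annotations,
                     unname(res$report$axioms_by_kind[["annotation"]]))
    expect_identical(counts$superclasses,
                     unname(res$report$axioms_by_kind[["superclass"]]))
    expect_identical(counts$equivalents,
                     unname(res$report$axioms_by_kind[["equivalent"]]))
    expect_identical(counts$class_declarations, res$report$classes_generated)
  }
})

test_that("runs are deterministic byte for byte", {
  b <- make_random_bundle(5L, rows = 5L)
  r1 <- run_bundle(b)
  r2 <- run_bundle(b)
  expect_identical(r1$manchester, r2$manchester)
  expect_identical(r1$output$serialization, r2$output$serialization)
})

test_that("row order permutation permutes outputs without cross-row leakage", {
  b <- make_clo_fixture()
  res <- run_new_classes(b$settings, b$table)
  perm <- b$table
  perm$rows <- perm$rows[c(2, 3, 1)]
  res_p <- run_new_classes(b$settings, perm)
  labels <- function(r) {
    lapply(r$classes, function(g)
      vapply(g$annotations, function(a) a$value, character(1)))
  }
  expect_identical(labels(res_p), labels(res)[c(2, 3, 1)])
  # minted IDs still follow row order
  expect_identical(vapply(res_p$classes, function(g) g$uri, character(1)),
                   vapply(res$classes, function(g) g$uri, character(1)))
})

test_that("the CLI runs, validates and fails with the right exit codes", {
  dir <- withr::local_tempdir()
  b <- make_clo_fixture()
  settings_path <- file.path(dir, "settings.txt")
  input_path <- file.path(dir, "input.tsv")
  writeLines(b$settings_text, settings_path, sep = "")
  write_table_tsv(b$table, input_path)
  out_owl <- file.path(dir, "out.owl")
  out_omn <- file.path(dir, "out.omn")

  status <- suppressMessages(cli_main(c(
    "run", "--settings", settings_path, "--input", input_path,
    "--output", out_owl, "--emit-manchester", out_omn)))
  expect_identical(status, 0L)
  expect_true(file.exists(out_owl))
  expect_true(file.exists(out_omn))
  reparse <- count_owl_output(paste(readLines(out_owl), collapse = "\n"))
  expect_identical(reparse$class_declarations, 3L)

  # dry run on inputs with an unresolved label: validation failure, exit 1
  bad <- sub("'RIKEN Cell Bank' <[^>]+>\n", "", b$settings_text)
  bad_path <- file.path(dir, "bad-settings.txt")
  writeLines(bad, bad_path, sep = "")
  status1 <- suppressMessages(cli_main(c(
    "run", "--dry-run", "--settings", bad_path, "--input", input_path)))
  expect_identical(status1, 1L)

  # missing --input is a usage error, exit 2
  status2 <- suppressMessages(cli_main(c("run", "--settings", settings_path)))
  expect_identical(status2, 2L)

  # write-settings emits the canonical serialization
  canon <- file.path(dir, "canon.txt")
  status3 <- suppressMessages(cli_main(c(
    "write-settings", "--settings", settings_path, "--out", canon)))
  expect_identical(status3, 0L)
  expect_identical(paste0(paste(readLines(canon), collapse = "\n"), "\n"),
                   b$settings_text)

  # turtle output
  out_ttl <- file.path(dir, "out.ttl")
  status4 <- suppressMessages(cli_main(c(
    "run", "--settings", settings_path, "--input", input_path,
    "--output", out_ttl, "--output-format", "turtle")))
  expect_identical(status4, 0L)
  expect_match(paste(readLines(out_ttl), collapse = "\n"), "owl:someValuesFrom")
})
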