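clo_settings_text <- function() {
  paste(
    "# cell-line pattern settings",
    "[Operation]",
    "new_classes",
    "",
    "[Term ID]",
    "prefix=VO_",
    "digits=7",
    "start=10000",
    "",
    "[Start portion of term URI]",
    "http://purl.obolibrary.org/obo/",
    "",
    "[Term URIs]",
    "'label' <http://www.w3.org/2000/01/rdf-schema#label>",
    "'is in cell line repository' <http://purl.obolibrary.org/obo/CLO_9990001>",
    "'RIKEN Cell Bank' <http://purl.obolibrary.org/obo/CLO_9990002>",
    "",
    "[Annotations]",
    "'label' \"{$columnA} cell\"",
    "",
    "[Superclasses]",
    "'is in cell line repository' some 'RIKEN Cell Bank'",
    sep = "\n")
}

test_that("parsing reads the canonical dialect", {
  s <- parse_settings(clo_settings_text())
  expect_identical(s$operation, "new_classes")
  expect_identical(s$id_policy$prefix, "VO_")
  expect_identical(s$id_policy$digits, 7L)
  expect_identical(s$id_policy$start, 10000)
  expect_length(s$annotation_patterns, 1L)
  expect_identical(s$annotation_patterns[[1]]$value_template, "{$columnA} cell")
  expect_length(s$expression_patterns, 1L)
  expect_identical(s$expression_patterns[[1]]$kind, "superclass")
  expect_identical(unname(s$term_uris[["RIKEN Cell Bank"]]),
                   "http://purl.obolibrary.org/obo/CLO_9990002")
})

test_that("parse errors and warnings carry structure", {
  expect_warning(parse_settings(c("[Operation]", "new_classes",
                                  "[Term ID]", "prefix=X_", "digits=2", "start=0",
                                  "[Start portion of term URI]", "http://x.org/",
                                  "[Bogus section]", "stuff")),
                 "unknown settings section")
  expect_error(parse_settings(c("[Operation]", "new_classes",
                                "[Start portion of term URI]", "http://x.org/")),
               "\\[Term ID\\]")
  expect_error(parse_settings(c("[Operation]", "edit_existing",
                                "[Start portion of term URI]", "http://x.org/")),
               "\\[Key column\\]")
  err <- tryCatch(parse_settings(c("[Operation]", "new_classes",
                                   "[Term ID]", "prefix=X_", "digits=oops",
                                   "start=1",
                                   "[Start portion of term URI]", "http://x.org/")),
                  error = identity)
  expect_s3_class(err, "settings_parse_error")
  expect_match(conditionMessage(err), "line [0-9]+")
  # comments and blank lines are ignored
  s <- parse_settings(c("# header comment", "", "[Operation]", "edit_existing",
                        "[Key column]", "A",
                        "[Start portion of term URI]", "http://x.org/"))
  expect_identical(s$key_column, "A")
})

test_that("serialization emits the canonical form and round-trips", {
  s <- parse_settings(clo_settings_text())
  text <- serialize_settings(s)
  expect_match(text, "{$columnA}", fixed = TRUE)
  expect_identical(parse_settings(text), s)
  # canonical form is a fixed point
  expect_identical(serialize_settings(parse_settings(text)), text)

  minimal <- axiom_settings("new_classes", uri_start = "http://x.org/",
                            id_policy = id_policy("X_", 2L, 0))
  mt <- serialize_settings(minimal)
  expect_identical(parse_settings(mt), minimal)
  expect_false(grepl("\\[Annotations\\]|\\[Term URIs\\]", mt))
})

test_that("serialization round-trips randomized settings", {
  for (seed in 1:120) {
    s <- make_random_settings(seed)
    expect_identical(parse_settings(serialize_settings(s)), s,
                     info = paste("seed", seed))
  }
})

test_that("id policy invariants are enforced", {
  expect_error(id_policy("", 7, 0), "non-empty")
  expect_error(id_policy("A ", 7, 0), "whitespace")
  expect_error(id_policy("X_", 0, 0), "between 1 and 18")
  expect_error(id_policy("X_", 19, 0), "between 1 and 18")
  expect_error(id_policy("X_", 2, 100), "\\[0, 10\\^2\\)")
  expect_silent(id_policy("X_", 2, 99))
})

test_that("validation reports unknown labels, bad columns and capacity", {
  tab <- data_table(list(c("a", "b", "c"), c("d", "e", "f")))
  s <- axiom_settings(
    "new_classes", uri_start = "http://x.org/",
    id_policy = id_policy("X_", 2L, 95),
    term_uris = c("RIKEN Cell Bank" = "http://x.org/rcb"),
    annotation_patterns = list(
      annotation_pattern("label", "{$columnZ}")),
    expression_patterns = list(
      expression_pattern("'RIKEN Cell Bank' and 'unknown term'", "superclass")))
  issues <- validate_settings(s, tab)
  kinds <- vapply(issues, function(i) i$kind, character(1))
  expect_true("out_of_range_column" %in% kinds)        # {$columnZ} vs width 3
  expect_true("unknown_label" %in% kinds)              # 'unknown term', 'label'
  expect_false(any(grepl("RIKEN", vapply(issues, function(i) i$message,
                                         character(1)))))

  # capacity: digits=2 start=95 leaves 5 IDs; 10 rows cannot fit
  wide <- data_table(lapply(1:10, function(i) as.character(i)))
  s2 <- axiom_settings("new_classes", uri_start = "http://x.org/",
                       id_policy = id_policy("X_", 2L, 95))
  caps <- validate_settings(s2, wide)
  expect_identical(vapply(caps, function(i) i$kind, character(1)), "id_capacity")

  # a clean configuration yields no issues
  clean <- axiom_settings(
    "new_classes", uri_start = "http://x.org/",
    id_policy = id_policy("X_", 7L, 1),
    term_uris = c("part of" = "http://x.org/p", "liver" = "http://x.org/l",
                  "label" = "http://www.w3.org/2000/01/rdf-schema#label"),
    annotation_patterns = list(annotation_pattern("label", "{$columnA}")),
    expression_patterns = list(expression_pattern("'part of' some 'liver'",
                                                  "superclass")))
  expect_length(validate_settings(clean, tab), 0L)
})

test_that("validation soundness: clean settings run without errors", {
  for (seed in 1:20) {
    b <- make_random_bundle(seed, rows = 4L)
    expect_length(validate_settings(b$settings, b$table), 0L)
    expect_no_error(run_bundle(b))
  }
})
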