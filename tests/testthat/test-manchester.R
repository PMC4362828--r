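res_clo <- make_resolver(c(
  "is in cell line repository" = "http://purl.obolibrary.org/obo/CLO_9990001",
  "RIKEN Cell Bank" = "http://purl.obolibrary.org/obo/CLO_9990002",
  "derived from" = "http://purl.obolibrary.org/obo/RO_9990001",
  "part of" = "http://purl.obolibrary.org/obo/BFO_9990050",
  "liver" = "http://purl.obolibrary.org/obo/UBERON_9990001",
  "Mus musculus" = "http://purl.obolibrary.org/obo/NCBITaxon_9990001"))

test_that("the repository superclass pattern parses to an existential restriction", {
  e <- parse_class_expression("'is in cell line repository' some 'RIKEN Cell Bank'",
                              res_clo)
  expect_identical(e$kind, "some")
  expect_identical(e$property$display, "is in cell line repository")
  expect_identical(e$filler$kind, "named")
  expect_identical(e$filler$term$display, "RIKEN Cell Bank")
})

test_that("nested derived-from patterns parse with the stated precedence", {
  e <- parse_class_expression(
    "'derived from' some ('liver' and 'part of' some 'Mus musculus')", res_clo)
  expect_identical(e$kind, "some")
  expect_identical(e$filler$kind, "and")
  expect_length(e$filler$operands, 2L)
  expect_identical(e$filler$operands[[1]]$kind, "named")
  expect_identical(e$filler$operands[[1]]$term$display, "liver")
  expect_identical(e$filler$operands[[2]]$kind, "some")
  expect_identical(e$filler$operands[[2]]$property$display, "part of")

  # atom case
  atom <- parse_class_expression("'RIKEN Cell Bank'", res_clo)
  expect_identical(atom$kind, "named")

  # or binds loosest, not tightest
  e2 <- parse_class_expression("'liver' or 'liver' and not 'Mus musculus'", res_clo)
  expect_identical(e2$kind, "or")
  expect_identical(e2$operands[[2]]$kind, "and")
  expect_identical(e2$operands[[2]]$operands[[2]]$kind, "not")
})

test_that("atoms accept <URI> and bare CURIE-like forms", {
  e <- parse_class_expression("<http://x.org/A> some <http://x.org/B>",
                              make_resolver(c()))
  expect_identical(e$property$uri, "http://x.org/A")
  e2 <- parse_class_expression("'part of' some CLO_0000001", res_clo,
                               uri_start = "http://purl.obolibrary.org/obo/")
  expect_identical(e2$filler$term$uri, "http://purl.obolibrary.org/obo/CLO_0000001")
})

test_that("unresolvable labels are all reported together", {
  err <- tryCatch(
    parse_class_expression("'mystery a' and 'liver' and 'mystery b'", res_clo),
    error = identity)
  expect_s3_class(err, "label_resolution_error")
  expect_match(conditionMessage(err), "mystery a")
  expect_match(conditionMessage(err), "mystery b")
  expect_identical(sort(err$labels), c("mystery a", "mystery b"))
})

test_that("syntax errors carry positions", {
  expect_error(parse_class_expression("'liver' some", res_clo), "position")
  expect_error(parse_class_expression("('liver'", res_clo), "position")
  expect_error(parse_class_expression("'liver' 'liver'", res_clo), "trailing")
  expect_error(parse_class_expression("", res_clo), "empty")
})

test_that("rendering emits minimal parentheses and round-trips", {
  e <- ce_some(term_ref("http://x/p", "is in cell line repository"),
               ce_named(term_ref("http://x/r", "RIKEN Cell Bank")))
  expect_identical(render_class_expression(e),
                   "'is in cell line repository' some 'RIKEN Cell Bank'")
  expect_identical(
    render_class_expression(ce_named(term_ref("http://x/r", "RIKEN Cell Bank"))),
    "'RIKEN Cell Bank'")
  # quoted-label escaping survives
  odd <- ce_named(term_ref("http://x/o", "O'Hara cell"))
  expect_identical(render_class_expression(odd), "'O''Hara cell'")
  parsed <- parse_class_expression(render_class_expression(odd),
                                   make_resolver(c("O'Hara cell" = "http://x/o")))
  expect_true(expr_equal(parsed, odd))
})

test_that("random trees round-trip through render and parse", {
  set.seed(424242)
  resolver <- expression_resolver()
  for (i in 1:300) {
    e <- random_expression(max_depth = 5L)
    text <- render_class_expression(e)
    back <- parse_class_expression(text, resolver)
    expect_true(expr_equal(back, e), info = text)
  }
})

test_that("the parser agrees with the independent splitting parser", {
  resolver <- expression_resolver()
  set.seed(3030)
  for (i in 1:150) {
    e <- random_expression(max_depth = 3L)
    text <- render_class_expression(e)
    shape_pkg <- as_shape(parse_class_expression(text, resolver))
    shape_ref <- ref_parse_text(text)
    expect_identical(shape_pkg, shape_ref, info = text)
  }
})

test_that("the intermediate document lists frames in canonical section order", {
  iri <- "http://x.org/out.owl"
  expect_match(render_manchester_document(list(), iri), "Ontology: <http://x.org/out.owl>")

  g <- generated_class(
    "http://x.org/X_0001",
    annotations = list(list(property = "http://www.w3.org/2000/01/rdf-schema#label",
                            property_display = "label",
                            value = "RCB2320 cell", lang = NULL, datatype = NULL)),
    superclasses = list(ce_some(term_ref("http://x/p", "is in cell line repository"),
                                ce_named(term_ref("http://x/r", "RIKEN Cell Bank")))))
  doc <- render_manchester_document(list(g), iri)
  counts <- count_manchester_document(doc)
  expect_identical(counts$classes, 1L)
  expect_identical(counts$annotations, 1L)
  expect_identical(counts$superclasses, 1L)
  expect_true(grepl("Class: <http://x.org/X_0001>", doc, fixed = TRUE))
  expect_identical(lengths(regmatches(doc, gregexpr(" some ", doc))), 1L)
})

test_that("the cell-line bundle's document holds one restriction per row", {
  b <- make_clo_fixture()
  res <- run_bundle(b)
  n_some <- lengths(regmatches(res$manchester, gregexpr(" some ", res$manchester)))
  expect_identical(n_some, n_rows(b$table))
})
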