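fixture_rdfxml <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"\n',
    '         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"\n',
    '         xmlns:owl="http://www.w3.org/2002/07/owl#">\n',
    '  <owl:Ontology rdf:about="https://example.org/fixture"/>\n',
    '  <owl:Class rdf:about="https://example.org/A">\n',
    '    <rdfs:label>term alpha</rdfs:label>\n',
    '  </owl:Class>\n',
    '  <owl:Class rdf:about="https://example.org/B">\n',
    '    <rdfs:label>term bravo</rdfs:label>\n',
    '  </owl:Class>\n',
    '  <owl:Class rdf:about="https://example.org/C"/>\n',
    '  <owl:ObjectProperty rdf:about="https://example.org/p"/>\n',
    '</rdf:RDF>\n')
}

fixture_turtle <- function() {
  paste0(
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .\n",
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .\n",
    "<https://example.org/fixture> a owl:Ontology .\n",
    "<https://example.org/A> a owl:Class ;\n",
    "    rdfs:label \"term alpha\" .\n",
    "<https://example.org/B> a owl:Class ;\n",
    "    rdfs:label \"term bravo\" .\n",
    "<https://example.org/C> a owl:Class .\n",
    "<https://example.org/p> a owl:ObjectProperty .\n")
}

test_that("snapshots capture entities, labels and the ontology IRI", {
  path <- withr::local_tempfile(fileext = ".owl", lines = fixture_rdfxml())
  snap <- load_ontology(path)
  expect_identical(snap$ontology_iri, "https://example.org/fixture")
  expect_true(length(snap$entity_uris) >= 3L)
  expect_identical(length(snap$label_index), 2L)
  expect_identical(unname(snap$label_index[["term alpha"]]), "https://example.org/A")

  # empty (header-only) document
  empty <- paste0(
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" ',
    'xmlns:owl="http://www.w3.org/2002/07/owl#">',
    '<owl:Ontology rdf:about="https://example.org/empty"/></rdf:RDF>')
  snap0 <- load_ontology(withr::local_tempfile(fileext = ".owl", lines = empty))
  expect_length(snap0$entity_uris, 0L)
})

test_that("Turtle and RDF/XML serializations yield equal snapshots", {
  s1 <- load_ontology(withr::local_tempfile(fileext = ".owl",
                                            lines = fixture_rdfxml()))
  s2 <- load_ontology(withr::local_tempfile(fileext = ".ttl",
                                            lines = fixture_turtle()))
  expect_identical(sort(s1$entity_uris), sort(s2$entity_uris))
  expect_identical(s1$label_index[order(names(s1$label_index))],
                   s2$label_index[order(names(s2$label_index))])
  expect_identical(s1$ontology_iri, s2$ontology_iri)
})

test_that("duplicate labels resolve to the smallest URI with a warning", {
  text <- paste0(
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"\n',
    ' xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"\n',
    ' xmlns:owl="http://www.w3.org/2002/07/owl#">\n',
    '<owl:Class rdf:about="https://example.org/zz"><rdfs:label>dup</rdfs:label></owl:Class>\n',
    '<owl:Class rdf:about="https://example.org/aa"><rdfs:label>dup</rdfs:label></owl:Class>\n',
    '</rdf:RDF>')
  path <- withr::local_tempfile(fileext = ".owl", lines = text)
  expect_warning(snap <- load_ontology(path), "ambiguous")
  expect_identical(unname(snap$label_index[["dup"]]), "https://example.org/aa")
})

test_that("unparseable content raises a format error", {
  path <- withr::local_tempfile(fileext = ".owl",
                                lines = "<?xml version='1.0'?><broken")
  expect_error(load_ontology(path), "RDF/XML")
  expect_error(load_ontology("/nonexistent/file.owl"), "not found")
})

test_that("the output document reparses with expected structure", {
  b <- make_clo_fixture()
  res <- run_bundle(b)
  counts <- count_owl_output(res$output$serialization)
  expect_identical(counts$class_declarations, 3L)
  expect_identical(counts$annotations, 5L)
  expect_identical(counts$superclasses, 3L)
  expect_identical(counts$equivalents, 0L)

  # row 0: label and the existential restriction, checked field by field
  doc <- xml2::read_xml(res$output$serialization)
  row0 <- xml2::xml_find_first(
    doc, "/rdf:RDF/owl:Class[@rdf:about='http://purl.obolibrary.org/obo/CLO_0010000']",
    ns = owl_ns)
  expect_identical(
    xml2::xml_text(xml2::xml_find_first(row0, "rdfs:label", ns = owl_ns)),
    "RCB2320 cell")
  restr <- xml2::xml_find_first(row0, "rdfs:subClassOf/owl:Restriction", ns = owl_ns)
  expect_identical(
    xml2::xml_attr(xml2::xml_find_first(restr, "owl:onProperty", ns = owl_ns),
                   "resource"),
    unname(b$settings$term_uris[["is in cell line repository"]]))
  expect_identical(
    xml2::xml_attr(xml2::xml_find_first(restr, "owl:someValuesFrom", ns = owl_ns),
                   "resource"),
    unname(b$settings$term_uris[["RIKEN Cell Bank"]]))
})

test_that("empty class lists give a valid header-only document", {
  out <- write_owl(list(), "https://example.org/out")
  doc <- xml2::read_xml(out$serialization)
  expect_identical(
    xml2::xml_attr(xml2::xml_find_first(doc, "/rdf:RDF/owl:Ontology", ns = owl_ns),
                   "about"),
    "https://example.org/out")
  expect_identical(count_owl_output(out$serialization)$class_declarations, 0L)
})

test_that("edit-existing output attaches axioms without declarations", {
  b <- make_biobank_fixture(5L)
  res <- run_bundle(b)
  counts <- count_owl_output(res$output$serialization)
  expect_identical(counts$class_declarations, 0L)
  expect_identical(counts$annotations, 10L)
  # axioms attach to exactly the key-column URIs
  expect_setequal(counts$subject_uris,
                  vapply(seq_len(5), function(i) cell(b$table, i - 1, "A"),
                         character(1)))
})

test_that("nested expressions serialize to valid anonymous class structures", {
  voc_res <- expression_resolver()
  e <- parse_class_expression(
    "'derived from' some ('term alpha' and 'part of' some 'term bravo') or not 'term charlie'",
    voc_res)
  g <- generated_class("http://x.org/X_1", superclasses = list(e))
  out <- write_owl(list(g), "http://x.org/out")
  doc <- xml2::read_xml(out$serialization)
  expect_length(xml2::xml_find_all(doc, "//owl:unionOf", ns = owl_ns), 1L)
  expect_length(xml2::xml_find_all(doc, "//owl:intersectionOf", ns = owl_ns), 1L)
  expect_length(xml2::xml_find_all(doc, "//owl:complementOf", ns = owl_ns), 1L)
  expect_length(xml2::xml_find_all(doc, "//owl:Restriction", ns = owl_ns), 2L)
})

test_that("RDF/XML and Turtle outputs are isomorphic graphs under rdflib", {
  b <- make_random_bundle(7L, rows = 5L)
  res <- run_bundle(b)
  xml_path <- withr::local_tempfile(fileext = ".owl")
  ttl_path <- withr::local_tempfile(fileext = ".ttl")
  writeLines(res$output$serialization, xml_path, sep = "")
  writeLines(write_owl_turtle(res$classes, res$output$ontology_iri), ttl_path,
             sep = "")
  script <- paste(
    "import sys, rdflib",
    "g1 = rdflib.Graph(); g1.parse(sys.argv[1], format='xml')",
    "g2 = rdflib.Graph(); g2.parse(sys.argv[2], format='turtle')",
    "print(int(g1.isomorphic(g2)))",
    sep = "\n")
  out <- system2("python", c("-", shQuote(xml_path), shQuote(ttl_path)),
                 input = script, stdout = TRUE)
  expect_identical(tail(out, 1L), "1")
})
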