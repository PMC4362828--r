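# Bundled synthetic inputs.
#
# Everything tests and examples need is generated in code: a cell-line
# bundle reconstructing the published RIKEN/CLO worked example from its
# printed fragments (the 'is in cell line repository' some 'RIKEN Cell
# Bank' superclass, the 'label' "{$columnA} cell" annotation, the RCB2320
# first row), a biobank-style edit-existing bundle, randomized bundles for
# property testing, and small target ontologies with chosen IDs. Values the
# published example shows only in screenshots are replaced by clearly
# synthetic placeholders.
#
# Each bundle carries `expectations`: output counts computed here by direct
# enumeration over patterns x rows x the empty-cell / multi-value rules,
# with plain string operations that share no code with the engine. Tests
# compare engine output against these independently derived numbers.

OBO_BASE <- "http://purl.obolibrary.org/obo/"

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle: %s, %d row(s), expects %d class(es) / %d annotation(s)>\n",
              x$settings$operation, n_rows(x$table),
              x$expectations$classes, x$expectations$annotations))
  invisible(x)
}

new_fixture_bundle <- function(settings, table, target_ontology_text = NULL) {
  settings_text <- serialize_settings(settings)
  structure(list(settings_text = settings_text,
                 settings = settings,
                 table = table,
                 target_ontology_text = target_ontology_text,
                 expectations = fx_enumerate(settings, table)),
            class = "fixture_bundle")
}

# --- independent enumeration oracle ----------------------------------------
# Deliberately re-derives the counting rules from scratch on raw strings;
# must not call find_variables / substitute / expand_row.

fx_vars <- function(template) {
  m <- regmatches(template,
                  gregexpr("\\{\\$column([A-Za-z]+)\\}", template))[[1]]
  unique(toupper(gsub("^\\{\\$column|\\}$", "", m, ignore.case = TRUE)))
}

fx_cell <- function(table, row, letter) {
  j <- 0L
  for (ch in strsplit(toupper(letter), "")[[1]]) {
    j <- j * 26L + (utf8ToInt(ch) - 64L)
  }
  r <- table$rows[[row + 1L]]
  if (j > length(r)) "" else r[[j]]
}

# axiom multiplicity of one pattern on one row: 0 when a referenced cell is
# empty, otherwise the product of per-cell multi-value counts
fx_multiplicity <- function(template, table, row, delim) {
  vars <- fx_vars(template)
  if (!length(vars)) return(1L)
  counts <- vapply(vars, function(v) {
    val <- fx_cell(table, row, v)
    if (!nzchar(val)) return(0L)
    length(strsplit(val, delim, fixed = TRUE)[[1]])
  }, integer(1))
  if (any(counts == 0L)) 0L else as.integer(prod(counts))
}

fx_enumerate <- function(settings, table) {
  delim <- settings$multivalue_delimiter
  is_new <- settings$operation == "new_classes"
  classes <- 0L
  annotations <- 0L
  superclasses <- 0L
  equivalents <- 0L
  for (row in seq_len(length(table$rows)) - 1L) {
    rowvals <- table$rows[[row + 1L]]
    if (!any(nzchar(rowvals))) next
    if (!is_new && !nzchar(fx_cell(table, row, settings$key_column))) next
    if (is_new) classes <- classes + 1L
    for (p in settings$annotation_patterns) {
      annotations <- annotations +
        fx_multiplicity(p$value_template, table, row, delim)
    }
    for (p in settings$expression_patterns) {
      k <- fx_multiplicity(p$template, table, row, delim)
      if (p$kind == "superclass") superclasses <- superclasses + k
      else equivalents <- equivalents + k
    }
  }
  list(classes = classes,
       declarations = if (is_new) classes else 0L,
       annotations = annotations,
       superclasses = superclasses,
       equivalents = equivalents)
}

# --- cell-line bundle -------------------------------------------------------

#' Cell-line (RIKEN/CLO style) fixture bundle
#'
#' A three-row new-classes bundle for a cell-line design pattern: each row
#' is one cell line from a repository catalogue, the label is the catalogue
#' ID followed by "cell", a comment records the source tissue and animal,
#' and a superclass axiom places the class in the RIKEN Cell Bank
#' repository. Row 0 column A is "RCB2320", so its generated label is
#' "RCB2320 cell". The third row has an empty animal cell, exercising the
#' empty-cell skip rule. Term URIs under the repository labels are
#' synthetic.
#'
#' @return a `fixture_bundle` with fields `settings_text`, `settings`,
#'   `table`, `target_ontology_text` (`NULL` here) and `expectations`.
#' @export
make_clo_fixture <- function() {
  settings <- axiom_settings(
    operation = "new_classes",
    uri_start = OBO_BASE,
    id_policy = id_policy("CLO_", 7L, 10000),
    term_uris = c(
      "label" = "http://www.w3.org/2000/01/rdf-schema#label",
      "comment" = "http://www.w3.org/2000/01/rdf-schema#comment",
      "is in cell line repository" = paste0(OBO_BASE, "CLO_9990001"),
      "RIKEN Cell Bank" = paste0(OBO_BASE, "CLO_9990002")),
    annotation_patterns = list(
      annotation_pattern("label", "{$columnA} cell"),
      annotation_pattern("comment",
                         "Derived from tissue: {$columnG} in animal: {$columnF}.")),
    expression_patterns = list(
      expression_pattern("'is in cell line repository' some 'RIKEN Cell Bank'",
                         "superclass")))
  table <- data_table(
    header = c("catalogue id", "name", "register", "originator", "depositor",
               "animal", "tissue"),
    rows = list(
      c("RCB2320", "synthetic line 1", "registrar A", "originator A", "", "Mus musculus", "liver"),
      c("RCB9001", "synthetic line 2", "registrar B", "originator B", "", "Rattus norvegicus", "spleen"),
      c("RCB9002", "synthetic line 3", "registrar C", "originator C", "", "", "kidney")))
  new_fixture_bundle(settings, table)
}

# --- biobank-style edit-existing bundle ------------------------------------

#' Biobank-style edit-existing fixture bundle
#'
#' Mirrors the use case of attaching missing definition-source and
#' definition-editor annotations to classes that already exist: the key
#' column holds the existing term URIs, and two annotation patterns pull
#' the editor and source strings from columns C and D. All URIs are
#' synthetic.
#'
#' @param rows number of data rows (at least 1).
#' @return a `fixture_bundle`
#' @export
make_biobank_fixture <- function(rows = 5L) {
  rows <- as.integer(rows)
  if (is.na(rows) || rows < 1L) {
    stop("the biobank bundle needs at least one row", call. = FALSE)
  }
  settings <- axiom_settings(
    operation = "edit_existing",
    uri_start = OBO_BASE,
    key_column = "A",
    term_uris = c(
      "definition editor" = paste0(OBO_BASE, "OBIB_9990001"),
      "definition source" = paste0(OBO_BASE, "OBIB_9990002")),
    annotation_patterns = list(
      annotation_pattern("definition editor", "{$columnC}"),
      annotation_pattern("definition source", "{$columnD}")))
  table <- data_table(
    header = c("term uri", "term label", "definition editor", "definition source"),
    rows = lapply(seq_len(rows), function(i) {
      c(sprintf("%sOBIB_99001%02d", OBO_BASE, i),
        sprintf("biobank term %d", i),
        sprintf("Editor %d", i),
        sprintf("https://example.org/source/%d", i))
    }))
  new_fixture_bundle(settings, table)
}

# --- randomized bundles -----------------------------------------------------

fx_vocab <- function() {
  cls <- c("term alpha", "term bravo", "term charlie", "term delta",
           "term echo", "term foxtrot")
  props <- c("part of", "derived from", "relates to")
  uris <- c(stats::setNames(sprintf("%sRND_91000%02d", OBO_BASE, seq_along(cls)), cls),
            stats::setNames(sprintf("%sRND_92000%02d", OBO_BASE, seq_along(props)), props),
            "label" = "http://www.w3.org/2000/01/rdf-schema#label",
            "note" = "http://www.w3.org/2004/02/skos/core#note")
  list(classes = cls, properties = props, uris = uris)
}

#' Randomized fixture bundle
#'
#' Deterministic in `seed`. The operation mode, patterns (drawn from the
#' supported Manchester subset), cell contents (including multi-valued
#' cells) and blanked cells are all randomized; `expectations` are computed
#' by the bundle's own enumeration, independent of the engine.
#'
#' @param seed integer seed.
#' @param rows number of data rows.
#' @param patterns number of expression patterns to draw.
#' @param empty_rate probability that any individual data cell is blank.
#' @return a `fixture_bundle`
#' @export
make_random_bundle <- function(seed, rows = 6L, patterns = 2L,
                               empty_rate = 0.15) {
  stopifnot(rows >= 0L, patterns >= 0L, empty_rate >= 0, empty_rate <= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  voc <- fx_vocab()
  operation <- sample(c("new_classes", "edit_existing"), 1L)
  # columns: A = key (edit mode) or plain id; B,C free text; D,E term cells
  text_cols <- c("B", "C")
  term_cols <- c("D", "E")

  ann <- list(
    annotation_pattern("label", "{$columnB} unit"),
    annotation_pattern("note", "Linked to {$columnC}."))
  expr_forms <- c(
    "'part of' some {$columnD}",
    "'derived from' some ({$columnD} and 'part of' some {$columnE})",
    "{$columnD} or {$columnE}",
    "not {$columnE}",
    "'relates to' only {$columnD}")
  expr <- lapply(seq_len(patterns), function(i) {
    expression_pattern(sample(expr_forms, 1L),
                       kind = sample(c("superclass", "equivalent"), 1L))
  })

  maybe_blank <- function(x) if (stats::runif(1) < empty_rate) "" else x
  term_cell <- function() {
    labs <- sample(voc$classes, sample(1:2, 1L, prob = c(0.8, 0.2)))
    paste(sprintf("'%s'", labs), collapse = "|")
  }
  rows_list <- lapply(seq_len(rows), function(i) {
    key <- if (operation == "edit_existing") {
      maybe_blank(sprintf("%sRND_93000%02d", OBO_BASE, i))
    } else maybe_blank(sprintf("item-%02d", i))
    c(key,
      maybe_blank(sprintf("sample %02d", i)),
      maybe_blank(if (stats::runif(1) < 0.25) {
        paste(sprintf("ref %02d-%d", i, 1:2), collapse = "|")
      } else sprintf("ref %02d", i)),
      maybe_blank(term_cell()),
      maybe_blank(term_cell()))
  })

  settings <- axiom_settings(
    operation = operation,
    uri_start = OBO_BASE,
    id_policy = if (operation == "new_classes") id_policy("RND_", 7L, 100) else NULL,
    key_column = if (operation == "edit_existing") "A" else NULL,
    term_uris = voc$uris,
    annotation_patterns = ann,
    expression_patterns = expr)
  table <- data_table(rows_list,
                      header = c("key", "name", "reference", "main term", "second term"))
  new_fixture_bundle(settings, table)
}

#' Random axiom settings
#'
#' Deterministic in `seed`; used for serialization round-trip property
#' tests. Draws the operation mode, ID policy, delimiter, term-URI map
#' (with quote-bearing labels), annotation patterns (with occasional
#' language tags and datatypes) and expression templates.
#'
#' @param seed integer seed.
#' @return an [axiom_settings()]
#' @export
make_random_settings <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  operation <- sample(c("new_classes", "edit_existing"), 1L)
  labels <- unique(replicate(sample(0:4, 1L), paste(
    sample(c("alpha", "beta", "gamma", "d'elta", "epsilon", "zeta"),
           sample(1:2, 1L), replace = TRUE), collapse = " ")))
  term_uris <- if (length(labels)) {
    stats::setNames(sprintf("https://example.org/vocab/t%03d", seq_along(labels)),
                    labels)
  } else character(0)
  ann <- lapply(seq_len(sample(0:3, 1L)), function(i) {
    annotation_pattern(
      property_ref = if (stats::runif(1) < 0.5 && length(labels)) {
        sample(labels, 1L)
      } else "http://www.w3.org/2000/01/rdf-schema#label",
      value_template = sample(c("{$columnA} cell", "plain \"quoted\" value",
                                "back\\slash {$columnB}", "Derived from {$columnC}."),
                              1L),
      lang = if (stats::runif(1) < 0.2) "en" else NULL,
      datatype = NULL)
  })
  expr <- lapply(seq_len(sample(0:3, 1L)), function(i) {
    expression_pattern(
      sample(c("'part of' some {$columnD}",
               "{$columnA} and 'part of' some {$columnB}",
               "not {$columnE}"), 1L),
      kind = sample(c("superclass", "equivalent"), 1L))
  })
  axiom_settings(
    operation = operation,
    uri_start = sample(c(OBO_BASE, "https://example.org/onto/"), 1L),
    id_policy = if (operation == "new_classes") {
      digits <- sample(2:9, 1L)
      id_policy(sample(c("VO_", "XX_", "T-"), 1L), digits,
                sample(0:9, 1L) * 10^(digits - 2L))
    } else NULL,
    key_column = if (operation == "edit_existing") sample(c("A", "B", "AA"), 1L) else NULL,
    term_uris = term_uris,
    annotation_patterns = ann,
    expression_patterns = expr,
    multivalue_delimiter = sample(c("|", ";", ","), 1L, prob = c(0.8, 0.1, 0.1)))
}

# --- target ontologies ------------------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Build a small target ontology holding chosen IDs
#'
#' Produces an RDF/XML ontology declaring one class per requested ID
#' number, each with a synthetic label, under `uri_start` + the policy
#' prefix with zero-padding to the policy width. Used to exercise
#' collision avoidance.
#'
#' @param existing_ids numeric vector of ID numbers to declare (duplicates
#'   collapsed); all must fit in the policy's digit count.
#' @param policy an [id_policy()].
#' @param uri_start absolute URI start portion.
#' @return the ontology document as a single string
#' @export
make_target_ontology <- function(existing_ids, policy, uri_start = OBO_BASE) {
  stopifnot(inherits(policy, "id_policy"))
  ids <- sort(unique(as.numeric(existing_ids)))
  if (length(ids) && any(ids >= 10^policy$digits)) {
    stop("an existing ID does not fit in ", policy$digits, " digits",
         call. = FALSE)
  }
  decls <- vapply(ids, function(n) {
    local <- paste0(policy$prefix,
                    formatC(n, width = policy$digits, flag = "0", format = "d"))
    sprintf(paste0("  <owl:Class rdf:about=\"%s%s\">\n",
                   "    <rdfs:label>existing term %s</rdfs:label>\n",
                   "  </owl:Class>"),
            xml_escape(uri_start), xml_escape(local), xml_escape(local))
  }, character(1))
  paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<rdf:RDF xmlns:rdf=\"", RDF_NS, "\"\n",
    "         xmlns:rdfs=\"", RDFS_NS, "\"\n",
    "         xmlns:owl=\"", OWL_NS, "\">\n",
    "  <owl:Ontology rdf:about=\"https://example.org/target-ontology\"/>\n",
    paste(decls, collapse = "\n"),
    if (length(decls)) "\n" else "",
    "</rdf:RDF>\n")
}

#' Random class expressions over the bundled vocabulary
#'
#' Draws a random expression tree of at most `max_depth` levels from the
#' supported construct subset (named atoms, some/only/value restrictions,
#' and/or/not), using the current RNG state. The accompanying
#' `expression_resolver()` resolves every label the generator can emit.
#'
#' @param max_depth maximum tree depth (1 gives a named atom).
#' @return a `class_expression`
#' @export
random_expression <- function(max_depth = 5L) {
  voc <- fx_vocab()
  named <- function() {
    lab <- sample(voc$classes, 1L)
    ce_named(term_ref(unname(voc$uris[[lab]]), display = lab))
  }
  prop <- function() {
    lab <- sample(voc$properties, 1L)
    term_ref(unname(voc$uris[[lab]]), display = lab)
  }
  gen <- function(depth) {
    if (depth <= 1L) return(named())
    kind <- sample(c("named", "some", "only", "value", "and", "or", "not"),
                   1L, prob = c(0.2, 0.2, 0.1, 0.1, 0.15, 0.15, 0.1))
    switch(kind,
      named = named(),
      some  = ce_some(prop(), gen(depth - 1L)),
      only  = ce_only(prop(), gen(depth - 1L)),
      value = ce_value(prop(), sample_individual()),
      "and" = ce_and(lapply(seq_len(sample(2:3, 1L)), function(i) gen(depth - 1L))),
      "or"  = ce_or(lapply(seq_len(sample(2:3, 1L)), function(i) gen(depth - 1L))),
      "not" = ce_not(gen(depth - 1L)))
  }
  sample_individual <- function() {
    lab <- sample(voc$classes, 1L)
    term_ref(unname(voc$uris[[lab]]), display = lab)
  }
  gen(max_depth)
}

#' @rdname random_expression
#' @export
expression_resolver <- function() {
  voc <- fx_vocab()
  make_resolver(voc$uris)
}
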