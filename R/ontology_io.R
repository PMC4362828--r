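# Target-ontology snapshots and OWL output serialization.
#
# The target ontology is only consulted for two things: the set of entity
# URIs (for ID-collision avoidance) and the rdfs:label index (as a fallback
# when resolving quoted labels). A restricted reader over xml2 extracts
# exactly that from RDF/XML; a small Turtle triple reader covers the other
# serialization commonly used for OWL ontologies. Neither attempts full RDF
# semantics (no reasoning, no triple store).
#
# Output is a standalone ontology document intended for owl:imports into
# the target: RDF/XML by default, Turtle on request. Generated classes are
# declared as owl:Class; in edit mode only the new axioms are emitted, no
# declarations. Properties referenced by the axioms receive minimal role
# declarations (object vs annotation property); referenced external classes
# and individuals are listed in a header comment rather than declared.

RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS  <- "http://www.w3.org/2002/07/owl#"
XSD_NS  <- "http://www.w3.org/2001/XMLSchema#"

#' Ontology snapshot
#'
#' The subset of a target ontology needed for a run: its IRI, the set of
#' entity URIs and the label-to-URI index.
#'
#' @param entity_uris character vector of entity URIs.
#' @param label_index named character vector mapping rdfs:label strings to
#'   URIs. When a label is ambiguous the lexicographically smallest URI
#'   wins and a warning is emitted.
#' @param ontology_iri the ontology IRI, or `NA` if absent.
#' @param source where the snapshot was loaded from.
#' @export
ontology_snapshot <- function(entity_uris = character(0),
                              label_index = character(0),
                              ontology_iri = NA_character_,
                              source = NA_character_) {
  structure(list(ontology_iri = ontology_iri,
                 entity_uris = unique(entity_uris),
                 label_index = as_named_chr(label_index),
                 source = source),
            class = "ontology_snapshot")
}

#' @export
print.ontology_snapshot <- function(x, ...) {
  cat(sprintf("<ontology_snapshot: %d entities, %d labels, IRI %s>\n",
              length(x$entity_uris), length(x$label_index),
              if (is.na(x$ontology_iri)) "(none)" else x$ontology_iri))
  invisible(x)
}

# label pairs -> deduplicated index (smallest URI wins, warn on conflicts)
build_label_index <- function(labels, uris) {
  if (!length(labels)) return(stats::setNames(character(0), character(0)))
  idx <- stats::setNames(character(0), character(0))
  for (lab in unique(labels)) {
    candidates <- sort(unique(uris[labels == lab]))
    if (length(candidates) > 1L) {
      warning("label \"", lab, "\" is ambiguous (", length(candidates),
              " entities); keeping ", candidates[[1]], call. = FALSE)
    }
    idx[lab] <- candidates[[1]]
  }
  idx
}

#' Load a target ontology into a snapshot
#'
#' Accepts RDF/XML or Turtle; the serialization is detected by content
#' sniffing (an XML declaration or `<rdf:RDF` root means RDF/XML), then by
#' file extension. Entities are gathered from typed declarations and from
#' the subject/object positions of subclass axioms; labels from rdfs:label
#' literals.
#'
#' @param source path to a local file, or an http(s) URL.
#' @return an [ontology_snapshot()]
#' @export
load_ontology <- function(source) {
  text <- if (grepl("^https?://", source)) {
    paste(readLines(url(source), warn = FALSE, encoding = "UTF-8"),
          collapse = "\n")
  } else {
    if (!file.exists(source)) {
      stop("target ontology not found: ", source, call. = FALSE)
    }
    paste(readLines(source, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  }
  text <- strip_bom(text)
  head <- substring(trimws(text), 1L, 200L)
  is_xml <- grepl("^<\\?xml", head) || grepl("^<(rdf:RDF|RDF)", head) ||
    (grepl("^<", head) && !grepl("^@", head) &&
     grepl("\\.(owl|rdf|xml)$", source, ignore.case = TRUE))
  snap <- if (is_xml) snapshot_from_rdfxml(text) else snapshot_from_turtle(text)
  snap$source <- source
  snap
}

snapshot_from_rdfxml <- function(text) {
  doc <- tryCatch(xml2::read_xml(text),
                  error = function(e) {
                    stop("cannot parse target ontology as RDF/XML: ",
                         conditionMessage(e), call. = FALSE)
                  })
  ns <- c(rdf = RDF_NS, rdfs = RDFS_NS, owl = OWL_NS)
  iri_node <- xml2::xml_find_first(doc, ".//owl:Ontology", ns = ns)
  ontology_iri <- if (inherits(iri_node, "xml_missing")) NA_character_ else
    xml2::xml_attr(iri_node, "about")

  ent <- character(0)
  labels <- character(0)
  label_uris <- character(0)

  typed <- xml2::xml_find_all(doc, paste0(
    ".//owl:Class[@rdf:about] | .//owl:ObjectProperty[@rdf:about] | ",
    ".//owl:AnnotationProperty[@rdf:about] | .//owl:DatatypeProperty[@rdf:about] | ",
    ".//owl:NamedIndividual[@rdf:about]"), ns = ns)
  ent <- c(ent, xml2::xml_attr(typed, "about"))

  descr <- xml2::xml_find_all(doc, ".//rdf:Description[@rdf:about][rdf:type]",
                              ns = ns)
  ent <- c(ent, xml2::xml_attr(descr, "about"))

  # objects of subclass / restriction arcs
  refs <- xml2::xml_find_all(doc, paste0(
    ".//rdfs:subClassOf[@rdf:resource] | .//owl:onProperty[@rdf:resource] | ",
    ".//owl:someValuesFrom[@rdf:resource] | .//owl:allValuesFrom[@rdf:resource]"),
    ns = ns)
  ent <- c(ent, xml2::xml_attr(refs, "resource"))

  for (node in c(typed, descr)) {
    uri <- xml2::xml_attr(node, "about")
    for (lab in xml2::xml_find_all(node, "rdfs:label", ns = ns)) {
      labels <- c(labels, xml2::xml_text(lab))
      label_uris <- c(label_uris, uri)
    }
  }

  ent <- ent[!is.na(ent) & nzchar(ent)]
  ontology_snapshot(entity_uris = ent,
                    label_index = build_label_index(labels, label_uris),
                    ontology_iri = ontology_iri)
}

# --- minimal Turtle reader --------------------------------------------------
# Supports the statement forms OWL ontologies serialized as Turtle use for
# declarations and labels: @prefix/PREFIX, <IRI> and prefixed-name terms,
# "literal" objects (with language/datatype suffixes), the 'a' keyword,
# ';' and ',' continuation, '.' termination. Blank-node bracket groups are
# skipped structurally.

ttl_tokenize <- function(text) {
  n <- nchar(text)
  i <- 1L
  toks <- list()
  push <- function(type, value) toks[[length(toks) + 1L]] <<- list(type = type, value = value)
  chr <- function(k) substring(text, k, k)
  while (i <= n) {
    ch <- chr(i)
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch == "#") { while (i <= n && chr(i) != "\n") i <- i + 1L; next }
    if (ch == "<") {
      j <- i + 1L
      while (j <= n && chr(j) != ">") j <- j + 1L
      push("iri", substring(text, i + 1L, j - 1L)); i <- j + 1L; next
    }
    if (ch == "\"") {
      j <- i + 1L
      buf <- character(0)
      while (j <= n) {
        cj <- chr(j)
        if (cj == "\\") { buf <- c(buf, chr(j + 1L)); j <- j + 2L; next }
        if (cj == "\"") break
        buf <- c(buf, cj); j <- j + 1L
      }
      i <- j + 1L
      # optional @lang or ^^type suffix
      if (chr(i) == "@") { while (i <= n && grepl("^[A-Za-z@-]$", chr(i))) i <- i + 1L }
      if (substring(text, i, i + 1L) == "^^") {
        i <- i + 2L
        if (chr(i) == "<") { while (i <= n && chr(i) != ">") i <- i + 1L; i <- i + 1L }
        else while (i <= n && grepl("^[A-Za-z0-9_:]$", chr(i))) i <- i + 1L
      }
      push("literal", paste(buf, collapse = "")); next
    }
    if (ch %in% c(".", ";", ",", "[", "]", "(", ")")) {
      push(ch, ch); i <- i + 1L; next
    }
    j <- i
    while (j <= n && grepl("^[^][[:space:]<>\"(),;.]$", chr(j))) j <- j + 1L
    word <- substring(text, i, j - 1L)
    if (!nzchar(word)) stop("cannot tokenize Turtle near position ", i, call. = FALSE)
    push(if (word %in% c("@prefix", "@base", "PREFIX", "BASE", "prefix", "base"))
           "directive" else "name", word)
    i <- j
  }
  toks
}

ttl_expand <- function(name, prefixes) {
  if (name == "a") return(paste0(RDF_NS, "type"))
  colon <- regexpr(":", name, fixed = TRUE)
  if (colon < 0L) return(name)
  p <- substring(name, 1L, colon - 1L)
  local <- substring(name, colon + 1L)
  if (!is.null(prefixes[[p]])) paste0(prefixes[[p]], local) else name
}

# returns list of triples: list(s, p, o, o_is_literal)
ttl_triples <- function(text) {
  toks <- ttl_tokenize(text)
  prefixes <- list()
  triples <- list()
  i <- 1L
  nt <- length(toks)
  term <- function(k) {
    t <- toks[[k]]
    if (t$type == "iri") list(value = t$value, literal = FALSE)
    else if (t$type == "literal") list(value = t$value, literal = TRUE)
    else if (t$type == "name") list(value = ttl_expand(t$value, prefixes), literal = FALSE)
    else NULL
  }
  skip_brackets <- function(k, open, close) {
    depth <- 1L
    k <- k + 1L
    while (k <= nt && depth > 0L) {
      if (toks[[k]]$type == open) depth <- depth + 1L
      if (toks[[k]]$type == close) depth <- depth - 1L
      k <- k + 1L
    }
    k
  }
  while (i <= nt) {
    t <- toks[[i]]
    if (t$type == "directive") {
      if (tolower(sub("^@", "", t$value)) == "prefix" && i + 2L <= nt) {
        pname <- sub(":$", "", toks[[i + 1L]]$value)
        prefixes[[pname]] <- toks[[i + 2L]]$value
        i <- i + 3L
        if (i <= nt && toks[[i]]$type == ".") i <- i + 1L
      } else {
        while (i <= nt && toks[[i]]$type != ".") i <- i + 1L
        i <- i + 1L
      }
      next
    }
    if (t$type == "[") { i <- skip_brackets(i, "[", "]"); next }
    subj <- term(i)
    if (is.null(subj) || subj$literal) { i <- i + 1L; next }
    i <- i + 1L
    repeat {
      if (i > nt || toks[[i]]$type == ".") { i <- i + 1L; break }
      pred <- term(i)
      if (is.null(pred)) { i <- i + 1L; next }
      i <- i + 1L
      repeat {
        if (i <= nt && toks[[i]]$type == "[") {
          i <- skip_brackets(i, "[", "]")
        } else if (i <= nt && toks[[i]]$type == "(") {
          i <- skip_brackets(i, "(", ")")
        } else if (i <= nt) {
          obj <- term(i)
          if (!is.null(obj)) {
            triples[[length(triples) + 1L]] <-
              list(s = subj$value, p = pred$value, o = obj$value,
                   o_is_literal = obj$literal)
          }
          i <- i + 1L
        }
        if (i <= nt && toks[[i]]$type == ",") { i <- i + 1L; next }
        break
      }
      if (i <= nt && toks[[i]]$type == ";") { i <- i + 1L; next }
      if (i <= nt && toks[[i]]$type == ".") { i <- i + 1L }
      break
    }
  }
  triples
}

entity_types <- paste0(OWL_NS, c("Class", "ObjectProperty", "AnnotationProperty",
                                 "DatatypeProperty", "NamedIndividual"))

snapshot_from_turtle <- function(text) {
  triples <- ttl_triples(text)
  rdf_type <- paste0(RDF_NS, "type")
  ontology_iri <- NA_character_
  ent <- character(0)
  labels <- character(0)
  label_uris <- character(0)
  for (tr in triples) {
    if (tr$p == rdf_type && !tr$o_is_literal) {
      if (tr$o == paste0(OWL_NS, "Ontology")) ontology_iri <- tr$s
      if (tr$o %in% entity_types) ent <- c(ent, tr$s)
    }
    if (tr$p == paste0(RDFS_NS, "subClassOf") && !tr$o_is_literal) {
      ent <- c(ent, tr$s, tr$o)
    }
    if (tr$p == paste0(RDFS_NS, "label") && tr$o_is_literal) {
      labels <- c(labels, tr$o)
      label_uris <- c(label_uris, tr$s)
    }
  }
  ontology_snapshot(entity_uris = ent,
                    label_index = build_label_index(labels, label_uris),
                    ontology_iri = ontology_iri)
}

# --- output -----------------------------------------------------------------

# walk expressions, classifying referenced URIs by role
collect_refs <- function(classes) {
  obj_props <- character(0)
  cls <- character(0)
  individuals <- character(0)
  walk <- function(e) {
    switch(e$kind,
      named = cls <<- c(cls, e$term$uri),
      some  = ,
      only  = { obj_props <<- c(obj_props, e$property$uri); walk(e$filler) },
      value = { obj_props <<- c(obj_props, e$property$uri)
                individuals <<- c(individuals, e$value$uri) },
      "and" = ,
      "or"  = for (o in e$operands) walk(o),
      "not" = walk(e$operand))
  }
  ann_props <- character(0)
  for (g in classes) {
    for (a in g$annotations) ann_props <- c(ann_props, a$property)
    for (e in c(g$superclasses, g$equivalents)) walk(e)
  }
  list(object_properties = sort(unique(obj_props)),
       annotation_properties = sort(unique(ann_props)),
       classes = sort(unique(cls)),
       individuals = sort(unique(individuals)))
}

xml_expression_node <- function(parent, expr) {
  switch(expr$kind,
    named = {
      node <- xml2::xml_add_child(parent, "rdf:Description")
      xml2::xml_set_attr(node, "rdf:about", expr$term$uri)
    },
    some = ,
    only = {
      node <- xml2::xml_add_child(parent, "owl:Restriction")
      onprop <- xml2::xml_add_child(node, "owl:onProperty")
      xml2::xml_set_attr(onprop, "rdf:resource", expr$property$uri)
      slot <- if (expr$kind == "some") "owl:someValuesFrom" else "owl:allValuesFrom"
      filler <- xml2::xml_add_child(node, slot)
      if (expr$filler$kind == "named") {
        xml2::xml_set_attr(filler, "rdf:resource", expr$filler$term$uri)
      } else {
        xml_expression_node(filler, expr$filler)
      }
    },
    value = {
      node <- xml2::xml_add_child(parent, "owl:Restriction")
      onprop <- xml2::xml_add_child(node, "owl:onProperty")
      xml2::xml_set_attr(onprop, "rdf:resource", expr$property$uri)
      hv <- xml2::xml_add_child(node, "owl:hasValue")
      xml2::xml_set_attr(hv, "rdf:resource", expr$value$uri)
    },
    "and" = ,
    "or" = {
      node <- xml2::xml_add_child(parent, "owl:Class")
      slot <- if (expr$kind == "and") "owl:intersectionOf" else "owl:unionOf"
      coll <- xml2::xml_add_child(node, slot)
      xml2::xml_set_attr(coll, "rdf:parseType", "Collection")
      for (o in expr$operands) xml_expression_node(coll, o)
    },
    "not" = {
      node <- xml2::xml_add_child(parent, "owl:Class")
      comp <- xml2::xml_add_child(node, "owl:complementOf")
      if (expr$operand$kind == "named") {
        xml2::xml_set_attr(comp, "rdf:resource", expr$operand$term$uri)
      } else {
        xml_expression_node(comp, expr$operand)
      }
    })
  invisible(parent)
}

# Split a property URI into (namespace, local) at the last '#' or '/'.
split_uri <- function(uri) {
  split_at <- max(regexpr("#[^#]*$", uri), regexpr("/[^/]*$", uri))
  if (split_at < 1L || split_at == nchar(uri)) {
    stop("cannot form a QName for property URI: ", uri, call. = FALSE)
  }
  local <- substring(uri, split_at + 1L)
  if (!grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", local)) {
    stop("property URI has a non-QName local part: ", uri, call. = FALSE)
  }
  c(ns = substring(uri, 1L, split_at), local = local)
}

#' Serialize generated classes as a standalone OWL document
#'
#' Produces an RDF/XML ontology document: an `owl:Ontology` header, one
#' `owl:Class` declaration per newly minted class carrying its annotation
#' assertions, subclass axioms (restrictions as anonymous nodes) and
#' equivalent-class axioms; classes being edited (`is_new = FALSE`) receive
#' axioms only, no declaration. Properties used by the axioms are declared
#' with their role; referenced external classes and individuals are listed
#' in a leading comment.
#'
#' @param classes list of [generated_class()] objects.
#' @param ontology_iri IRI of the output ontology.
#' @param prefixes named character vector of namespace prefixes (the rdf,
#'   rdfs, owl and xsd defaults are always included).
#' @return an object of class `output_document` with fields `ontology_iri`,
#'   `classes`, `declared_properties` and `serialization` (the RDF/XML
#'   text).
#' @export
write_owl <- function(classes, ontology_iri, prefixes = default_prefixes()) {
  refs <- collect_refs(classes)
  subject_uris <- vapply(classes, function(g) g$uri, character(1))
  external_classes <- setdiff(refs$classes, subject_uris)
  external_individuals <- refs$individuals

  ns <- c(default_prefixes(), prefixes)
  ns <- ns[!duplicated(ns) & !duplicated(names(ns))]
  # every annotation property must be expressible as a QName
  ann_ns <- unique(vapply(refs$annotation_properties,
                          function(p) split_uri(p)[["ns"]], character(1)))
  extra <- setdiff(ann_ns, unname(ns))
  if (length(extra)) {
    ns <- c(ns, stats::setNames(extra, paste0("ns", seq_along(extra))))
  }
  qname_for <- function(property_uri) {
    parts <- split_uri(property_uri)
    prefix <- names(ns)[ns == parts[["ns"]]][1]
    paste0(prefix, ":", parts[["local"]])
  }

  doc <- xml2::xml_new_root("rdf:RDF")
  for (p in names(ns)) xml2::xml_set_attr(doc, paste0("xmlns:", p), ns[[p]])

  header <- xml2::xml_add_child(doc, "owl:Ontology")
  xml2::xml_set_attr(header, "rdf:about", ontology_iri)

  for (p in refs$object_properties) {
    node <- xml2::xml_add_child(doc, "owl:ObjectProperty")
    xml2::xml_set_attr(node, "rdf:about", p)
  }
  ann_only <- setdiff(refs$annotation_properties, refs$object_properties)
  for (p in ann_only) {
    node <- xml2::xml_add_child(doc, "owl:AnnotationProperty")
    xml2::xml_set_attr(node, "rdf:about", p)
  }

  for (g in classes) {
    subject <- xml2::xml_add_child(
      doc, if (g$is_new) "owl:Class" else "rdf:Description")
    xml2::xml_set_attr(subject, "rdf:about", g$uri)
    for (a in g$annotations) {
      node <- xml2::xml_add_child(subject, qname_for(a$property))
      xml2::xml_set_text(node, a$value)
      if (!is.null(a$lang) && nzchar(a$lang)) {
        xml2::xml_set_attr(node, "xml:lang", a$lang)
      } else if (!is.null(a$datatype) && nzchar(a$datatype)) {
        xml2::xml_set_attr(node, "rdf:datatype", a$datatype)
      }
    }
    for (e in g$superclasses) {
      sub <- xml2::xml_add_child(subject, "rdfs:subClassOf")
      if (e$kind == "named") {
        xml2::xml_set_attr(sub, "rdf:resource", e$term$uri)
      } else {
        xml_expression_node(sub, e)
      }
    }
    for (e in g$equivalents) {
      eq <- xml2::xml_add_child(subject, "owl:equivalentClass")
      if (e$kind == "named") {
        xml2::xml_set_attr(eq, "rdf:resource", e$term$uri)
      } else {
        xml_expression_node(eq, e)
      }
    }
  }

  serialization <- as.character(doc)
  if (length(external_classes) || length(external_individuals)) {
    comment <- paste0(
      "<!-- External terms referenced but not declared here (expected to be\n",
      "     resolved by the importing ontology):\n",
      paste0("     ", c(external_classes, external_individuals), collapse = "\n"),
      " -->\n")
    serialization <- sub("(\\?>\n)", paste0("\\1", comment), serialization)
  }
  structure(list(ontology_iri = ontology_iri,
                 classes = classes,
                 declared_properties = c(refs$object_properties, ann_only),
                 serialization = serialization),
            class = "output_document")
}

#' @export
print.output_document <- function(x, ...) {
  cat(sprintf("<output_document: %s, %d class(es), %d declared propert%s>\n",
              x$ontology_iri, length(x$classes),
              length(x$declared_properties),
              if (length(x$declared_properties) == 1L) "y" else "ies"))
  invisible(x)
}

# --- Turtle output ----------------------------------------------------------

ttl_iri <- function(uri) paste0("<", uri, ">")

ttl_literal <- function(value, lang = NULL, datatype = NULL) {
  s <- paste0("\"", gsub("\"", "\\\"", gsub("\\", "\\\\", value, fixed = TRUE),
                         fixed = TRUE), "\"")
  if (!is.null(lang) && nzchar(lang)) paste0(s, "@", lang)
  else if (!is.null(datatype) && nzchar(datatype)) paste0(s, "^^<", datatype, ">")
  else s
}

ttl_expression <- function(expr) {
  switch(expr$kind,
    named = ttl_iri(expr$term$uri),
    some  = sprintf("[ a owl:Restriction ; owl:onProperty %s ; owl:someValuesFrom %s ]",
                    ttl_iri(expr$property$uri), ttl_expression(expr$filler)),
    only  = sprintf("[ a owl:Restriction ; owl:onProperty %s ; owl:allValuesFrom %s ]",
                    ttl_iri(expr$property$uri), ttl_expression(expr$filler)),
    value = sprintf("[ a owl:Restriction ; owl:onProperty %s ; owl:hasValue %s ]",
                    ttl_iri(expr$property$uri), ttl_iri(expr$value$uri)),
    "and" = sprintf("[ a owl:Class ; owl:intersectionOf ( %s ) ]",
                    paste(vapply(expr$operands, ttl_expression, character(1)),
                          collapse = " ")),
    "or"  = sprintf("[ a owl:Class ; owl:unionOf ( %s ) ]",
                    paste(vapply(expr$operands, ttl_expression, character(1)),
                          collapse = " ")),
    "not" = sprintf("[ a owl:Class ; owl:complementOf %s ]",
                    ttl_expression(expr$operand)))
}

#' Serialize generated classes as Turtle
#'
#' Same content as the RDF/XML serialization of [write_owl()], as Turtle.
#'
#' @inheritParams write_owl
#' @return the Turtle document as a single string
#' @export
write_owl_turtle <- function(classes, ontology_iri) {
  refs <- collect_refs(classes)
  lines <- c(
    "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "",
    paste0(ttl_iri(ontology_iri), " a owl:Ontology ."),
    "")
  for (p in refs$object_properties) {
    lines <- c(lines, paste0(ttl_iri(p), " a owl:ObjectProperty ."))
  }
  for (p in setdiff(refs$annotation_properties, refs$object_properties)) {
    lines <- c(lines, paste0(ttl_iri(p), " a owl:AnnotationProperty ."))
  }
  lines <- c(lines, "")
  for (g in classes) {
    stmts <- character(0)
    if (g$is_new) stmts <- "a owl:Class"
    for (a in g$annotations) {
      stmts <- c(stmts, paste(ttl_iri(a$property),
                              ttl_literal(a$value, a$lang, a$datatype)))
    }
    for (e in g$superclasses) {
      stmts <- c(stmts, paste("rdfs:subClassOf", ttl_expression(e)))
    }
    for (e in g$equivalents) {
      stmts <- c(stmts, paste("owl:equivalentClass", ttl_expression(e)))
    }
    if (!length(stmts)) next
    lines <- c(lines,
               paste0(ttl_iri(g$uri), " ",
                      paste(stmts, collapse = " ;\n    "), " ."),
               "")
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
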