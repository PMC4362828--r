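# Independent oracles used across the suite. Nothing here calls into the
# package's own parsing or serialization internals: the reference
# Manchester parser is a splitting parser over its own token stream, and
# the output counters re-derive axiom counts from the emitted documents
# with fresh XPath / line scanning.

# --- reference Manchester parser (brute-force splitting style) --------------
# Tokens: list(type = "atom"|"kw"|"(",")", value). Returns a plain nested
# list shape (op/term/args) or NULL when the input does not parse.

ref_tokenize <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substring(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "'") {
      j <- i + 1L
      repeat {
        if (j > n) return(NULL)
        if (substring(text, j, j) == "'") {
          if (substring(text, j + 1L, j + 1L) == "'") j <- j + 2L else break
        } else j <- j + 1L
      }
      lab <- gsub("''", "'", substring(text, i + 1L, j - 1L))
      toks[[length(toks) + 1L]] <- list(type = "atom", value = lab)
      i <- j + 1L
    } else if (ch == "<") {
      j <- regexpr(">", substring(text, i))[[1]]
      if (j < 0) return(NULL)
      toks[[length(toks) + 1L]] <- list(type = "atom",
                                        value = substring(text, i + 1L, i + j - 2L))
      i <- i + j
    } else if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, value = ch)
      i <- i + 1L
    } else {
      m <- regexpr("^[A-Za-z0-9_:./#-]+", substring(text, i))
      if (m < 0) return(NULL)
      w <- regmatches(substring(text, i), m)
      toks[[length(toks) + 1L]] <- list(
        type = if (w %in% c("some", "only", "value", "and", "or", "not")) "kw" else "atom",
        value = w)
      i <- i + attr(m, "match.length")
    }
  }
  toks
}

# indices of keyword `kw` at paren depth 0
ref_split_points <- function(toks, kw) {
  depth <- 0L
  pts <- integer(0)
  for (k in seq_along(toks)) {
    t <- toks[[k]]
    if (t$type == "(") depth <- depth + 1L
    else if (t$type == ")") { depth <- depth - 1L; if (depth < 0L) return(NULL) }
    else if (depth == 0L && t$type == "kw" && t$value == kw) pts <- c(pts, k)
  }
  if (depth != 0L) return(NULL)
  pts
}

ref_segments <- function(toks, pts) {
  bounds <- c(0L, pts, length(toks) + 1L)
  lapply(seq_len(length(bounds) - 1L), function(i) {
    lo <- bounds[[i]] + 1L
    hi <- bounds[[i + 1L]] - 1L
    if (lo > hi) NULL else toks[lo:hi]
  })
}

ref_parse <- function(toks) {
  if (is.null(toks) || !length(toks)) return(NULL)
  pts <- ref_split_points(toks, "or")
  if (is.null(pts)) return(NULL)
  if (length(pts)) {
    args <- lapply(ref_segments(toks, pts), ref_parse_and)
    if (any(vapply(args, is.null, logical(1)))) return(NULL)
    return(list(op = "or", args = args))
  }
  ref_parse_and(toks)
}

ref_parse_and <- function(toks) {
  if (is.null(toks) || !length(toks)) return(NULL)
  pts <- ref_split_points(toks, "and")
  if (is.null(pts)) return(NULL)
  if (length(pts)) {
    args <- lapply(ref_segments(toks, pts), ref_parse_not)
    if (any(vapply(args, is.null, logical(1)))) return(NULL)
    return(list(op = "and", args = args))
  }
  ref_parse_not(toks)
}

ref_parse_not <- function(toks) {
  if (is.null(toks) || !length(toks)) return(NULL)
  if (toks[[1]]$type == "kw" && toks[[1]]$value == "not") {
    inner <- ref_parse_not(toks[-1])
    if (is.null(inner)) return(NULL)
    return(list(op = "not", arg = inner))
  }
  ref_parse_restriction(toks)
}

# consume one primary from the front; list(shape, rest) or NULL
ref_take_primary <- function(toks) {
  if (!length(toks)) return(NULL)
  t1 <- toks[[1]]
  if (t1$type == "atom") {
    return(list(shape = list(op = "named", term = t1$value), rest = toks[-1]))
  }
  if (t1$type == "(") {
    depth <- 0L
    close <- NA_integer_
    for (k in seq_along(toks)) {
      if (toks[[k]]$type == "(") depth <- depth + 1L
      if (toks[[k]]$type == ")") {
        depth <- depth - 1L
        if (depth == 0L) { close <- k; break }
      }
    }
    if (is.na(close) || close == 2L) return(NULL)
    inner <- ref_parse(toks[2:(close - 1L)])
    if (is.null(inner)) return(NULL)
    return(list(shape = inner,
                rest = if (close == length(toks)) list() else toks[(close + 1L):length(toks)]))
  }
  NULL
}

ref_parse_restriction <- function(toks) {
  left <- ref_take_primary(toks)
  if (is.null(left)) return(NULL)
  rest <- left$rest
  if (!length(rest)) return(left$shape)
  t <- rest[[1]]
  if (t$type != "kw" || !t$value %in% c("some", "only", "value")) return(NULL)
  if (!identical(left$shape$op, "named")) return(NULL)
  filler <- ref_take_primary(rest[-1])
  if (is.null(filler) || length(filler$rest)) return(NULL)
  if (t$value == "value") {
    if (!identical(filler$shape$op, "named")) return(NULL)
    return(list(op = "value", prop = left$shape$term, term = filler$shape$term))
  }
  list(op = t$value, prop = left$shape$term, arg = filler$shape)
}

ref_parse_text <- function(text) {
  toks <- ref_tokenize(text)
  if (is.null(toks)) return(NULL)
  ref_parse(toks)
}

# package AST -> the reference shape (display label when known, else URI)
as_shape <- function(expr) {
  term_of <- function(r) if (!is.null(r$display)) r$display else r$uri
  switch(expr$kind,
    named = list(op = "named", term = term_of(expr$term)),
    some  = list(op = "some", prop = term_of(expr$property), arg = as_shape(expr$filler)),
    only  = list(op = "only", prop = term_of(expr$property), arg = as_shape(expr$filler)),
    value = list(op = "value", prop = term_of(expr$property), term = term_of(expr$value)),
    "and" = list(op = "and", args = lapply(expr$operands, as_shape)),
    "or"  = list(op = "or", args = lapply(expr$operands, as_shape)),
    "not" = list(op = "not", arg = as_shape(expr$operand)))
}

# --- independent RDF/XML output counters ------------------------------------

owl_ns <- c(rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
            rdfs = "http://www.w3.org/2000/01/rdf-schema#",
            owl  = "http://www.w3.org/2002/07/owl#")

count_owl_output <- function(serialization) {
  doc <- xml2::read_xml(serialization)
  subj <- "/rdf:RDF/owl:Class[@rdf:about] | /rdf:RDF/rdf:Description[@rdf:about]"
  subjects <- xml2::xml_find_all(doc, subj, ns = owl_ns)
  ann <- 0L
  sup <- 0L
  eqv <- 0L
  for (s in subjects) {
    for (child in xml2::xml_children(s)) {
      nm <- xml2::xml_name(child)  # local name, namespace-agnostic
      if (nm == "subClassOf") sup <- sup + 1L
      else if (nm == "equivalentClass") eqv <- eqv + 1L
      else if (nm != "type") ann <- ann + 1L
    }
  }
  list(
    class_declarations = length(
      xml2::xml_find_all(doc, "/rdf:RDF/owl:Class[@rdf:about]", ns = owl_ns)),
    annotations = ann, superclasses = sup, equivalents = eqv,
    subject_uris = xml2::xml_attr(subjects, "about"))
}

# --- independent Manchester-document counter --------------------------------

count_manchester_document <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  classes <- 0L
  ann <- 0L
  sup <- 0L
  eqv <- 0L
  section <- ""
  for (ln in lines) {
    if (grepl("^Class: ", ln)) { classes <- classes + 1L; section <- ""; next }
    if (grepl("^    Annotations:", ln)) { section <- "ann"; next }
    if (grepl("^    SubClassOf:", ln)) { section <- "sup"; next }
    if (grepl("^    EquivalentTo:", ln)) { section <- "eqv"; next }
    if (grepl("^        ", ln)) {
      if (section == "ann") ann <- ann + 1L
      if (section == "sup") sup <- sup + 1L
      if (section == "eqv") eqv <- eqv + 1L
    }
  }
  list(classes = classes, annotations = ann, superclasses = sup,
       equivalents = eqv)
}

# --- regex ID-extraction oracle ---------------------------------------------

regex_scan_ids <- function(document_text, prefix, digits, uri_start) {
  pat <- paste0("rdf:about=\"", uri_start, prefix,
                "([0-9]{", digits, "})\"")
  m <- regmatches(document_text, gregexpr(pat, document_text))[[1]]
  sort(unique(as.numeric(sub(pat, "\\1", m))))
}

# run a fixture bundle through the engine in its own mode
run_bundle <- function(bundle, snapshot = NULL) {
  run_patterns(bundle$settings, bundle$table, snapshot)
}
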