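# Manchester-OWL-syntax class expressions.
#
# The pattern language of this package uses the human-readable Manchester
# syntax for class expressions: quoted labels or <URI> atoms combined with
# the keywords some, only, value, and, or, not and parentheses. The subset
# implemented here covers the existential/universal/has-value restrictions
# and boolean connectives common in OBO-style design patterns; cardinality
# and datatype restrictions are deliberately out of scope.
#
# Grammar (precedence low -> high):
#   expr        := and_expr ("or" and_expr)*
#   and_expr    := not_expr ("and" not_expr)*
#   not_expr    := "not" not_expr | restriction
#   restriction := primary [ ("some" | "only" | "value") primary ]
#   primary     := atom | "(" expr ")"
#   atom        := 'quoted label' | <URI> | bare-token
# Keywords are lower-case reserved words. Quoted labels use single quotes
# with doubled-quote escaping ('O''Hara cell').

#' Term reference
#'
#' A resolved reference to an ontology entity: how it was written in the
#' pattern (`display`, a label or URI) together with its absolute URI.
#'
#' @param uri absolute URI of the entity.
#' @param display the display form as written (a label string), or `NULL`
#'   when the term was written directly as a URI.
#' @export
term_ref <- function(uri, display = NULL) {
  stopifnot(is.character(uri), length(uri) == 1L)
  if (!is_absolute_uri(uri)) {
    stop("term URI is not absolute: ", uri, call. = FALSE)
  }
  structure(list(uri = uri, display = display), class = "term_ref")
}

is_absolute_uri <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) &&
    grepl("^[A-Za-z][A-Za-z0-9+.-]*://?[^ ]", x) && !grepl("[[:space:]]", x)
}

# --- class-expression constructors -----------------------------------------

ce_node <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = "class_expression")
}

#' Class-expression constructors
#'
#' Build abstract-syntax trees for Manchester-syntax class expressions.
#' `ce_named` wraps a single term; `ce_some`/`ce_only` build existential and
#' universal restrictions; `ce_value` a has-value restriction on a named
#' individual; `ce_and`/`ce_or` n-ary intersections and unions (at least two
#' operands, written order preserved); `ce_not` a complement.
#'
#' @param term,property,value a [term_ref()]
#' @param filler,operand a `class_expression`
#' @param operands list of at least two `class_expression` objects
#' @name class_expression
NULL

#' @rdname class_expression
#' @export
ce_named <- function(term) {
  stopifnot(inherits(term, "term_ref"))
  ce_node("named", list(term = term))
}

#' @rdname class_expression
#' @export
ce_some <- function(property, filler) {
  stopifnot(inherits(property, "term_ref"), inherits(filler, "class_expression"))
  ce_node("some", list(property = property, filler = filler))
}

#' @rdname class_expression
#' @export
ce_only <- function(property, filler) {
  stopifnot(inherits(property, "term_ref"), inherits(filler, "class_expression"))
  ce_node("only", list(property = property, filler = filler))
}

#' @rdname class_expression
#' @export
ce_value <- function(property, value) {
  stopifnot(inherits(property, "term_ref"), inherits(value, "term_ref"))
  ce_node("value", list(property = property, value = value))
}

#' @rdname class_expression
#' @export
ce_and <- function(operands) {
  stopifnot(is.list(operands), length(operands) >= 2L,
            all(vapply(operands, inherits, logical(1), "class_expression")))
  ce_node("and", list(operands = operands))
}

#' @rdname class_expression
#' @export
ce_or <- function(operands) {
  stopifnot(is.list(operands), length(operands) >= 2L,
            all(vapply(operands, inherits, logical(1), "class_expression")))
  ce_node("or", list(operands = operands))
}

#' @rdname class_expression
#' @export
ce_not <- function(operand) {
  stopifnot(inherits(operand, "class_expression"))
  ce_node("not", list(operand = operand))
}

#' @export
print.class_expression <- function(x, ...) {
  cat("<class_expression> ", render_class_expression(x), "\n", sep = "")
  invisible(x)
}

#' Structural equality of class expressions
#'
#' Two expressions are equal when they have the same tree shape and every
#' term reference resolves to the same URI (display forms are ignored).
#'
#' @param a,b `class_expression` objects
#' @return `TRUE` or `FALSE`
#' @export
expr_equal <- function(a, b) {
  if (!inherits(a, "class_expression") || !inherits(b, "class_expression")) return(FALSE)
  if (!identical(a$kind, b$kind)) return(FALSE)
  switch(a$kind,
    named = identical(a$term$uri, b$term$uri),
    some  = identical(a$property$uri, b$property$uri) && expr_equal(a$filler, b$filler),
    only  = identical(a$property$uri, b$property$uri) && expr_equal(a$filler, b$filler),
    value = identical(a$property$uri, b$property$uri) && identical(a$value$uri, b$value$uri),
    "and" = ,
    "or"  = length(a$operands) == length(b$operands) &&
            all(mapply(expr_equal, a$operands, b$operands)),
    "not" = expr_equal(a$operand, b$operand),
    FALSE)
}

# --- tokenizer --------------------------------------------------------------

mn_keywords <- c("some", "only", "value", "and", "or", "not")

# Tokens: list(type = label|uri|bare|keyword|lparen|rparen, value, pos)
mn_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  toks <- list()
  push <- function(type, value, pos) {
    toks[[length(toks) + 1L]] <<- list(type = type, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- chars[[i]]
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    start <- i
    if (ch == "'") {
      # quoted label, '' escapes a literal quote
      i <- i + 1L
      buf <- character(0)
      closed <- FALSE
      while (i <= n) {
        if (chars[[i]] == "'") {
          if (i + 1L <= n && chars[[i + 1L]] == "'") {
            buf <- c(buf, "'"); i <- i + 2L
          } else { closed <- TRUE; i <- i + 1L; break }
        } else { buf <- c(buf, chars[[i]]); i <- i + 1L }
      }
      if (!closed) stop(mn_err("unterminated quoted label", start, text))
      push("label", paste(buf, collapse = ""), start)
    } else if (ch == "<") {
      j <- i + 1L
      while (j <= n && chars[[j]] != ">") j <- j + 1L
      if (j > n) stop(mn_err("unterminated <URI>", start, text))
      push("uri", paste(chars[(i + 1L):(j - 1L)], collapse = ""), start)
      i <- j + 1L
    } else if (ch == "(") { push("lparen", "(", start); i <- i + 1L
    } else if (ch == ")") { push("rparen", ")", start); i <- i + 1L
    } else if (grepl("^[A-Za-z0-9_:./#-]$", ch)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z0-9_:./#-]$", chars[[j]])) j <- j + 1L
      word <- paste(chars[i:(j - 1L)], collapse = "")
      push(if (word %in% mn_keywords) "keyword" else "bare", word, start)
      i <- j
    } else {
      stop(mn_err(paste0("unexpected character '", ch, "'"), start, text))
    }
  }
  toks
}

mn_err <- function(msg, pos, text) {
  structure(
    class = c("manchester_parse_error", "error", "condition"),
    list(message = sprintf("Manchester syntax error at position %d: %s\n  in: %s",
                           pos, msg, text),
         call = NULL))
}

#' Build a label resolver
#'
#' Returns a resolution function `function(label) -> URI or NA` that looks
#' labels up first in the settings' term-URI declarations, then (optionally)
#' in a target-ontology label index. Bare non-quoted tokens that are not
#' absolute URIs are resolved by appending to `uri_start` when given.
#'
#' @param term_uris named character vector: label -> absolute URI
#' @param label_index optional second named character vector (e.g. the
#'   target ontology's label index) consulted when the first misses
#' @return a function usable as the `resolver` argument of
#'   [parse_class_expression()]
#' @export
make_resolver <- function(term_uris = character(0), label_index = character(0)) {
  term_uris <- as_named_chr(term_uris)
  label_index <- as_named_chr(label_index)
  function(label) {
    if (label %in% names(term_uris)) return(unname(term_uris[[label]]))
    if (label %in% names(label_index)) return(unname(label_index[[label]]))
    NA_character_
  }
}

as_named_chr <- function(x) {
  if (is.null(x) || !length(x)) return(stats::setNames(character(0), character(0)))
  stopifnot(is.character(x), !is.null(names(x)))
  x
}

# --- parser -----------------------------------------------------------------

#' Parse a Manchester-syntax class expression
#'
#' @param text fully substituted expression text (no residual `{$column}`
#'   variables).
#' @param resolver a function `label -> URI or NA`, e.g. from
#'   [make_resolver()]. All quoted labels must resolve; unresolvable labels
#'   are collected and reported together in a single error.
#' @param uri_start optional absolute URI prefix against which bare
#'   CURIE-like atoms (e.g. `CLO_0000001`) are resolved.
#' @return a `class_expression`
#' @export
parse_class_expression <- function(text, resolver = make_resolver(),
                                   uri_start = NULL) {
  toks <- mn_tokenize(text)
  if (!length(toks)) stop(mn_err("empty expression", 1L, text))
  unknown <- character(0)
  pos <- 1L

  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect_kw <- function(t, what) {
    if (is.null(t)) stop(mn_err(paste0("expected ", what, ", found end of input"),
                                nchar(text) + 1L, text))
    t
  }
  resolve_ref <- function(tok) {
    if (tok$type == "uri") {
      if (!is_absolute_uri(tok$value)) {
        stop(mn_err(paste0("relative URI <", tok$value, ">"), tok$pos, text))
      }
      return(term_ref(tok$value))
    }
    if (tok$type == "bare") {
      if (is_absolute_uri(tok$value)) return(term_ref(tok$value))
      if (!is.null(uri_start)) {
        return(term_ref(paste0(uri_start, tok$value), display = NULL))
      }
      unknown <<- c(unknown, tok$value)
      return(term_ref("http://unresolved.invalid/", display = tok$value))
    }
    uri <- resolver(tok$value)
    if (is.na(uri)) {
      unknown <<- c(unknown, tok$value)
      return(term_ref("http://unresolved.invalid/", display = tok$value))
    }
    term_ref(uri, display = tok$value)
  }

  parse_or <- function() {
    ops <- list(parse_and())
    while (!is.null(peek()) && peek()$type == "keyword" && peek()$value == "or") {
      advance()
      ops[[length(ops) + 1L]] <- parse_and()
    }
    if (length(ops) == 1L) ops[[1L]] else ce_or(ops)
  }
  parse_and <- function() {
    ops <- list(parse_not())
    while (!is.null(peek()) && peek()$type == "keyword" && peek()$value == "and") {
      advance()
      ops[[length(ops) + 1L]] <- parse_not()
    }
    if (length(ops) == 1L) ops[[1L]] else ce_and(ops)
  }
  parse_not <- function() {
    t <- peek()
    if (!is.null(t) && t$type == "keyword" && t$value == "not") {
      advance()
      return(ce_not(parse_not()))
    }
    parse_restriction()
  }
  parse_restriction <- function() {
    first_tok <- peek()
    left <- parse_primary()
    t <- peek()
    if (!is.null(t) && t$type == "keyword" && t$value %in% c("some", "only", "value")) {
      kw <- advance()$value
      if (left$kind != "named") {
        stop(mn_err(paste0("the property of a '", kw,
                           "' restriction must be a named term"),
                    first_tok$pos, text))
      }
      prop <- left$term
      filler <- parse_primary()
      if (kw == "value") {
        if (filler$kind != "named") {
          stop(mn_err("'value' requires a named individual", first_tok$pos, text))
        }
        return(ce_value(prop, filler$term))
      }
      return(if (kw == "some") ce_some(prop, filler) else ce_only(prop, filler))
    }
    left
  }
  parse_primary <- function() {
    t <- expect_kw(peek(), "a term or '('")
    if (t$type == "lparen") {
      advance()
      e <- parse_or()
      closing <- peek()
      if (is.null(closing) || closing$type != "rparen") {
        stop(mn_err("expected ')'", t$pos, text))
      }
      advance()
      return(e)
    }
    if (t$type %in% c("label", "uri", "bare")) {
      advance()
      return(ce_named(resolve_ref(t)))
    }
    stop(mn_err(paste0("unexpected token '", t$value, "'"), t$pos, text))
  }

  expr <- parse_or()
  if (pos <= length(toks)) {
    t <- toks[[pos]]
    stop(mn_err(paste0("unexpected trailing token '", t$value, "'"), t$pos, text))
  }
  if (length(unknown)) {
    stop(structure(
      class = c("label_resolution_error", "error", "condition"),
      list(message = paste0("unresolvable label(s): ",
                            paste0("'", unique(unknown), "'", collapse = ", "),
                            "; declare their URIs in the settings [Term URIs] section"),
           call = NULL, labels = unique(unknown))))
  }
  expr
}

# --- renderer ---------------------------------------------------------------

render_term <- function(ref) {
  if (!is.null(ref$display)) {
    paste0("'", gsub("'", "''", ref$display, fixed = TRUE), "'")
  } else {
    paste0("<", ref$uri, ">")
  }
}

# precedence: or=1, and=2, not=3, restriction=4, named=5
ce_prec <- function(e) {
  switch(e$kind, "or" = 1L, "and" = 2L, "not" = 3L,
         some = 4L, only = 4L, value = 4L, named = 5L)
}

#' Render a class expression as Manchester syntax
#'
#' Produces the minimal-parenthesis canonical text: parentheses are inserted
#' only where required to re-parse to a structurally identical tree (boolean
#' operands of equal or lower precedence, and non-atomic restriction
#' fillers).
#'
#' @param expr a `class_expression`
#' @return a single string
#' @export
render_class_expression <- function(expr) {
  stopifnot(inherits(expr, "class_expression"))
  wrap <- function(e, need_paren) {
    s <- render_class_expression(e)
    if (need_paren) paste0("(", s, ")") else s
  }
  switch(expr$kind,
    named = render_term(expr$term),
    some  = paste0(render_term(expr$property), " some ",
                   wrap(expr$filler, expr$filler$kind != "named")),
    only  = paste0(render_term(expr$property), " only ",
                   wrap(expr$filler, expr$filler$kind != "named")),
    value = paste0(render_term(expr$property), " value ", render_term(expr$value)),
    "and" = paste(vapply(expr$operands, function(o) wrap(o, ce_prec(o) <= 2L),
                         character(1)), collapse = " and "),
    "or"  = paste(vapply(expr$operands, function(o) wrap(o, ce_prec(o) <= 1L),
                         character(1)), collapse = " or "),
    "not" = paste0("not ", wrap(expr$operand, ce_prec(expr$operand) <= 2L))
  )
}

# --- intermediate Manchester document ---------------------------------------

mn_literal <- function(value, lang = NULL, datatype = NULL) {
  s <- paste0("\"", gsub("\"", "\\\"", gsub("\\", "\\\\", value, fixed = TRUE),
                         fixed = TRUE), "\"")
  if (!is.null(lang) && nzchar(lang)) s <- paste0(s, "@", lang)
  else if (!is.null(datatype) && nzchar(datatype)) s <- paste0(s, "^^<", datatype, ">")
  s
}

#' Render the intermediate Manchester-syntax document
#'
#' The human-debuggable textual form of the generated frames, produced
#' before conversion to the final OWL serialization. One `Class:` frame per
#' generated class, with `Annotations:`, `SubClassOf:` and `EquivalentTo:`
#' sections in that order. Term references are written as their quoted
#' display label when one is known, otherwise as `<URI>`.
#'
#' @param classes list of `generated_class` objects (see [expand_row()])
#' @param ontology_iri IRI written in the `Ontology:` header
#' @param prefixes named character vector of prefix declarations
#' @return the document as a single string
#' @export
render_manchester_document <- function(classes, ontology_iri,
                                       prefixes = default_prefixes()) {
  lines <- character(0)
  for (p in names(prefixes)) {
    lines <- c(lines, sprintf("Prefix: %s: <%s>", p, prefixes[[p]]))
  }
  lines <- c(lines, "", sprintf("Ontology: <%s>", ontology_iri), "")
  for (cls in classes) {
    lines <- c(lines, sprintf("Class: <%s>", cls$uri))
    if (length(cls$annotations)) {
      lines <- c(lines, "    Annotations:")
      ann_lines <- vapply(cls$annotations, function(a) {
        prop <- if (!is.null(a$property_display)) {
          paste0("'", gsub("'", "''", a$property_display, fixed = TRUE), "'")
        } else paste0("<", a$property, ">")
        paste0("        ", prop, " ", mn_literal(a$value, a$lang, a$datatype))
      }, character(1))
      lines <- c(lines, paste0(ann_lines, c(rep(",", length(ann_lines) - 1L), "")))
    }
    for (e in cls$superclasses) {
      lines <- c(lines, "    SubClassOf:",
                 paste0("        ", render_class_expression(e)))
    }
    for (e in cls$equivalents) {
      lines <- c(lines, "    EquivalentTo:",
                 paste0("        ", render_class_expression(e)))
    }
    lines <- c(lines, "")
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Default prefix declarations for emitted documents
#' @export
default_prefixes <- function() {
  c(rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs = "http://www.w3.org/2000/01/rdf-schema#",
    owl  = "http://www.w3.org/2002/07/owl#",
    xsd  = "http://www.w3.org/2001/XMLSchema#")
}
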