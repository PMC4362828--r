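# The axiom-settings artifact: the reusable pattern file.
#
# A settings file captures everything about a design pattern except the
# per-term data: the operation mode, the annotation / equivalent-class /
# superclass templates (Manchester syntax with {$columnX} variables), the
# label -> URI declarations for every quoted term, the start portion of the
# term URI, and either an ID-minting policy (new_classes) or the key column
# holding existing term URIs (edit_existing).
#
# Canonical dialect: line-oriented UTF-8 text with bracketed section
# headers, one declaration per line, "#" comments, blank lines ignored:
#
#   [Operation]            new_classes | edit_existing
#   [Term ID]              prefix=CLO_ / digits=7 / start=10000
#   [Key column]           e.g. A           (edit_existing only)
#   [Start portion of term URI]
#   [Term URIs]            'label' <URI>
#   [Annotations]          'property' "value template" [@lang | ^^<datatype>]
#   [Equivalent classes]   one Manchester template per line
#   [Superclasses]         one Manchester template per line
#   [Multivalue delimiter] single character, default "|"

#' ID-minting policy
#'
#' OBO-style local identifiers are a short prefix followed by a fixed-width
#' zero-padded number, e.g. `VO_0010000` (prefix `"VO_"`, 7 digits).
#'
#' @param prefix non-empty identifier prefix without whitespace, e.g. `"VO_"`
#' @param digits number of numeric digits, between 1 and 18
#' @param start first candidate ID number (non-negative, `< 10^digits`)
#' @return an object of class `id_policy`
#' @export
id_policy <- function(prefix, digits, start = 0) {
  digits <- as.integer(digits)
  start <- as.numeric(start)
  if (!is.character(prefix) || length(prefix) != 1L || !nzchar(prefix) ||
      grepl("[[:space:]]", prefix)) {
    stop("id policy prefix must be non-empty and contain no whitespace",
         call. = FALSE)
  }
  if (is.na(digits) || digits < 1L || digits > 18L) {
    stop("id policy digits must be between 1 and 18", call. = FALSE)
  }
  if (is.na(start) || start < 0 || start >= 10^digits || start != floor(start)) {
    stop(sprintf("id policy start must be an integer in [0, 10^%d)", digits),
         call. = FALSE)
  }
  structure(list(prefix = prefix, digits = digits, start = start),
            class = "id_policy")
}

#' Annotation pattern
#'
#' @param property_ref how the annotation property is written in the
#'   pattern: a label (resolved through the term-URI map) or an absolute URI.
#' @param value_template literal value template, possibly containing
#'   `{$columnX}` variables.
#' @param lang optional language tag; `datatype` optional datatype URI
#'   (mutually exclusive; plain literals by default).
#' @export
annotation_pattern <- function(property_ref, value_template,
                               lang = NULL, datatype = NULL) {
  stopifnot(is.character(property_ref), length(property_ref) == 1L,
            is.character(value_template), length(value_template) == 1L)
  if (!is.null(lang) && !is.null(datatype)) {
    stop("an annotation value may carry a language tag or a datatype, not both",
         call. = FALSE)
  }
  structure(list(property_ref = property_ref, value_template = value_template,
                 lang = lang, datatype = datatype),
            class = "annotation_pattern")
}

#' Class-expression pattern
#'
#' @param template Manchester-syntax class-expression template, possibly
#'   containing `{$columnX}` variables.
#' @param kind `"superclass"` (necessary condition) or `"equivalent"`
#'   (necessary and sufficient).
#' @export
expression_pattern <- function(template, kind = c("superclass", "equivalent")) {
  kind <- match.arg(kind)
  stopifnot(is.character(template), length(template) == 1L)
  structure(list(template = template, kind = kind), class = "expression_pattern")
}

#' Axiom settings: the full reusable pattern specification
#'
#' @param operation `"new_classes"` (mint classes, one per data row) or
#'   `"edit_existing"` (attach new axioms to classes named in `key_column`).
#' @param uri_start absolute URI prefix for newly minted terms, e.g. the OBO
#'   PURL base `"http://purl.obolibrary.org/obo/"`.
#' @param annotation_patterns list of [annotation_pattern()] objects.
#' @param expression_patterns list of [expression_pattern()] objects.
#' @param term_uris named character vector mapping each quoted label used in
#'   any pattern to its absolute URI.
#' @param id_policy an [id_policy()]; required when `operation =
#'   "new_classes"`.
#' @param key_column spreadsheet column letters of the cell holding the
#'   existing term's URI or local ID; required when `operation =
#'   "edit_existing"`.
#' @param multivalue_delimiter single character splitting multi-valued
#'   cells; default `"|"` (escape a literal occurrence as `\\|`).
#' @return an object of class `axiom_settings`
#' @export
axiom_settings <- function(operation = c("new_classes", "edit_existing"),
                           uri_start,
                           annotation_patterns = list(),
                           expression_patterns = list(),
                           term_uris = character(0),
                           id_policy = NULL,
                           key_column = NULL,
                           multivalue_delimiter = "|") {
  operation <- match.arg(operation)
  if (!is_absolute_uri(uri_start)) {
    stop("uri_start must be an absolute URI, got: ", deparse(uri_start),
         call. = FALSE)
  }
  if (operation == "new_classes" && is.null(id_policy)) {
    stop("operation 'new_classes' requires an id_policy ([Term ID] section)",
         call. = FALSE)
  }
  if (operation == "edit_existing" && is.null(key_column)) {
    stop("operation 'edit_existing' requires a key_column ([Key column] section)",
         call. = FALSE)
  }
  if (!is.null(id_policy)) stopifnot(inherits(id_policy, "id_policy"))
  if (!is.null(key_column)) {
    key_column <- toupper(key_column)
    column_index(key_column)  # validates the letters
  }
  stopifnot(is.list(annotation_patterns),
            all(vapply(annotation_patterns, inherits, logical(1),
                       "annotation_pattern")),
            is.list(expression_patterns),
            all(vapply(expression_patterns, inherits, logical(1),
                       "expression_pattern")))
  if (length(term_uris)) {
    stopifnot(is.character(term_uris), !is.null(names(term_uris)),
              !anyDuplicated(names(term_uris)))
    bad <- term_uris[!vapply(term_uris, is_absolute_uri, logical(1))]
    if (length(bad)) {
      stop("term URIs must be absolute; offending: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  } else {
    term_uris <- stats::setNames(character(0), character(0))
  }
  if (!is.character(multivalue_delimiter) || nchar(multivalue_delimiter) != 1L) {
    stop("multivalue_delimiter must be a single character", call. = FALSE)
  }
  # canonical pattern order: equivalent-class patterns before superclasses
  # (stable within each kind), matching the settings-file section order
  kinds <- vapply(expression_patterns, function(p) p$kind, character(1))
  expression_patterns <- c(expression_patterns[kinds == "equivalent"],
                           expression_patterns[kinds == "superclass"])
  structure(list(operation = operation,
                 uri_start = uri_start,
                 annotation_patterns = annotation_patterns,
                 expression_patterns = expression_patterns,
                 term_uris = term_uris,
                 id_policy = id_policy,
                 key_column = key_column,
                 multivalue_delimiter = multivalue_delimiter),
            class = "axiom_settings")
}

#' @export
print.axiom_settings <- function(x, ...) {
  cat(sprintf(paste0("<axiom_settings: %s, %d annotation pattern(s), ",
                     "%d expression pattern(s), %d term URI(s)>\n"),
              x$operation, length(x$annotation_patterns),
              length(x$expression_patterns), length(x$term_uris)))
  invisible(x)
}

# --- serialization ----------------------------------------------------------

quote_label <- function(label) paste0("'", gsub("'", "''", label, fixed = TRUE), "'")

serialize_term_ref <- function(ref) {
  if (is_absolute_uri(ref)) paste0("<", ref, ">") else quote_label(ref)
}

serialize_annotation_line <- function(p) {
  suffix <- if (!is.null(p$lang)) paste0(" @", p$lang)
            else if (!is.null(p$datatype)) paste0(" ^^<", p$datatype, ">")
            else ""
  paste0(serialize_term_ref(p$property_ref), " ",
         "\"", gsub("\"", "\\\"",
                    gsub("\\", "\\\\", p$value_template, fixed = TRUE),
                    fixed = TRUE), "\"", suffix)
}

#' Serialize axiom settings to the canonical settings-file text
#'
#' The output parses back to an equal `axiom_settings` object
#' (`parse_settings(serialize_settings(s))` equals `s`). Sections are
#' emitted in canonical order: Operation, Term ID / Key column, start
#' portion of the term URI, Term URIs, Annotations, Equivalent classes,
#' Superclasses, Multivalue delimiter.
#'
#' @param settings an [axiom_settings()] object
#' @return the settings file content as a single string
#' @export
serialize_settings <- function(settings) {
  stopifnot(inherits(settings, "axiom_settings"))
  num_chr <- function(n) sprintf("%.0f", n)
  out <- c("[Operation]", settings$operation, "")
  if (!is.null(settings$id_policy)) {
    p <- settings$id_policy
    out <- c(out, "[Term ID]",
             paste0("prefix=", p$prefix),
             paste0("digits=", p$digits),
             paste0("start=", num_chr(p$start)), "")
  }
  if (!is.null(settings$key_column)) {
    out <- c(out, "[Key column]", settings$key_column, "")
  }
  out <- c(out, "[Start portion of term URI]", settings$uri_start, "")
  if (length(settings$term_uris)) {
    out <- c(out, "[Term URIs]",
             vapply(names(settings$term_uris), function(lab) {
               paste0(quote_label(lab), " <", settings$term_uris[[lab]], ">")
             }, character(1)), "")
  }
  if (length(settings$annotation_patterns)) {
    out <- c(out, "[Annotations]",
             vapply(settings$annotation_patterns, serialize_annotation_line,
                    character(1)), "")
  }
  eq <- Filter(function(p) p$kind == "equivalent", settings$expression_patterns)
  su <- Filter(function(p) p$kind == "superclass", settings$expression_patterns)
  if (length(eq)) {
    out <- c(out, "[Equivalent classes]",
             vapply(eq, function(p) p$template, character(1)), "")
  }
  if (length(su)) {
    out <- c(out, "[Superclasses]",
             vapply(su, function(p) p$template, character(1)), "")
  }
  if (!identical(settings$multivalue_delimiter, "|")) {
    out <- c(out, "[Multivalue delimiter]", settings$multivalue_delimiter, "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

# --- parsing ----------------------------------------------------------------

settings_sections <- c("Operation", "Term ID", "Key column",
                       "Start portion of term URI", "Term URIs",
                       "Annotations", "Equivalent classes", "Superclasses",
                       "Multivalue delimiter")

settings_error <- function(msg, line = NULL) {
  if (!is.null(line)) msg <- sprintf("line %d: %s", line, msg)
  structure(class = c("settings_parse_error", "error", "condition"),
            list(message = msg, call = NULL))
}

# parse `'label' <URI>` -> c(label = uri)
parse_term_uri_line <- function(content, lineno) {
  m <- regmatches(content,
                  regexec("^'((?:[^']|'')*)'\\s+<([^>]+)>$", content,
                          perl = TRUE))[[1]]
  if (length(m) != 3L) {
    stop(settings_error(
      paste0("malformed term-URI declaration (expected 'label' <URI>): ",
             content), lineno))
  }
  stats::setNames(m[[3]], gsub("''", "'", m[[2]], fixed = TRUE))
}

parse_annotation_line <- function(content, lineno) {
  # property ref: quoted label or <URI>
  m <- regmatches(content, regexec(
    "^(?:'((?:[^']|'')*)'|<([^>]+)>)\\s+\"((?:[^\"\\\\]|\\\\.)*)\"\\s*(@[A-Za-z-]+|\\^\\^<[^>]+>)?$",
    content, perl = TRUE))[[1]]
  if (length(m) != 5L) {
    stop(settings_error(
      paste0("malformed annotation pattern (expected 'property' \"value\"): ",
             content), lineno))
  }
  prop <- if (startsWith(content, "'")) gsub("''", "'", m[[2]], fixed = TRUE) else m[[3]]
  value <- gsub("\\\\(.)", "\\1", m[[4]])  # single-pass unescape of \" and \\
  lang <- datatype <- NULL
  if (nzchar(m[[5]])) {
    if (startsWith(m[[5]], "@")) lang <- substring(m[[5]], 2L)
    else datatype <- sub("\\^\\^<([^>]+)>", "\\1", m[[5]])
  }
  annotation_pattern(prop, value, lang = lang, datatype = datatype)
}

#' Parse a settings file
#'
#' Reads the canonical settings dialect (see [serialize_settings()] for the
#' layout). Comment lines (leading `#`) and blank lines are ignored; unknown
#' sections produce a warning and are skipped.
#'
#' @param text settings-file content as a single string, or a character
#'   vector of lines.
#' @return an [axiom_settings()] object
#' @export
parse_settings <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- strip_bom(lines)
  section <- NULL
  acc <- list()  # section name -> list of (content, lineno)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!section %in% settings_sections) {
        warning("unknown settings section [", section, "] ignored (line ", i, ")",
                call. = FALSE)
        section <- NA_character_
      }
      next
    }
    if (is.null(section)) {
      stop(settings_error(paste0("content before any [section] header: ", ln), i))
    }
    if (is.na(section)) next
    acc[[section]] <- c(acc[[section]], list(list(content = ln, lineno = i)))
  }

  get1 <- function(name) {
    if (is.null(acc[[name]])) return(NULL)
    if (length(acc[[name]]) > 1L) {
      stop(settings_error(paste0("section [", name, "] expects a single line"),
                          acc[[name]][[2]]$lineno))
    }
    acc[[name]][[1]]$content
  }

  operation <- get1("Operation")
  if (is.null(operation)) stop(settings_error("missing mandatory section [Operation]"))
  if (!operation %in% c("new_classes", "edit_existing")) {
    stop(settings_error(paste0("unknown operation: ", operation),
                        acc[["Operation"]][[1]]$lineno))
  }
  uri_start <- get1("Start portion of term URI")
  if (is.null(uri_start)) {
    stop(settings_error("missing mandatory section [Start portion of term URI]"))
  }

  policy <- NULL
  if (!is.null(acc[["Term ID"]])) {
    kv <- list()
    for (entry in acc[["Term ID"]]) {
      m <- regmatches(entry$content,
                      regexec("^(prefix|digits|start)\\s*=\\s*(\\S+)$", entry$content))[[1]]
      if (length(m) != 3L) {
        stop(settings_error(paste0("malformed [Term ID] line (expected ",
                                   "prefix=/digits=/start=): ", entry$content),
                            entry$lineno))
      }
      kv[[m[[2]]]] <- m[[3]]
    }
    missing_keys <- setdiff(c("prefix", "digits", "start"), names(kv))
    if (length(missing_keys)) {
      stop(settings_error(paste0("[Term ID] section missing: ",
                                 paste(missing_keys, collapse = ", "))))
    }
    num <- suppressWarnings(c(digits = as.numeric(kv$digits),
                              start = as.numeric(kv$start)))
    if (anyNA(num)) {
      stop(settings_error("[Term ID] digits and start must be numeric",
                          acc[["Term ID"]][[1]]$lineno))
    }
    policy <- id_policy(kv$prefix, num[["digits"]], num[["start"]])
  } else if (operation == "new_classes") {
    stop(settings_error(
      "operation 'new_classes' requires the [Term ID] section"))
  }

  key_column <- get1("Key column")
  if (operation == "edit_existing" && is.null(key_column)) {
    stop(settings_error(
      "operation 'edit_existing' requires the [Key column] section"))
  }

  term_uris <- stats::setNames(character(0), character(0))
  for (entry in acc[["Term URIs"]]) {
    term_uris <- c(term_uris, parse_term_uri_line(entry$content, entry$lineno))
  }
  ann <- lapply(acc[["Annotations"]],
                function(e) parse_annotation_line(e$content, e$lineno))
  expr <- c(
    lapply(acc[["Equivalent classes"]],
           function(e) expression_pattern(e$content, "equivalent")),
    lapply(acc[["Superclasses"]],
           function(e) expression_pattern(e$content, "superclass")))

  delim <- get1("Multivalue delimiter")
  axiom_settings(operation = operation,
                 uri_start = uri_start,
                 annotation_patterns = ann,
                 expression_patterns = expr,
                 term_uris = term_uris,
                 id_policy = policy,
                 key_column = key_column,
                 multivalue_delimiter = if (is.null(delim)) "|" else delim)
}

# --- validation -------------------------------------------------------------

issue <- function(kind, message) {
  structure(list(kind = kind, message = message), class = "ontoforge_issue")
}

#' @export
print.ontoforge_issue <- function(x, ...) {
  cat(sprintf("[%s] %s\n", x$kind, x$message))
  invisible(x)
}

quoted_labels_in <- function(text) {
  m <- regmatches(text, gregexpr("'(?:[^']|'')*'", text, perl = TRUE))[[1]]
  gsub("''", "'", substring(m, 2L, nchar(m) - 1L), fixed = TRUE)
}

#' Validate settings against a data table
#'
#' Collects (never raises) the problems that would make a run fail:
#' quoted labels missing from the term-URI map, variables addressing
#' columns beyond the table width, insufficient ID capacity for the row
#' count, and a missing key column in edit mode. An empty result means the
#' run can proceed.
#'
#' @param settings an [axiom_settings()]
#' @param table a [data_table()]
#' @return list of issues, each with fields `kind` and `message`
#' @export
validate_settings <- function(settings, table) {
  stopifnot(inherits(settings, "axiom_settings"), inherits(table, "data_table"))
  issues <- list()
  add <- function(kind, msg) issues[[length(issues) + 1L]] <<- issue(kind, msg)

  # unknown quoted labels across all patterns
  texts <- c(
    vapply(settings$annotation_patterns, function(p) p$property_ref, character(1)),
    vapply(settings$expression_patterns, function(p) p$template, character(1)))
  labels <- unique(unlist(lapply(texts[!vapply(texts, is_absolute_uri, logical(1))],
                                 quoted_labels_in)))
  unknown <- setdiff(labels, names(settings$term_uris))
  for (lab in unknown) {
    add("unknown_label",
        paste0("label '", lab, "' is not declared in [Term URIs]"))
  }
  # also flag annotation property refs that are labels (unquoted in storage)
  ann_props <- vapply(settings$annotation_patterns, function(p) p$property_ref,
                      character(1))
  for (pr in unique(ann_props)) {
    if (!is_absolute_uri(pr) && !pr %in% names(settings$term_uris)) {
      add("unknown_label",
          paste0("annotation property '", pr, "' is not declared in [Term URIs]"))
    }
  }

  # variables out of table range
  all_templates <- c(
    vapply(settings$annotation_patterns, function(p) p$value_template, character(1)),
    vapply(settings$expression_patterns, function(p) p$template, character(1)))
  vars <- unique(unlist(lapply(all_templates, find_variables)))
  for (v in vars) {
    if (column_index(v) >= table$width) {
      add("out_of_range_column",
          sprintf("variable {$column%s} addresses column %d but the table has %d column(s)",
                  v, column_index(v) + 1L, table$width))
    }
  }

  # ID capacity
  if (!is.null(settings$id_policy)) {
    p <- settings$id_policy
    capacity <- 10^p$digits - p$start
    need <- sum(vapply(table$rows, function(r) any(nzchar(r)), logical(1)))
    if (need > capacity) {
      add("id_capacity",
          sprintf("%d row(s) to mint but only %.0f ID(s) available (digits=%d, start=%.0f)",
                  need, capacity, p$digits, p$start))
    }
  }

  if (settings$operation == "edit_existing") {
    if (is.null(settings$key_column)) {
      add("missing_key_column", "edit_existing requires a key column")
    } else if (column_index(settings$key_column) >= table$width) {
      add("out_of_range_column",
          sprintf("key column %s is beyond the table width %d",
                  settings$key_column, table$width))
    }
  }
  issues
}
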