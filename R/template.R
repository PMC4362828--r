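# Variable substitution and row expansion.
#
# Pattern templates reference data-table columns with the {$columnX}
# convention ({$columnA} is the first column, {$columnB} the second, ...).
# expand_row() turns one data row into one generated_class: annotation
# patterns become annotation assertions, expression patterns are substituted
# and then parsed as Manchester-syntax class expressions. A pattern whose
# substitution touches an empty cell is skipped for that row (emitting
# axioms with blank literals or dangling term references would corrupt the
# ontology), and the skip is recorded in the run report.

variable_regex <- "\\{\\$column([A-Za-z]+)\\}"

# escape a string for use as a gsub replacement (backslashes only; there
# are no backreference digits to protect once backslashes are doubled)
esc_repl <- function(x) gsub("\\", "\\\\", x, fixed = TRUE)

#' Find column variables in a template
#'
#' @param template a pattern string.
#' @return column letters (upper-cased) in first-occurrence order, unique.
#'   Malformed near-matches such as `{$colA}` are left untouched; a warning
#'   is raised for anything that looks like an attempted variable.
#' @export
find_variables <- function(template) {
  m <- regmatches(template, gregexpr(variable_regex, template))[[1]]
  letters <- toupper(sub(variable_regex, "\\1", m))
  near <- regmatches(template,
                     gregexpr("\\{\\$[A-Za-z]*\\}?", template))[[1]]
  near <- near[!grepl(paste0("^", variable_regex, "$"), near)]
  if (length(near)) {
    warning("possible malformed column variable(s) left untouched: ",
            paste(near, collapse = ", "), call. = FALSE)
  }
  unique(letters)
}

#' Substitute row cells into a template
#'
#' Replaces every `{$columnX}` occurrence with `cell(table, row, X)`;
#' nothing else in the template is altered.
#'
#' @param template pattern string.
#' @param table a [data_table()].
#' @param row zero-based row index.
#' @return a list with fields `text` (the substituted string), `all_filled`
#'   (`TRUE` iff every referenced cell was non-empty) and `used_columns`.
#' @export
substitute_template <- function(template, table, row) {
  vars <- suppressWarnings(find_variables(template))
  text <- template
  all_filled <- TRUE
  for (v in vars) {
    val <- cell(table, row, v)
    if (!nzchar(val)) all_filled <- FALSE
    text <- gsub(paste0("\\{\\$column", v, "\\}"), esc_repl(val), text,
                 ignore.case = TRUE)
  }
  list(text = text, all_filled = all_filled, used_columns = vars)
}

# split a multi-valued cell on the unescaped delimiter; "\|" is a literal
split_multivalue <- function(value, delimiter) {
  if (!nzchar(value)) return(character(0))
  esc <- paste0("\\", delimiter)
  placeholder <- "\x01"
  tmp <- gsub(esc, placeholder, value, fixed = TRUE)
  parts <- strsplit(tmp, delimiter, fixed = TRUE)[[1]]
  gsub(placeholder, delimiter, parts, fixed = TRUE)
}

# all combinations of per-variable value vectors (Cartesian product,
# first variable varying slowest so row order is predictable)
value_combinations <- function(values_by_var) {
  if (!length(values_by_var)) return(list(stats::setNames(character(0), character(0))))
  grid <- expand.grid(rev(values_by_var), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(values_by_var)), drop = FALSE]
  names(grid) <- names(values_by_var)
  lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, , drop = FALSE]))
}

substitute_fixed <- function(template, assignment) {
  text <- template
  for (v in names(assignment)) {
    text <- gsub(paste0("\\{\\$column", v, "\\}"), esc_repl(assignment[[v]]),
                 text, ignore.case = TRUE)
  }
  text
}

#' Generated class
#'
#' One output term: its URI plus the annotation assertions, superclass
#' expressions and equivalent-class expressions generated for it.
#'
#' @param uri absolute URI of the class.
#' @param annotations list of annotation assertions, each a list with
#'   fields `property` (URI), `property_display`, `value`, `lang`,
#'   `datatype`.
#' @param superclasses,equivalents lists of `class_expression` objects.
#' @param is_new `TRUE` for classes minted in this run, `FALSE` in
#'   edit-existing mode.
#' @export
generated_class <- function(uri, annotations = list(), superclasses = list(),
                            equivalents = list(), is_new = TRUE) {
  if (!is_absolute_uri(uri)) stop("class URI is not absolute: ", uri, call. = FALSE)
  structure(list(uri = uri, annotations = annotations,
                 superclasses = superclasses, equivalents = equivalents,
                 is_new = is_new),
            class = "generated_class")
}

#' @export
print.generated_class <- function(x, ...) {
  cat(sprintf("<generated_class%s> %s\n  %d annotation(s), %d superclass(es), %d equivalent(s)\n",
              if (x$is_new) "" else " (existing)", x$uri,
              length(x$annotations), length(x$superclasses), length(x$equivalents)))
  invisible(x)
}

#' Expand one data row into a generated class
#'
#' Applies every pattern in the settings to the given row. Multi-valued
#' cells (values separated by the settings' delimiter) yield one axiom per
#' value; when a single pattern references several multi-valued cells the
#' Cartesian product of the values is emitted (with a warning above 25
#' combinations). Patterns referencing an empty cell are skipped and the
#' skip recorded.
#'
#' @param settings an [axiom_settings()].
#' @param table a [data_table()].
#' @param row zero-based row index.
#' @param subject_uri URI of the class the axioms attach to (minted for
#'   new classes, resolved from the key column when editing).
#' @param resolver label resolution function from [make_resolver()].
#' @param is_new whether this row mints a new class.
#' @return a list with fields `class` (a [generated_class()]) and `skipped`
#'   (list of `list(row, pattern, reason)` records).
#' @export
expand_row <- function(settings, table, row, subject_uri, resolver,
                       is_new = settings$operation == "new_classes") {
  delim <- settings$multivalue_delimiter
  skipped <- list()
  note_skip <- function(pattern, reason) {
    skipped[[length(skipped) + 1L]] <<- list(row = row, pattern = pattern,
                                             reason = reason)
  }

  pattern_values <- function(template) {
    # per-variable split values, or NULL when some referenced cell is empty
    vars <- suppressWarnings(find_variables(template))
    if (!length(vars)) return(list())
    vals <- lapply(vars, function(v) split_multivalue(cell(table, row, v), delim))
    names(vals) <- vars
    if (any(lengths(vals) == 0L)) return(NULL)
    vals
  }

  annotations <- list()
  for (p in settings$annotation_patterns) {
    vals <- pattern_values(p$value_template)
    if (is.null(vals)) {
      note_skip(p$value_template, "empty cell referenced by annotation pattern")
      next
    }
    prop_uri <- if (is_absolute_uri(p$property_ref)) p$property_ref else resolver(p$property_ref)
    if (is.na(prop_uri)) {
      stop("annotation property '", p$property_ref,
           "' has no URI declared", call. = FALSE)
    }
    combos <- value_combinations(vals)
    if (length(combos) > 25L) {
      warning(sprintf("row %d: pattern expands to %d multi-value combinations",
                      row, length(combos)), call. = FALSE)
    }
    for (a in combos) {
      annotations[[length(annotations) + 1L]] <- list(
        property = prop_uri,
        property_display = if (is_absolute_uri(p$property_ref)) NULL else p$property_ref,
        value = substitute_fixed(p$value_template, a),
        lang = p$lang, datatype = p$datatype)
    }
  }

  superclasses <- list()
  equivalents <- list()
  for (p in settings$expression_patterns) {
    vals <- pattern_values(p$template)
    if (is.null(vals)) {
      note_skip(p$template, "empty cell referenced by expression pattern")
      next
    }
    combos <- value_combinations(vals)
    if (length(combos) > 25L) {
      warning(sprintf("row %d: pattern expands to %d multi-value combinations",
                      row, length(combos)), call. = FALSE)
    }
    for (a in combos) {
      text <- substitute_fixed(p$template, a)
      expr <- tryCatch(
        parse_class_expression(text, resolver, uri_start = settings$uri_start),
        error = function(e) {
          stop(structure(
            class = c("row_expansion_error", "error", "condition"),
            list(message = sprintf("row %d, pattern \"%s\": %s",
                                   row, p$template, conditionMessage(e)),
                 call = NULL, row = row, pattern = p$template)))
        })
      if (p$kind == "superclass") {
        superclasses[[length(superclasses) + 1L]] <- expr
      } else {
        equivalents[[length(equivalents) + 1L]] <- expr
      }
    }
  }

  list(class = generated_class(subject_uri, annotations, superclasses,
                               equivalents, is_new = is_new),
       skipped = skipped)
}
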