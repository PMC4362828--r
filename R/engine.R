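# Run orchestration: settings + table + optional target ontology -> outputs.
#
# A run processes the data table row by row. In new_classes mode each
# non-empty row mints one class (IDs scanned from the target ontology so
# nothing collides); in edit_existing mode the subject URI is taken from
# the key column and only new axioms are attached. Both modes produce the
# intermediate Manchester-syntax document, the OWL output document and a
# run report.

#' Run report
#'
#' Bookkeeping for one engine run: rows read and processed, classes
#' generated, axiom counts by kind, skipped patterns and warnings.
#' @param rows_read,rows_processed,classes_generated counts
#' @param axioms_by_kind named numeric vector with entries `annotation`,
#'   `superclass`, `equivalent`
#' @param skipped_axioms list of `list(row, pattern, reason)` records
#' @param warnings character vector
#' @export
run_report <- function(rows_read = 0L, rows_processed = 0L,
                       classes_generated = 0L,
                       axioms_by_kind = c(annotation = 0L, superclass = 0L,
                                          equivalent = 0L),
                       skipped_axioms = list(), warnings = character(0)) {
  structure(list(rows_read = rows_read, rows_processed = rows_processed,
                 classes_generated = classes_generated,
                 axioms_by_kind = axioms_by_kind,
                 skipped_axioms = skipped_axioms, warnings = warnings),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("ontoforge run report\n")
  cat(sprintf("  rows read:         %d\n", x$rows_read))
  cat(sprintf("  rows processed:    %d\n", x$rows_processed))
  cat(sprintf("  classes generated: %d\n", x$classes_generated))
  cat(sprintf("  axioms:            %d annotation, %d superclass, %d equivalent\n",
              x$axioms_by_kind[["annotation"]],
              x$axioms_by_kind[["superclass"]],
              x$axioms_by_kind[["equivalent"]]))
  if (length(x$skipped_axioms)) {
    cat(sprintf("  skipped patterns:  %d (empty referenced cells)\n",
                length(x$skipped_axioms)))
  }
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

count_axioms <- function(classes) {
  c(annotation = sum(vapply(classes, function(g) length(g$annotations), integer(1))),
    superclass = sum(vapply(classes, function(g) length(g$superclasses), integer(1))),
    equivalent = sum(vapply(classes, function(g) length(g$equivalents), integer(1))))
}

resolver_for <- function(settings, snapshot) {
  make_resolver(settings$term_uris,
                if (is.null(snapshot)) character(0) else snapshot$label_index)
}

default_output_iri <- function(settings) {
  paste0(settings$uri_start, "ontoforge-output.owl")
}

run_core <- function(settings, table, snapshot, ontology_iri, skip_bad_rows) {
  resolver <- resolver_for(settings, snapshot)
  warnings <- character(0)
  skipped <- list()
  classes <- list()
  rows_processed <- 0L
  is_new_mode <- settings$operation == "new_classes"

  state <- NULL
  if (is_new_mode) {
    used <- if (is.null(snapshot)) numeric(0) else
      scan_existing_ids(snapshot, settings$id_policy, settings$uri_start)
    state <- id_state(settings$id_policy, used = used)
  }

  for (i in seq_len(n_rows(table))) {
    row <- i - 1L
    rowvals <- table$rows[[i]]
    if (!any(nzchar(rowvals))) next  # fully empty row

    if (is_new_mode) {
      subject_uri <- mint_uri(settings$uri_start, allocate(state))
    } else {
      key <- cell(table, row, settings$key_column)
      if (!nzchar(key)) {
        warnings <- c(warnings,
                      sprintf("row %d skipped: empty key cell in column %s",
                              row, settings$key_column))
        next
      }
      subject_uri <- if (is_absolute_uri(key)) key else
        mint_uri(settings$uri_start, key)
      if (!is_absolute_uri(subject_uri)) {
        stop(sprintf("row %d: key cell %s is neither a URI nor a local ID",
                     row, deparse(key)), call. = FALSE)
      }
    }

    expanded <- withCallingHandlers(
      tryCatch(
        expand_row(settings, table, row, subject_uri, resolver,
                   is_new = is_new_mode),
        error = function(e) {
          if (skip_bad_rows) {
            warnings <<- c(warnings, paste0("row ", row, " skipped: ",
                                            conditionMessage(e)))
            NULL
          } else stop(e)
        }),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (is.null(expanded)) next
    rows_processed <- rows_processed + 1L
    classes[[length(classes) + 1L]] <- expanded$class
    skipped <- c(skipped, expanded$skipped)
  }

  manchester <- render_manchester_document(classes, ontology_iri)
  output <- write_owl(classes, ontology_iri)
  report <- run_report(
    rows_read = n_rows(table),
    rows_processed = rows_processed,
    classes_generated = if (is_new_mode) length(classes) else 0L,
    axioms_by_kind = count_axioms(classes),
    skipped_axioms = skipped,
    warnings = warnings)
  list(output = output, manchester = manchester, report = report,
       classes = classes)
}

#' Generate new ontology classes from a data table
#'
#' One class is minted per non-empty data row, in row order; IDs are
#' scanned from the target-ontology snapshot (when given) so minted IDs
#' never duplicate existing ones.
#'
#' @param settings an [axiom_settings()] with `operation = "new_classes"`.
#' @param table a [data_table()].
#' @param snapshot optional [ontology_snapshot()] of the target ontology.
#' @param ontology_iri IRI for the output ontology; defaults to
#'   `uri_start` + `"ontoforge-output.owl"`.
#' @param skip_bad_rows if `TRUE`, a row whose substituted expression fails
#'   to parse is skipped with a warning instead of aborting the run.
#' @return a list with components `output` (an `output_document`),
#'   `manchester` (the intermediate document text), `report` (a
#'   [run_report()]) and `classes`.
#' @export
run_new_classes <- function(settings, table, snapshot = NULL,
                            ontology_iri = default_output_iri(settings),
                            skip_bad_rows = FALSE) {
  stopifnot(inherits(settings, "axiom_settings"), inherits(table, "data_table"))
  if (settings$operation != "new_classes") {
    stop("settings operation is '", settings$operation,
         "'; expected 'new_classes'", call. = FALSE)
  }
  run_core(settings, table, snapshot, ontology_iri, skip_bad_rows)
}

#' Attach new axioms to existing ontology classes
#'
#' The subject class of each row is read from the settings' key column: an
#' absolute URI is used verbatim, a bare local ID (e.g. `"VO_0000001"`) is
#' resolved against the URI start portion. No class declarations are
#' emitted; rows with an empty key cell are skipped with a warning.
#'
#' @inheritParams run_new_classes
#' @export
run_edit_existing <- function(settings, table, snapshot = NULL,
                              ontology_iri = default_output_iri(settings),
                              skip_bad_rows = FALSE) {
  stopifnot(inherits(settings, "axiom_settings"), inherits(table, "data_table"))
  if (settings$operation != "edit_existing") {
    stop("settings operation is '", settings$operation,
         "'; expected 'edit_existing'", call. = FALSE)
  }
  run_core(settings, table, snapshot, ontology_iri, skip_bad_rows)
}

#' Run with the mode taken from the settings
#'
#' Dispatches to [run_new_classes()] or [run_edit_existing()] according to
#' `settings$operation`.
#'
#' @inheritParams run_new_classes
#' @export
run_patterns <- function(settings, table, snapshot = NULL,
                         ontology_iri = default_output_iri(settings),
                         skip_bad_rows = FALSE) {
  if (settings$operation == "new_classes") {
    run_new_classes(settings, table, snapshot, ontology_iri, skip_bad_rows)
  } else {
    run_edit_existing(settings, table, snapshot, ontology_iri, skip_bad_rows)
  }
}
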