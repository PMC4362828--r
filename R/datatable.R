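# Input data tables with spreadsheet-letter column addressing.
#
# A data_table is the populated quick-term template: one to-be-generated (or
# to-be-edited) ontology term per row, one variable per column. Columns are
# addressed by spreadsheet letters ("A", "B", ..., "AA") because that is how
# pattern variables ({$columnA}) name them.

#' Construct a data table
#'
#' @param rows list of character vectors, one per data row. Rows are padded
#'   with empty strings to the width of the widest row (rectangularity).
#' @param header optional character vector of column names. Purely
#'   informational: `{$columnX}` addressing always refers to data rows.
#' @return an object of class `data_table` with fields `header`, `rows`
#'   (each padded to `width`) and `width`.
#' @export
data_table <- function(rows, header = NULL) {
  stopifnot(is.list(rows))
  rows <- lapply(rows, function(r) as.character(r))
  width <- if (length(rows)) max(c(0L, lengths(rows))) else 0L
  if (!is.null(header)) {
    header <- as.character(header)
    width <- max(width, length(header))
    length(header) <- width
    header[is.na(header)] <- ""
  }
  rows <- lapply(rows, function(r) {
    length(r) <- width
    r[is.na(r)] <- ""
    r
  })
  structure(list(header = header, rows = rows, width = width),
            class = "data_table")
}

#' @export
print.data_table <- function(x, ...) {
  cat(sprintf("<data_table: %d row(s) x %d column(s)%s>\n",
              length(x$rows), x$width,
              if (is.null(x$header)) "" else ", with header"))
  invisible(x)
}

#' Number of data rows in a table
#' @param table a `data_table`
#' @export
n_rows <- function(table) length(table$rows)

#' Convert spreadsheet column letters to a zero-based index
#'
#' Implements the bijective base-26 column sequence used by spreadsheets:
#' A -> 0, B -> 1, ..., Z -> 25, AA -> 26, AB -> 27, ...
#'
#' @param letters a single string of column letters; case-insensitive.
#' @return zero-based integer column index.
#' @export
column_index <- function(letters) {
  if (!is.character(letters) || length(letters) != 1L || is.na(letters) ||
      !grepl("^[A-Za-z]+$", letters)) {
    stop("column letters must be a non-empty alphabetic string, got: ",
         deparse(letters), call. = FALSE)
  }
  chars <- utf8ToInt(toupper(letters)) - utf8ToInt("A") + 1L
  idx <- 0
  for (d in chars) idx <- idx * 26 + d
  as.integer(idx - 1)
}

#' Read a cell by row index and column letters
#'
#' @param table a `data_table`
#' @param row zero-based data-row index (the header, if any, is excluded).
#' @param letters spreadsheet column letters.
#' @return the cell string; columns beyond the table width yield `""`.
#' @export
cell <- function(table, row, letters) {
  stopifnot(inherits(table, "data_table"))
  if (row < 0 || row >= length(table$rows)) {
    stop(sprintf("row index %d out of range [0, %d)", row, length(table$rows)),
         call. = FALSE)
  }
  j <- column_index(letters) + 1L
  r <- table$rows[[row + 1L]]
  if (j > length(r)) "" else r[[j]]
}

strip_bom <- function(x) sub("^\ufeff", "", x)

read_delim_rows <- function(path, sep) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines)) lines[1] <- strip_bom(lines[1])
  lapply(lines, function(ln) strsplit(ln, sep, fixed = TRUE)[[1]])
}

read_csv_rows <- function(path) {
  # RFC-4180 quoting, all cells kept as text
  df <- utils::read.csv(path, header = FALSE, colClasses = "character",
                        check.names = FALSE, blank.lines.skip = FALSE,
                        fileEncoding = "UTF-8", na.strings = character())
  if (!nrow(df)) return(list())
  df[[1]] <- strip_bom(df[[1]])
  lapply(seq_len(nrow(df)), function(i) as.character(df[i, ]))
}

#' Read an input data table
#'
#' @param source path to the input file.
#' @param format one of `"tsv"` (tab-delimited, no quoting), `"csv"`
#'   (RFC-4180 quoting) or `"xlsx"` (first worksheet only).
#' @param has_header if `TRUE` (default) the first row is treated as the
#'   template's header of element names and excluded from data rows.
#' @return a `data_table`. Trailing fully-empty rows are dropped; all rows
#'   are padded to the table width.
#' @export
read_table <- function(source, format = c("tsv", "csv", "xlsx"),
                       has_header = TRUE) {
  format <- match.arg(format)
  if (!file.exists(source)) {
    stop("input data file not found: ", source, call. = FALSE)
  }
  rows <- switch(format,
    tsv  = read_delim_rows(source, "\t"),
    csv  = read_csv_rows(source),
    xlsx = read_xlsx_rows(source)
  )
  # drop trailing fully-empty rows
  nonempty <- vapply(rows, function(r) any(nzchar(r)), logical(1))
  if (any(nonempty)) rows <- rows[seq_len(max(which(nonempty)))] else rows <- list()
  header <- NULL
  if (has_header && length(rows)) {
    header <- rows[[1]]
    rows <- rows[-1]
  }
  data_table(rows, header = header)
}

#' Write a data table as TSV
#'
#' @param table a `data_table`
#' @param path output file path
#' @export
write_table_tsv <- function(table, path) {
  stopifnot(inherits(table, "data_table"))
  lines <- character(0)
  if (!is.null(table$header)) lines <- paste(table$header, collapse = "\t")
  lines <- c(lines, vapply(table$rows, paste, character(1), collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# --- minimal XLSX (SpreadsheetML) reader -----------------------------------
# Reads the first worksheet of an .xlsx archive: shared strings, inline
# strings and raw values, honouring the A1-style cell references so that
# sparse rows land in the right columns.

xlsx_ns <- c(x = "http://schemas.openxmlformats.org/spreadsheetml/2006/main")

read_xlsx_rows <- function(path) {
  tmp <- tempfile("xlsx_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  files <- utils::unzip(path, exdir = tmp)
  sheets <- sort(grep("xl/worksheets/sheet[0-9]+\\.xml$", files, value = TRUE))
  if (!length(sheets)) stop("no worksheet found in xlsx file: ", path, call. = FALSE)
  if (length(sheets) > 1L) {
    warning("xlsx file has ", length(sheets),
            " worksheets; only the first is read", call. = FALSE)
  }
  shared <- character(0)
  ss_path <- file.path(tmp, "xl", "sharedStrings.xml")
  if (file.exists(ss_path)) {
    ss <- xml2::read_xml(ss_path)
    shared <- vapply(xml2::xml_find_all(ss, ".//x:si", ns = xlsx_ns),
                     xml2::xml_text, character(1))
  }
  sheet <- xml2::read_xml(sheets[[1]])
  out <- list()
  for (rnode in xml2::xml_find_all(sheet, ".//x:sheetData/x:row", ns = xlsx_ns)) {
    rowvals <- character(0)
    for (cnode in xml2::xml_find_all(rnode, "x:c", ns = xlsx_ns)) {
      ref <- xml2::xml_attr(cnode, "r")
      type <- xml2::xml_attr(cnode, "t")
      val <- if (!is.na(type) && type == "inlineStr") {
        xml2::xml_text(xml2::xml_find_first(cnode, "x:is", ns = xlsx_ns))
      } else {
        v <- xml2::xml_find_first(cnode, "x:v", ns = xlsx_ns)
        if (inherits(v, "xml_missing")) "" else xml2::xml_text(v)
      }
      if (!is.na(type) && type == "s") {
        i <- suppressWarnings(as.integer(val))
        val <- if (!is.na(i) && i + 1L <= length(shared)) shared[[i + 1L]] else ""
      }
      j <- if (is.na(ref)) length(rowvals) + 1L else
        column_index(gsub("[0-9]+$", "", ref)) + 1L
      if (j > length(rowvals)) length(rowvals) <- j
      rowvals[[j]] <- val
    }
    rowvals[is.na(rowvals)] <- ""
    out[[length(out) + 1L]] <- rowvals
  }
  out
}
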