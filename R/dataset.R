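#' Omics datasets
#'
#' An imported omics table: typed measurement columns plus rows keyed by an
#' [xref()].  Several rows may share one xref (e.g. multiple probes or
#' multiple experiments measuring the same gene); row order is the file
#' order throughout.
#'
#' @param data A data frame whose first columns are `datasource` and
#'   `identifier` (the row key) followed by measurement columns.
#' @param skipped Number of input rows dropped for having a blank
#'   identifier.
#' @return An object of class `omics_dataset` with fields `columns` (a
#'   tibble of `name`, `kind`), `data` (a tibble with `datasource`,
#'   `identifier` and one column per measurement) and `skipped`.
#' @export
omics_dataset <- function(data, skipped = 0L) {
  data <- as_tibble(data)
  if (!all(c("datasource", "identifier") %in% names(data))) {
    abort("`data` must have `datasource` and `identifier` columns")
  }
  meas <- setdiff(names(data), c("datasource", "identifier"))
  if (!length(meas)) abort("a dataset needs at least one measurement column")
  kinds <- vapply(meas, function(cn) {
    if (is.numeric(data[[cn]])) "numeric" else "text"
  }, character(1))
  structure(list(
    columns = tibble(name = meas, kind = unname(kinds)),
    data = data[c("datasource", "identifier", meas)],
    skipped = as.integer(skipped)),
    class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("<omics_dataset> %d row(s), %d measurement column(s)\n",
              nrow(x$data), nrow(x$columns)))
  for (i in seq_len(nrow(x$columns))) {
    cat(sprintf("  %s <%s>\n", x$columns$name[i], x$columns$kind[i]))
  }
  if (x$skipped > 0L) cat(sprintf("  (%d input row(s) skipped)\n", x$skipped))
  invisible(x)
}

# Strict numeric literal: decimal point only, optional scientific notation.
# Locale-dependent separators ("1,5") deliberately fail, so such a column
# stays text rather than silently changing meaning across machines.
NUMERIC_RE <- "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$"

#' Import a delimited omics data table
#'
#' Reads a TSV/CSV table of measurements keyed by an identifier column.
#' Column kinds are inferred: a column is numeric iff every non-missing
#' value parses as a plain real (decimal point, optional scientific
#' notation); a single unparseable non-missing value (e.g. `"n/a"`) makes
#' the whole column text.  Empty cells are missing.  Rows with a blank
#' identifier are skipped with one summary warning.
#'
#' @param file Path to the table, or a string containing it.
#' @param id_column Name of the identifier column.
#' @param system Identifier system for all rows (e.g. `"Entrez Gene"`), or
#' @param system_column name of a column giving each row's system.  Exactly
#'   one of `system`/`system_column` must be supplied.
#' @param sep Field separator; default: sniffed from the file extension
#'   (`.csv` is comma, anything else tab).
#' @return An [omics_dataset()].
#' @export
import_data_table <- function(file, id_column, system = NULL,
                              system_column = NULL, sep = NULL) {
  if (is.null(system) == is.null(system_column)) {
    abort("supply exactly one of `system` or `system_column`")
  }
  is_path <- length(file) == 1L && !grepl("\n", file) && file.exists(file)
  if (is.null(sep)) {
    sep <- if (is_path && grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  }
  src <- if (is_path) file else I(paste(file, collapse = "\n"))
  tab <- readr::read_delim(src, delim = sep,
                           col_types = readr::cols(.default = "c"),
                           na = character(), progress = FALSE,
                           show_col_types = FALSE)
  if (!id_column %in% names(tab)) {
    abort(sprintf("identifier column '%s' not found in table", id_column))
  }
  if (!is.null(system_column) && !system_column %in% names(tab)) {
    abort(sprintf("system column '%s' not found in table", system_column))
  }

  ids <- tab[[id_column]]
  blank <- is.na(ids) | !nzchar(trimws(ids))
  if (any(blank)) {
    warn(sprintf("%d row(s) skipped: blank identifier", sum(blank)))
    tab <- tab[!blank, , drop = FALSE]
  }

  systems <- if (!is.null(system)) rep(system, nrow(tab)) else tab[[system_column]]
  meas_names <- setdiff(names(tab), c(id_column, system_column))
  if (!length(meas_names)) abort("no measurement columns in table")

  out <- tibble(datasource = systems, identifier = tab[[id_column]])
  for (cn in meas_names) {
    v <- tab[[cn]]
    v[!is.na(v) & !nzchar(v)] <- NA_character_     # empty cell -> missing
    nonmiss <- v[!is.na(v)]
    if (length(nonmiss) && all(grepl(NUMERIC_RE, nonmiss))) {
      out[[cn]] <- as.numeric(v)
    } else {
      out[[cn]] <- v
    }
  }
  omics_dataset(out, skipped = sum(blank))
}

# Component key for each dataset row under a mapper: rows in the same mapper
# component share a key; unmapped rows key on their own xref.
row_keys <- function(d, m) {
  key <- xref_key(d$data$datasource, d$data$identifier)
  comp <- component_of(m, key)
  ifelse(is.na(comp), key, paste0("component:", comp))
}

single_key <- function(m, datasource, identifier) {
  key <- xref_key(datasource, identifier)
  comp <- component_of(m, key)
  if (is.na(comp)) key else paste0("component:", comp)
}

#' Dataset rows matching a pathway node
#'
#' Returns every dataset row whose xref matches `node_xref` under the
#' mapper (exact equality or cross-reference closure), in file order.
#'
#' @param d An [omics_dataset()].
#' @param m An [id_mapper()] or `NULL` (exact matching only).
#' @param node_xref The node's [xref()].
#' @return A tibble: the matching subset of `d$data`.
#' @export
rows_for_xref <- function(d, m, node_xref) {
  stopifnot(is_xref(node_xref))
  target <- single_key(m, node_xref$datasource, node_xref$identifier)
  d$data[row_keys(d, m) == target, , drop = FALSE]
}
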