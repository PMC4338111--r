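#' Table-driven identifier cross-reference mapping
#'
#' Omics datasets rarely use the identifier system the pathway author chose,
#' so data rows must be matched to pathway nodes through cross-reference
#' pairs (e.g. gene symbol `HGNC:KNG1` linked to `Entrez Gene:3827`).  An
#' `id_mapper` holds an undirected graph of such pairs; two xrefs match when
#' they are connected through any chain of pairs (full transitive closure —
#' the simplest policy consistent with mapping through a hub system without
#' designating one).  Identifiers and system names are compared exactly and
#' case-sensitively, as stored.
#'
#' @param pairs A data frame with columns `source_system`, `source_id`,
#'   `target_system`, `target_id`; one cross-reference pair per row.
#'   Duplicate pairs (in either orientation) collapse; a row linking an xref
#'   to itself is dropped.
#' @return An object of class `id_mapper`.
#' @seealso [load_mapping_table()], [map_xref()], [xrefs_match()]
#' @export
id_mapper <- function(pairs = NULL) {
  if (is.null(pairs) || !nrow(pairs)) {
    return(structure(list(pairs = tibble(source_system = character(),
                                         source_id = character(),
                                         target_system = character(),
                                         target_id = character()),
                          component = integer(), systems = character()),
                     class = "id_mapper"))
  }
  need <- c("source_system", "source_id", "target_system", "target_id")
  if (!all(need %in% names(pairs))) {
    abort(sprintf("mapping table is missing column(s): %s",
                  paste(setdiff(need, names(pairs)), collapse = ", ")))
  }
  pairs <- as_tibble(pairs)[need]
  blank <- !nzchar(pairs$source_id) | !nzchar(pairs$target_id) |
    !nzchar(pairs$source_system) | !nzchar(pairs$target_system) |
    is.na(pairs$source_id) | is.na(pairs$target_id)
  if (any(blank)) {
    abort(sprintf("blank identifier in mapping row(s): %s",
                  paste(which(blank), collapse = ", ")))
  }
  a <- xref_key(pairs$source_system, pairs$source_id)
  b <- xref_key(pairs$target_system, pairs$target_id)
  self <- a == b
  pairs <- pairs[!self, , drop = FALSE]; a <- a[!self]; b <- b[!self]
  # canonical unordered-pair key for dedup
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  pairs <- pairs[keep, , drop = FALSE]; a <- a[keep]; b <- b[keep]

  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  comp <- igraph::components(g)$membership
  structure(list(pairs = pairs, component = comp,
                 systems = sort(unique(c(pairs$source_system,
                                         pairs$target_system)))),
            class = "id_mapper")
}

#' @export
print.id_mapper <- function(x, ...) {
  cat(sprintf("<id_mapper> %d pair(s) across %d system(s)\n",
              nrow(x$pairs), length(x$systems)))
  invisible(x)
}

#' Load a cross-reference mapping table
#'
#' Reads a tab-separated table with header
#' `source_system  source_id  target_system  target_id` into an
#' [id_mapper()].  Each row adds one symmetric pair; duplicates collapse.  A
#' missing column or a blank identifier is an error (reported with its row
#' number).
#'
#' @param x Path to a TSV file, or a string containing the table.
#' @return An [id_mapper()].
#' @export
load_mapping_table <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    txt <- paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    txt <- paste(x, collapse = "\n")
  }
  tab <- readr::read_tsv(I(txt), col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  need <- c("source_system", "source_id", "target_system", "target_id")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    abort(sprintf("mapping table is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  id_mapper(tab)
}

component_of <- function(m, key) {
  if (is.null(m) || !length(m$component)) return(rep(NA_integer_, length(key)))
  unname(m$component[key])
}

#' Map an xref into a target identifier system
#'
#' Returns every xref in `target_system` reachable from `x` through the
#' mapper's pair graph (transitive closure).  When `x` is itself in the
#' target system it is included in the result, so mapping is always
#' reflexive within a system.  An xref unknown to the mapper yields an empty
#' result (or just itself when already in the target system).
#'
#' @param m An [id_mapper()] (or `NULL` for the empty mapper).
#' @param x An [xref()].
#' @param target_system Identifier system name to map into.
#' @return A tibble with columns `datasource`, `identifier`, sorted by
#'   identifier.
#' @examples
#' m <- load_mapping_table(paste(
#'   "source_system\tsource_id\ttarget_system\ttarget_id",
#'   "HGNC\tKNG1\tEntrez Gene\t3827", sep = "\n"))
#' map_xref(m, xref("HGNC", "KNG1"), "Entrez Gene")
#' @export
map_xref <- function(m, x, target_system) {
  stopifnot(is_xref(x))
  keys <- character()
  comp <- component_of(m, xref_key1(x))
  if (!is.na(comp)) {
    members <- names(m$component)[m$component == comp]
    keys <- members[startsWith(members, paste0(target_system, "\t"))]
  }
  if (identical(x$datasource, target_system)) {
    keys <- union(keys, xref_key1(x))
  }
  keys <- sort(keys, method = "radix")
  parts <- strsplit(keys, "\t", fixed = TRUE)
  tibble(datasource = vapply(parts, `[[`, character(1), 1L),
         identifier = vapply(parts, function(p) paste(p[-1L], collapse = "\t"),
                             character(1)))
}

#' Do two xrefs denote the same entity under a mapper?
#'
#' `TRUE` when `a` and `b` are exactly equal, or connected through the
#' mapper's cross-reference pairs.  Symmetric in its arguments.
#'
#' @inheritParams map_xref
#' @param a,b [xref()] objects.
#' @return A logical scalar.
#' @export
xrefs_match <- function(m, a, b) {
  stopifnot(is_xref(a), is_xref(b))
  if (xref_equal(a, b)) return(TRUE)
  ca <- component_of(m, xref_key1(a))
  cb <- component_of(m, xref_key1(b))
  !is.na(ca) && !is.na(cb) && ca == cb
}
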