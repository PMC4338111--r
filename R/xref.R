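#' External database cross-references
#'
#' An `xref` annotates a pathway element or a dataset row with a pair
#' (identifier system, identifier), e.g. the KNG1 gene annotated with the
#' Entrez Gene identifier "3827".  Both fields must be non-empty; an
#' unannotated element carries no xref at all (`NULL`), never an xref with
#' empty strings.  Equality is exact, case-sensitive string equality on both
#' fields.
#'
#' @param datasource Identifier system name, e.g. `"Entrez Gene"`,
#'   `"Ensembl"`, `"HMDB"`.
#' @param identifier Identifier within that system.
#' @return An object of class `xref`.
#' @examples
#' xref("Entrez Gene", "3827")
#' @export
xref <- function(datasource, identifier) {
  if (!is.character(datasource) || length(datasource) != 1L || is.na(datasource) ||
      !nzchar(datasource)) {
    abort("`datasource` must be a non-empty string")
  }
  if (!is.character(identifier) || length(identifier) != 1L || is.na(identifier) ||
      !nzchar(identifier)) {
    abort("`identifier` must be a non-empty string")
  }
  structure(list(datasource = datasource, identifier = identifier),
            class = "xref")
}

#' @export
print.xref <- function(x, ...) {
  cat(sprintf("<xref> %s:%s\n", x$datasource, x$identifier))
  invisible(x)
}

#' @export
format.xref <- function(x, ...) sprintf("%s:%s", x$datasource, x$identifier)

is_xref <- function(x) inherits(x, "xref")

#' @rdname xref
#' @param a,b Two `xref` objects.
#' @export
xref_equal <- function(a, b) {
  is_xref(a) && is_xref(b) &&
    identical(a$datasource, b$datasource) &&
    identical(a$identifier, b$identifier)
}

# Internal string key for set/map operations on xrefs.  Tab never occurs in
# either field of data read from delimited tables, and GPML attribute values
# containing a literal tab are not produced by any writer we know of.
xref_key <- function(datasource, identifier) paste(datasource, identifier, sep = "\t")
xref_key1 <- function(x) xref_key(x$datasource, x$identifier)
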