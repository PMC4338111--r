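GENE_TYPES <- c("GeneProduct", "Protein", "Rna")
METABOLITE_TYPES <- "Metabolite"

#' Hypergeometric Z-score for pathway over-representation
#'
#' Scores how strongly a pathway is enriched for genes meeting a criterion.
#' Drawing the pathway's `n` measured genes from a universe of `N` measured
#' genes of which `R` meet the criterion, the number of positives in the
#' pathway follows a hypergeometric distribution with mean `nR/N`; the
#' Z-score is the observed count `r` minus that expectation, divided by the
#' hypergeometric standard deviation:
#'
#' \deqn{Z = \frac{r - nR/N}{\sqrt{n \frac{R}{N}\left(1 - \frac{R}{N}\right)\left(1 - \frac{n-1}{N-1}\right)}}}
#'
#' Positive Z means more positives than expected (enrichment), negative
#' fewer.  When the variance collapses (`n == 0`, `n == N`, `R == 0` or
#' `R == N`) the score is undefined and `NA` is returned — not 0, which
#' would fake "exactly as expected".
#'
#' @param n Genes of the pathway measured in the dataset.
#' @param r Of those, genes meeting the criterion.
#' @param N Measured genes present in at least one pathway of the
#'   collection.
#' @param R Of those, genes meeting the criterion.
#' @return A numeric vector (arguments recycle); `NA` where undefined.
#' @examples
#' zscore(n = 10, r = 5, N = 100, R = 20)
#' zscore(n = 10, r = 2, N = 100, R = 20)  # exactly the expected count: 0
#' @export
zscore <- function(n, r, N, R) {
  k <- max(length(n), length(r), length(N), length(R))
  n <- rep_len(as.numeric(n), k); r <- rep_len(as.numeric(r), k)
  N <- rep_len(as.numeric(N), k); R <- rep_len(as.numeric(R), k)
  bad <- is.na(n) | is.na(r) | is.na(N) | is.na(R) |
    r < 0 | r > n | n > N | R < 0 | R > N | N < 1
  if (any(bad)) {
    abort("zscore() requires 0 <= r <= n <= N, 0 <= R <= N and N >= 1")
  }
  undef <- n == 0 | n == N | R == 0 | R == N
  z <- rep(NA_real_, k)
  i <- !undef
  p <- R[i] / N[i]
  # numerator as (rN - nR)/N: the products are exact integers, so r equal to
  # its expectation nR/N gives exactly zero
  z[i] <- ((r[i] * N[i] - n[i] * R[i]) / N[i]) /
    sqrt(n[i] * p * (1 - p) * (1 - (n[i] - 1) / (N[i] - 1)))
  z
}

#' Per-pathway over-representation counts
#'
#' Counts, for one pathway: `total`, the distinct xrefs annotated on data
#' nodes of the selected types; `n`, how many of those have at least one
#' matching dataset row; and `r`, how many have at least one matching row on
#' which the criterion evaluates exactly true.  Counting is gene-level: the
#' same annotation on two nodes, or several dataset rows for one gene,
#' contribute once, and any true row makes its gene positive.
#'
#' @param p A [pathway()].
#' @param d An [omics_dataset()].
#' @param m An [id_mapper()] or `NULL`.
#' @param criterion A criterion (object or source text).
#' @param types Data node types that enter the analysis (default: gene-like
#'   types GeneProduct, Protein, Rna).
#' @return A named numeric vector `c(total =, n =, r =)`.
#' @export
pathway_counts <- function(p, d, m, criterion, types = GENE_TYPES) {
  truth <- eval_criterion_rows(criterion, d$data)
  counts_from_xrefs(annotated_xrefs(p, types), d, m, truth)
}

counts_from_xrefs <- function(xr, d, m, truth) {
  total <- nrow(xr)
  if (!total) return(c(total = 0, n = 0, r = 0))
  keys <- row_keys(d, m)
  measured_keys <- unique(keys)
  positive_keys <- unique(keys[truth %in% TRUE])
  node_keys <- vapply(seq_len(total), function(i) {
    single_key(m, xr$datasource[i], xr$identifier[i])
  }, character(1))
  c(total = total,
    n = sum(node_keys %in% measured_keys),
    r = sum(node_keys %in% positive_keys))
}

#' Collection-wide counts for over-representation analysis
#'
#' Builds the union of annotated xrefs over all pathways, merged into
#' mapper-equivalence classes, and counts `N`, the classes with at least
#' one matching dataset row, and `R`, those with at least one row meeting
#' the criterion.  Genes measured in the dataset but absent from every
#' pathway are ignored.
#'
#' @param coll A [pathway_collection()].
#' @inheritParams pathway_counts
#' @return A named numeric vector `c(N =, R =)`.
#' @export
global_counts <- function(coll, d, m, criterion, types = GENE_TYPES) {
  truth <- eval_criterion_rows(criterion, d$data)
  keys <- row_keys(d, m)
  measured_keys <- unique(keys)
  positive_keys <- unique(keys[truth %in% TRUE])

  class_keys <- character()
  for (p in coll$pathways) {
    xr <- annotated_xrefs(p, types)
    if (nrow(xr)) {
      class_keys <- c(class_keys, vapply(seq_len(nrow(xr)), function(i) {
        single_key(m, xr$datasource[i], xr$identifier[i])
      }, character(1)))
    }
  }
  class_keys <- unique(class_keys)
  c(N = sum(class_keys %in% measured_keys),
    R = sum(class_keys %in% positive_keys))
}

#' Over-representation analysis across a pathway collection
#'
#' Runs the full analysis: evaluates the criterion over the dataset,
#' computes the global counts `N` and `R` and the per-pathway counts
#' (`total`, `n`, `r`), scores every pathway with [zscore()] and ranks the
#' result by Z-score, descending.  Undefined scores sort last; ties break
#' by pathway name, then source filename, ascending, so the ranking is
#' fully deterministic.
#'
#' @inheritParams global_counts
#' @return An `ora_report`: fields `criterion` (text), `N`, `R`, and `rows`,
#'   a tibble with columns `pathway`, `file`, `total`, `measured`,
#'   `positive`, `zscore`.  Use [tidy()] / [glance()] / [autoplot()] on it.
#' @examples
#' \donttest{
#' fx <- fixture_spec(n_pathways = 5, genes_per_pathway = 6,
#'                    gene_universe = 40, planted_index = 2, seed = 1)
#' coll <- generate_collection(fx)
#' d <- import_data_table(generate_dataset(fx, coll$collection),
#'                        id_column = "id", system = "SysB")
#' m <- load_mapping_table(coll$idmap)
#' run_ora(coll$collection, d, m, "ABS([log2FC]) > 1 AND [pvalue] < 0.05")
#' }
#' @export
run_ora <- function(coll, d, m, criterion, types = GENE_TYPES) {
  criterion <- as_criterion(criterion)
  truth <- eval_criterion_rows(criterion, d$data)
  keys <- row_keys(d, m)
  measured_keys <- unique(keys)
  positive_keys <- unique(keys[truth %in% TRUE])

  k <- length(coll$pathways)
  total <- n <- r <- numeric(k)
  all_class_keys <- character()
  per_pathway_keys <- vector("list", k)
  for (i in seq_len(k)) {
    xr <- annotated_xrefs(coll$pathways[[i]], types)
    nk <- if (nrow(xr)) vapply(seq_len(nrow(xr)), function(j) {
      single_key(m, xr$datasource[j], xr$identifier[j])
    }, character(1)) else character()
    per_pathway_keys[[i]] <- nk
    all_class_keys <- c(all_class_keys, nk)
    total[i] <- nrow(xr)
    n[i] <- sum(nk %in% measured_keys)
    r[i] <- sum(nk %in% positive_keys)
  }
  all_class_keys <- unique(all_class_keys)
  N <- sum(all_class_keys %in% measured_keys)
  R <- sum(all_class_keys %in% positive_keys)
  if (R == 0) {
    warn("no gene in any pathway meets the criterion (R = 0); all Z-scores are undefined")
  }

  z <- if (N >= 1) zscore(n, r, rep(N, k), rep(R, k)) else rep(NA_real_, k)
  rows <- tibble(
    pathway = vapply(coll$pathways, `[[`, character(1), "name"),
    file = coll$files,
    total = as.integer(total), measured = as.integer(n),
    positive = as.integer(r), zscore = z)
  sort_key <- ifelse(is.na(rows$zscore), -Inf, rows$zscore)
  rows <- rows[order(-sort_key, rows$pathway, rows$file, method = "radix"), ]

  structure(list(criterion = criterion$source_text,
                 N = as.integer(N), R = as.integer(R), rows = rows),
            class = "ora_report")
}

#' @export
print.ora_report <- function(x, ...) {
  cat(sprintf("<ora_report> criterion: %s\n", x$criterion))
  cat(sprintf("  N = %d measured genes in pathways, R = %d meeting the criterion\n",
              x$N, x$R))
  print(x$rows, ...)
  invisible(x)
}

#' @rdname run_ora
#' @param x An `ora_report`.
#' @param ... Unused.
#' @export
tidy.ora_report <- function(x, ...) x$rows

#' @rdname run_ora
#' @export
glance.ora_report <- function(x, ...) {
  tibble(N = x$N, R = x$R, n_pathways = nrow(x$rows),
         criterion = x$criterion)
}

#' @rdname run_ora
#' @param object An `ora_report`.
#' @param top Number of top-ranked pathways to show.
#' @export
autoplot.ora_report <- function(object, top = 15, ...) {
  rows <- head(object$rows[!is.na(object$rows$zscore), ], top)
  ggplot2::ggplot(rows, ggplot2::aes(
    x = .data$zscore,
    y = stats::reorder(.data$pathway, .data$zscore))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Z-score", y = NULL,
                  title = "Pathway over-representation",
                  subtitle = object$criterion) +
    ggplot2::theme_minimal()
}

#' Write / read a ranked ORA report
#'
#' The on-disk form is a TSV with header `pathway file total measured
#' positive zscore zscore_exact`: the Z-score column is formatted to two
#' decimals for display (undefined scores as `NA`), with the full-precision
#' value in the extra `zscore_exact` column so the report round-trips.
#'
#' @param report An `ora_report` from [run_ora()].
#' @param path Output file.
#' @return `write_ora_report()` returns `path` invisibly;
#'   `read_ora_report()` returns the report tibble with `zscore` restored to
#'   full precision.
#' @export
write_ora_report <- function(report, path) {
  rows <- report$rows
  lines <- c(
    "pathway\tfile\ttotal\tmeasured\tpositive\tzscore\tzscore_exact",
    sprintf("%s\t%s\t%d\t%d\t%d\t%s\t%s",
            rows$pathway, rows$file, rows$total, rows$measured, rows$positive,
            ifelse(is.na(rows$zscore), "NA", sprintf("%.2f", rows$zscore)),
            ifelse(is.na(rows$zscore), "NA", fmt_num(rows$zscore))))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ora_report
#' @export
read_ora_report <- function(path) {
  tab <- readr::read_tsv(path, col_types = "cciiidd", na = "NA",
                         progress = FALSE)
  tab$zscore <- tab$zscore_exact
  tab$zscore_exact <- NULL
  tab
}
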