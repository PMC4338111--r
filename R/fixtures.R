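#' Synthetic pathway collections with planted enrichment
#'
#' The fixture generator builds a complete, self-consistent analysis input:
#' a collection of pathways whose data nodes sample genes from a common
#' universe, a 1:1 cross-reference table between two synthetic identifier
#' systems ("SysA", used by the pathway nodes, and "SysB", used by the
#' dataset — so every match must go through the mapper), and a
#' log2FC/p-value dataset in which the genes of one optional "planted"
#' pathway meet the standard differential-expression criterion with high
#' probability while background genes rarely do.  Recovering the planted
#' pathway at rank one is the end-to-end check of the whole
#' over-representation pipeline.
#'
#' @param n_pathways Number of pathways in the collection.
#' @param genes_per_pathway Genes sampled (without replacement) per pathway.
#' @param gene_universe Size of the shared gene universe.
#' @param planted_index 1-based index of the enriched pathway, or `NULL`
#'   for a null collection with no enrichment.
#' @param positive_fraction_planted Probability that a planted-pathway gene
#'   is differentially expressed.
#' @param positive_fraction_background Same for all other genes.
#' @param seed Integer seed; all outputs are deterministic given the spec.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(n_pathways = 20, genes_per_pathway = 10,
                         gene_universe = 200, planted_index = NULL,
                         positive_fraction_planted = 0.9,
                         positive_fraction_background = 0.1,
                         seed = 7) {
  if (genes_per_pathway > gene_universe) {
    abort("`genes_per_pathway` cannot exceed `gene_universe`")
  }
  if (!is.null(planted_index) &&
      (planted_index < 1 || planted_index > n_pathways)) {
    abort("`planted_index` must be between 1 and `n_pathways`")
  }
  for (f in c(positive_fraction_planted, positive_fraction_background)) {
    if (f < 0 || f > 1) abort("positive fractions must be in [0, 1]")
  }
  structure(list(
    n_pathways = as.integer(n_pathways),
    genes_per_pathway = as.integer(genes_per_pathway),
    gene_universe = as.integer(gene_universe),
    planted_index = if (is.null(planted_index)) NULL else as.integer(planted_index),
    positive_fraction_planted = positive_fraction_planted,
    positive_fraction_background = positive_fraction_background,
    seed = as.integer(seed)),
    class = "fixture_spec")
}

gene_ids <- function(n) sprintf("G%06d", seq_len(n))

#' @rdname fixture_spec
#' @param spec A `fixture_spec`.
#' @return `generate_collection()` returns a list with `collection` (a
#'   [pathway_collection()]), `idmap` (the mapping table as TSV text) and
#'   `gene_sets` (the gene ids per pathway, for bookkeeping in tests).
#' @export
generate_collection <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  universe <- gene_ids(spec$gene_universe)
  pathways <- list(); files <- character(); gene_sets <- list()
  for (i in seq_len(spec$n_pathways)) {
    genes <- sample(universe, spec$genes_per_pathway)
    gene_sets[[i]] <- genes
    ncol_grid <- ceiling(sqrt(spec$genes_per_pathway))
    nodes <- lapply(seq_along(genes), function(j) {
      data_node(
        graph_id = sprintf("n%03d", j), text_label = genes[j],
        node_type = "GeneProduct",
        geometry = geometry(70 + ((j - 1) %% ncol_grid) * 100,
                            60 + ((j - 1) %/% ncol_grid) * 50, 80, 25),
        xref = xref("SysA", genes[j]))
    })
    edges <- lapply(seq_len(length(genes) - 1L), function(j) {
      a <- nodes[[j]]$geometry; b <- nodes[[j + 1L]]$geometry
      interaction(
        graph_id = sprintf("e%03d", j),
        waypoints = list(waypoint(a$center_x, a$center_y),
                         waypoint(b$center_x, b$center_y)),
        end_arrow = "Arrow")
    })
    pathways[[i]] <- pathway(
      name = sprintf("Synthetic pathway %02d", i), organism = "Synthetic",
      version = "1", data_nodes = nodes, interactions = edges)
    files <- c(files, sprintf("synthetic-%03d.gpml", i))
  }
  idmap <- paste(
    c("source_system\tsource_id\ttarget_system\ttarget_id",
      sprintf("SysA\t%s\tSysB\t%s", universe, universe)),
    collapse = "\n")
  list(collection = pathway_collection(pathways, files),
       idmap = idmap, gene_sets = gene_sets)
}

#' @rdname fixture_spec
#' @param collection The value of `generate_collection(spec)` (or its
#'   `$collection`).
#' @return `generate_dataset()` returns the data table as TSV text with
#'   columns `id` (SysB identifiers), `log2FC`, `pvalue`: one row per
#'   universe gene.  Differentially expressed genes draw
#'   `|log2FC| ~ U(1.5, 3)` with random sign and `pvalue ~ U(1e-4, 0.01)`;
#'   the rest draw `log2FC ~ U(-0.5, 0.5)` and `pvalue ~ U(0.2, 0.9)`.
#' @export
generate_dataset <- function(spec, collection) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.list(collection) && !inherits(collection, "pathway_collection")) {
    collection <- collection$collection
  }
  set.seed(spec$seed + 1L)
  universe <- gene_ids(spec$gene_universe)
  planted_genes <- if (!is.null(spec$planted_index)) {
    annotated_xrefs(collection$pathways[[spec$planted_index]])$identifier
  } else {
    character()
  }
  frac <- ifelse(universe %in% planted_genes,
                 spec$positive_fraction_planted,
                 spec$positive_fraction_background)
  u <- spec$gene_universe
  is_pos <- runif(u) < frac
  sgn <- sample(c(-1, 1), u, replace = TRUE)
  lfc_pos <- runif(u, 1.5, 3) * sgn
  p_pos <- runif(u, 1e-4, 0.01)
  lfc_neg <- runif(u, -0.5, 0.5)
  p_neg <- runif(u, 0.2, 0.9)
  lfc <- ifelse(is_pos, lfc_pos, lfc_neg)
  pv <- ifelse(is_pos, p_pos, p_neg)
  paste(c("id\tlog2FC\tpvalue",
          sprintf("%s\t%s\t%s", universe, fmt_num(lfc), fmt_num(pv))),
        collapse = "\n")
}

#' @rdname fixture_spec
#' @return `default_scheme()` returns the stock [viz_scheme()] used by the
#'   demo: a blue-white-red gradient over log2FC in -2..2 and three p-value
#'   bands (`< 0.01`, `< 0.05`, `>= 0.05`).
#' @export
default_scheme <- function() {
  viz_scheme(
    list(
      column_viz("log2FC", gradient = gradient_spec(
        c(-2, 0, 2), c("#0000FF", "#FFFFFF", "#FF0000"))),
      column_viz("pvalue", rules = list(
        color_rule("[pvalue] < 0.01", "#006400"),
        color_rule("[pvalue] < 0.05", "#66CC66"),
        color_rule("[pvalue] >= 0.05", "#DDDDDD")))),
    not_measured_color = "#C0C0C0", no_match_color = "#FFFFFF")
}

#' @rdname fixture_spec
#' @param dir Output directory; created if needed.
#' @return `write_fixtures()` writes `pathways/*.gpml`, `idmap.tsv`,
#'   `data.tsv` and `scheme.json` under `dir` and returns their paths
#'   invisibly.
#' @export
write_fixtures <- function(spec, dir) {
  gen <- generate_collection(spec)
  pw_dir <- file.path(dir, "pathways")
  dir.create(pw_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(gen$collection$pathways)) {
    write_gpml(gen$collection$pathways[[i]],
               file.path(pw_dir, gen$collection$files[i]))
  }
  idmap_path <- file.path(dir, "idmap.tsv")
  writeLines(gen$idmap, idmap_path)
  data_path <- file.path(dir, "data.tsv")
  writeLines(generate_dataset(spec, gen$collection), data_path)
  scheme_path <- file.path(dir, "scheme.json")
  write_scheme(default_scheme(), scheme_path)
  invisible(list(pathways = pw_dir, idmap = idmap_path, data = data_path,
                 scheme = scheme_path))
}

#' Random valid pathway (round-trip testing)
#'
#' Draws a structurally varied pathway — random node types and geometry,
#' optional xrefs, comments and literature references, interactions with
#' bends and arrowheads, graphical lines, labels, shapes and a group — for
#' exercising the GPML writer/reader round trip.  Deterministic under
#' `seed`.
#'
#' @param seed Integer seed.
#' @return A [pathway()] that passes [validate_pathway()].
#' @export
generate_random_pathway <- function(seed) {
  set.seed(seed)
  n_nodes <- sample(1:8, 1)
  nodes <- lapply(seq_len(n_nodes), function(j) {
    data_node(
      graph_id = sprintf("dn%02d", j),
      text_label = sprintf("Gene %d", j),
      node_type = sample(NODE_TYPES, 1),
      geometry = geometry(round(runif(1, 50, 600), 2), round(runif(1, 50, 400), 2),
                          round(runif(1, 40, 120), 2), round(runif(1, 15, 40), 2)),
      xref = if (runif(1) < 0.7) xref(sample(c("Entrez Gene", "Ensembl", "HMDB"), 1),
                                      as.character(sample(1:99999, 1))) else NULL,
      comments = if (runif(1) < 0.3) sprintf("comment %d", sample(1:9, 1)) else character(),
      literature_refs = if (runif(1) < 0.3) sprintf("ref%d", sample(1:9, 1)) else character())
  })
  n_edges <- sample(0:4, 1)
  edges <- lapply(seq_len(n_edges), function(j) {
    npts <- sample(2:4, 1)
    from <- sample(n_nodes, 1)
    wps <- lapply(seq_len(npts), function(k) {
      waypoint(round(runif(1, 0, 600), 2), round(runif(1, 0, 400), 2),
               anchor_ref = if (k == 1L && runif(1) < 0.5)
                 sprintf("dn%02d", from) else NA_character_)
    })
    interaction(
      graph_id = sprintf("ix%02d", j), waypoints = wps,
      start_arrow = sample(c("None", "Arrow", "TBar"), 1),
      end_arrow = sample(c("None", "Arrow", "TBar"), 1),
      graphical_line = runif(1) < 0.2)
  })
  labels <- if (runif(1) < 0.5) list(label_element(
    "lb01", "a label", geometry(300, 30, 120, 20))) else list()
  shapes <- if (runif(1) < 0.5) list(shape_element(
    "sh01", sample(SHAPE_TYPES, 1), geometry(300, 250, 400, 300))) else list()
  groups <- if (n_nodes >= 2 && runif(1) < 0.5) {
    list(group_element("gr01", members = sprintf("dn%02d", sample(n_nodes, 2))))
  } else {
    list()
  }
  pathway(
    name = sprintf("Random pathway %d", seed), organism = "Synthetic",
    version = "1", data_nodes = nodes, interactions = edges, labels = labels,
    shapes = shapes, groups = groups)
}
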