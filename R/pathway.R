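#' Pathway diagram object model
#'
#' A pathway diagram is a set of typed elements on a drawing board: data
#' nodes (genes, proteins, RNAs, metabolites, sub-pathways), interactions
#' between them, free-text labels, graphical shapes and groups.  Every
#' element carries a `graph_id` unique within the pathway; data nodes and
#' interactions may be annotated with an [xref()].  Coordinates are real
#' canvas units with the origin at the top-left and the y axis pointing
#' downward (the GPML and SVG convention).
#'
#' @name pathway-model
NULL

NODE_TYPES <- c("GeneProduct", "Protein", "Rna", "Metabolite", "Pathway", "Unknown")
SHAPE_TYPES <- c("Rectangle", "Oval", "RoundedRectangle", "Compartment")

#' Element geometry
#'
#' Center-based box geometry in canvas units; width and height must be
#' strictly positive.
#'
#' @param center_x,center_y Center of the element.
#' @param width,height Extent of the element; both `> 0`.
#' @return An object of class `geometry`.
#' @export
geometry <- function(center_x, center_y, width, height) {
  structure(list(center_x = as.numeric(center_x), center_y = as.numeric(center_y),
                 width = as.numeric(width), height = as.numeric(height)),
            class = "geometry")
}

new_element <- function(cls, fields) {
  structure(fields, class = c(cls, "pathway_element"))
}

#' Pathway elements
#'
#' Constructors for the element types of a [pathway()]: `data_node()` for
#' biological entities, `interaction()` for edges with an ordered list of
#' waypoints, `label_element()` for free text, `shape_element()` for
#' graphical shapes and compartments, and `group_element()` for grouping
#' other elements.
#'
#' @param graph_id Identifier unique within the pathway.
#' @param text_label Displayed text.
#' @param node_type One of `"GeneProduct"`, `"Protein"`, `"Rna"`,
#'   `"Metabolite"`, `"Pathway"`, `"Unknown"`.
#' @param geometry A [geometry()].
#' @param xref Optional [xref()] annotation (`NULL` when unannotated).
#' @param comments Character vector of free-text comments.
#' @param literature_refs Character vector of opaque literature reference
#'   keys.
#' @param extra_attrs,graphics_extra,extra_children Opaque stores for
#'   attributes and child elements read from a GPML document that this model
#'   does not interpret; they are re-emitted verbatim on write so that
#'   foreign documents round-trip.
#' @return An object of the respective element class.
#' @export
data_node <- function(graph_id, text_label, node_type = "GeneProduct",
                      geometry, xref = NULL,
                      comments = character(), literature_refs = character(),
                      extra_attrs = character(), graphics_extra = character(),
                      extra_children = character()) {
  if (!node_type %in% NODE_TYPES) {
    abort(sprintf("unknown data node type '%s'", node_type))
  }
  if (!is.null(xref) && !is_xref(xref)) abort("`xref` must be an xref or NULL")
  new_element("data_node", list(
    graph_id = graph_id, text_label = text_label, node_type = node_type,
    geometry = geometry, xref = xref, comments = comments,
    literature_refs = literature_refs, extra_attrs = extra_attrs,
    graphics_extra = graphics_extra, extra_children = extra_children))
}

#' @rdname data_node
#' @param x,y Waypoint coordinates (for `waypoint()`).
#' @param anchor_ref Optional `graph_id` (element or anchor) this waypoint
#'   attaches to.
#' @export
waypoint <- function(x, y, anchor_ref = NA_character_, extra = character()) {
  list(x = as.numeric(x), y = as.numeric(y),
       anchor_ref = as.character(anchor_ref), extra = extra)
}

#' @rdname data_node
#' @param waypoints List of [waypoint()]s, at least two: start, optional
#'   bends, end.
#' @param start_arrow,end_arrow Arrowhead names (`"None"`, `"Arrow"`,
#'   `"TBar"`, or any GPML arrowhead string, preserved verbatim).
#' @param anchors List of `list(graph_id =, position =)` anchors placed on
#'   the interaction line that other interactions can attach to.
#' @param graphical_line `TRUE` for a purely graphical line (GPML
#'   `GraphicalLine`), which never carries an xref.
#' @export
interaction <- function(graph_id, waypoints, start_arrow = "None",
                        end_arrow = "None", xref = NULL, anchors = list(),
                        graphical_line = FALSE,
                        comments = character(), literature_refs = character(),
                        extra_attrs = character(), graphics_extra = character(),
                        extra_children = character()) {
  if (length(waypoints) < 2L) abort("an interaction needs at least 2 waypoints")
  if (!is.null(xref) && !is_xref(xref)) abort("`xref` must be an xref or NULL")
  if (graphical_line && !is.null(xref)) {
    abort("a graphical line cannot carry an xref")
  }
  new_element("interaction", list(
    graph_id = graph_id, waypoints = waypoints, start_arrow = start_arrow,
    end_arrow = end_arrow, xref = xref, anchors = anchors,
    graphical_line = isTRUE(graphical_line), comments = comments,
    literature_refs = literature_refs, extra_attrs = extra_attrs,
    graphics_extra = graphics_extra, extra_children = extra_children))
}

#' @rdname data_node
#' @param text Label text.
#' @export
label_element <- function(graph_id, text, geometry,
                          extra_attrs = character(), graphics_extra = character(),
                          extra_children = character()) {
  new_element("label_element", list(
    graph_id = graph_id, text = text, geometry = geometry,
    extra_attrs = extra_attrs, graphics_extra = graphics_extra,
    extra_children = extra_children))
}

#' @rdname data_node
#' @param shape_type One of `"Rectangle"`, `"Oval"`, `"RoundedRectangle"`,
#'   `"Compartment"`.
#' @export
shape_element <- function(graph_id, shape_type, geometry,
                          extra_attrs = character(), graphics_extra = character(),
                          extra_children = character()) {
  if (!shape_type %in% SHAPE_TYPES) {
    abort(sprintf("unknown shape type '%s'", shape_type))
  }
  new_element("shape_element", list(
    graph_id = graph_id, shape_type = shape_type, geometry = geometry,
    extra_attrs = extra_attrs, graphics_extra = graphics_extra,
    extra_children = extra_children))
}

#' @rdname data_node
#' @param members Character vector of member `graph_id`s.
#' @param label Optional group label.
#' @export
group_element <- function(graph_id, members = character(), label = NULL,
                          extra_attrs = character()) {
  new_element("group_element", list(
    graph_id = graph_id, members = as.character(members), label = label,
    extra_attrs = extra_attrs))
}

#' Construct a pathway
#'
#' Assembles elements into a pathway diagram.  All `graph_id`s (including
#' interaction anchors) must be unique across the element lists.  When board
#' dimensions are omitted they are grown to the bounding box of all elements
#' plus a margin.  Group membership is normalized so that members are listed
#' in element order (data nodes, interactions, labels, shapes), which keeps
#' the model identical across a write/read cycle.
#'
#' @param name Pathway title.
#' @param organism,version Optional metadata strings.
#' @param board_width,board_height Drawing board size in canvas units.
#' @param data_nodes,interactions,labels,shapes,groups Lists of elements
#'   built with the element constructors.
#' @param extra_attrs,extra_children Opaque round-trip stores (see
#'   [data_node()]).
#' @return An object of class `pathway`.
#' @seealso [read_gpml()], [write_gpml()], [validate_pathway()]
#' @export
pathway <- function(name, organism = NULL, version = NULL,
                    board_width = NULL, board_height = NULL,
                    data_nodes = list(), interactions = list(),
                    labels = list(), shapes = list(), groups = list(),
                    extra_attrs = character(), extra_children = character()) {
  p <- structure(list(
    name = name, organism = organism, version = version,
    board_width = board_width, board_height = board_height,
    data_nodes = data_nodes, interactions = interactions,
    labels = labels, shapes = shapes, groups = groups,
    extra_attrs = extra_attrs, extra_children = extra_children),
    class = "pathway")
  bb <- pathway_bbox(p)
  if (is.null(board_width)) {
    p$board_width <- if (is.null(bb)) 100 else bb[["x_max"]] + 20
  }
  if (is.null(board_height)) {
    p$board_height <- if (is.null(bb)) 100 else bb[["y_max"]] + 20
  }
  p$board_width <- as.numeric(p$board_width)
  p$board_height <- as.numeric(p$board_height)
  normalize_groups(p)
}

# Elements in canonical write order (groups excluded: they have no geometry
# of their own).
pathway_elements <- function(p) {
  c(p$data_nodes, p$interactions, p$labels, p$shapes)
}

pathway_bbox <- function(p) {
  xs <- numeric(); ys <- numeric()
  for (el in pathway_elements(p)) {
    if (!is.null(el$geometry)) {
      g <- el$geometry
      xs <- c(xs, g$center_x - g$width / 2, g$center_x + g$width / 2)
      ys <- c(ys, g$center_y - g$height / 2, g$center_y + g$height / 2)
    } else if (!is.null(el$waypoints)) {
      xs <- c(xs, vapply(el$waypoints, `[[`, numeric(1), "x"))
      ys <- c(ys, vapply(el$waypoints, `[[`, numeric(1), "y"))
    }
  }
  if (!length(xs)) return(NULL)
  c(x_min = min(xs), y_min = min(ys), x_max = max(xs), y_max = max(ys))
}

# All graph_ids defined in a pathway, including interaction anchors and
# group ids.
all_graph_ids <- function(p) {
  ids <- c(
    vapply(pathway_elements(p), `[[`, character(1), "graph_id"),
    vapply(p$groups, `[[`, character(1), "graph_id"))
  anchor_ids <- unlist(lapply(p$interactions, function(i) {
    vapply(i$anchors, `[[`, character(1), "graph_id")
  }))
  c(ids, anchor_ids)
}

# Reorder each group's member list to element order so that the in-memory
# model is invariant under GPML serialization (membership is stored as a
# GroupRef attribute on the members, whose order on re-read is document
# order).
normalize_groups <- function(p) {
  if (!length(p$groups)) return(p)
  ord <- vapply(pathway_elements(p), `[[`, character(1), "graph_id")
  p$groups <- lapply(p$groups, function(g) {
    g$members <- g$members[order(match(g$members, ord))]
    g
  })
  p
}

#' @export
print.pathway <- function(x, ...) {
  cat(sprintf("<pathway> %s%s\n", x$name,
              if (!is.null(x$organism)) paste0(" (", x$organism, ")") else ""))
  cat(sprintf("  board %g x %g\n", x$board_width, x$board_height))
  cat(sprintf("  %d data nodes, %d interactions, %d labels, %d shapes, %d groups\n",
              length(x$data_nodes), length(x$interactions), length(x$labels),
              length(x$shapes), length(x$groups)))
  invisible(x)
}

#' Element counts of a pathway
#'
#' @param p A [pathway()].
#' @return A one-row tibble with counts per element class and the number of
#'   distinct annotated xrefs.
#' @export
pathway_summary <- function(p) {
  tibble(
    name = p$name,
    data_nodes = length(p$data_nodes),
    interactions = length(p$interactions),
    labels = length(p$labels),
    shapes = length(p$shapes),
    groups = length(p$groups),
    annotated_xrefs = nrow(annotated_xrefs(p)))
}

#' Distinct xrefs annotated on a pathway's data nodes
#'
#' Collects the set of distinct (datasource, identifier) annotations carried
#' by data nodes of the selected types.  Duplicate annotations (the same
#' gene drawn twice) collapse to one entry; unannotated nodes are excluded.
#' This set is the per-pathway universe that over-representation analysis
#' counts ("total").
#'
#' @param p A [pathway()].
#' @param types Character vector of node types to include (default: all).
#' @return A tibble with columns `datasource`, `identifier`, one row per
#'   distinct xref, in first-appearance order.
#' @export
annotated_xrefs <- function(p, types = NODE_TYPES) {
  ds <- character(); id <- character()
  for (n in p$data_nodes) {
    if (n$node_type %in% types && !is.null(n$xref)) {
      ds <- c(ds, n$xref$datasource); id <- c(id, n$xref$identifier)
    }
  }
  keep <- !duplicated(xref_key(ds, id))
  tibble(datasource = ds[keep], identifier = id[keep])
}

#' Data node listing
#'
#' Tabulates every data node of a pathway with its annotation; the on-disk
#' form (see [write_datanode_list()]) is the classic "datanode list" export.
#'
#' @param p A [pathway()].
#' @return A tibble with columns `text_label`, `node_type`, `datasource`,
#'   `identifier` (the last two `NA` for unannotated nodes).
#' @export
datanode_table <- function(p) {
  tibble(
    text_label = vapply(p$data_nodes, `[[`, character(1), "text_label"),
    node_type = vapply(p$data_nodes, `[[`, character(1), "node_type"),
    datasource = vapply(p$data_nodes, function(n)
      if (is.null(n$xref)) NA_character_ else n$xref$datasource, character(1)),
    identifier = vapply(p$data_nodes, function(n)
      if (is.null(n$xref)) NA_character_ else n$xref$identifier, character(1)))
}

#' @rdname datanode_table
#' @param path Output file path (tab-separated, with header).
#' @export
write_datanode_list <- function(p, path) {
  readr::write_tsv(datanode_table(p), path, na = "")
  invisible(path)
}
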