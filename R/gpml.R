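GPML_NS_2013 <- "http://pathvisio.org/GPML/2013a"
GPML_NS_2010 <- "http://genmapp.org/GPML/2010a"

# Attributes this model interprets, per element; anything else is carried
# verbatim in the element's opaque attribute store and re-emitted on write.
KNOWN_ATTRS <- list(
  Pathway = c("Name", "Organism", "Version"),
  DataNode = c("TextLabel", "GraphId", "Type", "GroupRef"),
  Interaction = c("GraphId", "GroupRef"),
  Label = c("TextLabel", "GraphId", "GroupRef"),
  Shape = c("GraphId", "GroupRef"),
  Group = c("GroupId", "TextLabel"),
  Point = c("X", "Y", "GraphRef", "ArrowHead"),
  Anchor = c("Position", "GraphId"),
  GraphicsBox = c("CenterX", "CenterY", "Width", "Height"),
  GraphicsShape = c("CenterX", "CenterY", "Width", "Height", "ShapeType"))

extra_attrs_of <- function(node, known) {
  at <- xml2::xml_attrs(node)
  at <- at[setdiff(names(at), known)]
  if (!length(at)) character() else at
}

#' Read a GPML pathway document
#'
#' Parses a pathway diagram in the GPML (Graphical Pathway Markup Language)
#' XML format into a [pathway()] object.  The 2013a dialect is the native
#' one; documents in the older 2010a namespace are accepted and normalized
#' to the same model.  Recognized elements (data nodes, interactions,
#' graphical lines, labels, shapes, groups) are materialized; everything
#' else — including unrecognized attributes — is preserved verbatim in
#' opaque side-stores so that [write_gpml()] round-trips foreign documents.
#'
#' @param x Path to a `.gpml` file, or a string containing a GPML document.
#' @return A [pathway()].
#' @examples
#' p <- pathway("demo", data_nodes = list(
#'   data_node("n1", "KNG1", "GeneProduct", geometry(60, 40, 80, 20),
#'             xref = xref("Entrez Gene", "3827"))))
#' p2 <- read_gpml(write_gpml(p))
#' identical(p, p2)
#' @export
read_gpml <- function(x) {
  doc <- tryCatch(xml2::read_xml(x), error = function(e) {
    # libxml reports the line for structural errors; pass it through
    abort(sprintf("malformed XML: %s", conditionMessage(e)))
  })
  root <- xml2::xml_root(doc)
  ns <- tryCatch(xml2::xml_ns(doc), error = function(e) character())
  uri <- if ("d1" %in% names(ns)) ns[["d1"]] else ""
  if (!uri %in% c(GPML_NS_2013, GPML_NS_2010)) {
    abort(sprintf("unsupported GPML dialect: namespace '%s' is not recognized", uri))
  }
  if (xml2::xml_name(root) != "Pathway") {
    abort("not a GPML document: root element is not <Pathway>")
  }
  xml2::xml_ns_strip(doc)

  auto_counter <- 0L
  need_id <- function(node) {
    id <- xml2::xml_attr(node, "GraphId")
    if (is.na(id)) {
      auto_counter <<- auto_counter + 1L
      id <- sprintf("auto%d", auto_counter)
    }
    id
  }

  group_of <- character()   # member graph_id -> group id, in document order
  note_group <- function(node, id) {
    gr <- xml2::xml_attr(node, "GroupRef")
    if (!is.na(gr)) group_of[[id]] <<- gr
  }

  parse_box_graphics <- function(node, known) {
    g <- xml2::xml_find_first(node, "./Graphics")
    if (inherits(g, "xml_missing")) {
      abort(sprintf("element '%s' has no Graphics child",
                    xml2::xml_attr(node, "GraphId")))
    }
    list(geom = geometry(as.numeric(xml2::xml_attr(g, "CenterX")),
                         as.numeric(xml2::xml_attr(g, "CenterY")),
                         as.numeric(xml2::xml_attr(g, "Width")),
                         as.numeric(xml2::xml_attr(g, "Height"))),
         extra = extra_attrs_of(g, known),
         node = g)
  }

  parse_notes <- function(node) {
    comments <- character(); litrefs <- character(); extra_children <- character()
    for (ch in xml2::xml_children(node)) {
      nm <- xml2::xml_name(ch)
      if (nm == "Comment" && !length(xml2::xml_attrs(ch))) {
        comments <- c(comments, xml2::xml_text(ch))
      } else if (nm == "BiopaxRef") {
        litrefs <- c(litrefs, xml2::xml_text(ch))
      } else if (!nm %in% c("Graphics", "Xref")) {
        extra_children <- c(extra_children, as.character(ch))
      }
    }
    list(comments = comments, literature_refs = litrefs,
         extra_children = extra_children)
  }

  parse_xref <- function(node) {
    xr <- xml2::xml_find_first(node, "./Xref")
    if (inherits(xr, "xml_missing")) return(NULL)
    db <- xml2::xml_attr(xr, "Database"); id <- xml2::xml_attr(xr, "ID")
    if (is.na(db) || is.na(id) || !nzchar(db) || !nzchar(id)) return(NULL)
    xref(db, id)
  }

  data_nodes <- list(); interactions <- list(); labels <- list()
  shapes <- list(); groups <- list()
  board_width <- 100; board_height <- 100
  pw_extra_children <- character()

  for (ch in xml2::xml_children(root)) {
    nm <- xml2::xml_name(ch)
    if (nm == "Graphics") {
      board_width <- as.numeric(xml2::xml_attr(ch, "BoardWidth"))
      board_height <- as.numeric(xml2::xml_attr(ch, "BoardHeight"))
    } else if (nm == "DataNode") {
      id <- need_id(ch); note_group(ch, id)
      type <- xml2::xml_attr(ch, "Type")
      extra <- extra_attrs_of(ch, KNOWN_ATTRS$DataNode)
      if (is.na(type)) type <- "Unknown"
      if (!type %in% NODE_TYPES) {
        extra <- c(extra, c(Type = type))  # keep foreign type verbatim
        type <- "Unknown"
      }
      gfx <- parse_box_graphics(ch, KNOWN_ATTRS$GraphicsBox)
      notes <- parse_notes(ch)
      data_nodes[[length(data_nodes) + 1L]] <- data_node(
        graph_id = id,
        text_label = xml2::xml_attr(ch, "TextLabel") %|na|% "",
        node_type = type, geometry = gfx$geom, xref = parse_xref(ch),
        comments = notes$comments, literature_refs = notes$literature_refs,
        extra_attrs = extra, graphics_extra = gfx$extra,
        extra_children = notes$extra_children)
    } else if (nm %in% c("Interaction", "GraphicalLine")) {
      id <- need_id(ch); note_group(ch, id)
      g <- xml2::xml_find_first(ch, "./Graphics")
      pts <- xml2::xml_find_all(g, "./Point")
      if (length(pts) < 2L) {
        abort(sprintf("interaction '%s' has fewer than 2 points", id))
      }
      wps <- lapply(pts, function(pt) waypoint(
        as.numeric(xml2::xml_attr(pt, "X")),
        as.numeric(xml2::xml_attr(pt, "Y")),
        xml2::xml_attr(pt, "GraphRef"),
        extra = extra_attrs_of(pt, KNOWN_ATTRS$Point)))
      arrow_of <- function(pt) xml2::xml_attr(pt, "ArrowHead") %|na|% "None"
      anchors <- lapply(xml2::xml_find_all(g, "./Anchor"), function(a) {
        list(graph_id = need_id(a),
             position = as.numeric(xml2::xml_attr(a, "Position")),
             extra = extra_attrs_of(a, KNOWN_ATTRS$Anchor))
      })
      notes <- parse_notes(ch)
      interactions[[length(interactions) + 1L]] <- interaction(
        graph_id = id, waypoints = wps,
        start_arrow = arrow_of(pts[[1]]), end_arrow = arrow_of(pts[[length(pts)]]),
        xref = if (nm == "Interaction") parse_xref(ch) else NULL,
        anchors = anchors, graphical_line = nm == "GraphicalLine",
        comments = notes$comments, literature_refs = notes$literature_refs,
        extra_attrs = extra_attrs_of(ch, KNOWN_ATTRS$Interaction),
        graphics_extra = extra_attrs_of(g, character()),
        extra_children = notes$extra_children)
    } else if (nm == "Label") {
      id <- need_id(ch); note_group(ch, id)
      gfx <- parse_box_graphics(ch, KNOWN_ATTRS$GraphicsBox)
      notes <- parse_notes(ch)
      labels[[length(labels) + 1L]] <- label_element(
        graph_id = id, text = xml2::xml_attr(ch, "TextLabel") %|na|% "",
        geometry = gfx$geom,
        extra_attrs = extra_attrs_of(ch, KNOWN_ATTRS$Label),
        graphics_extra = gfx$extra, extra_children = notes$extra_children)
    } else if (nm == "Shape") {
      id <- need_id(ch); note_group(ch, id)
      gfx <- parse_box_graphics(ch, KNOWN_ATTRS$GraphicsShape)
      st <- xml2::xml_attr(gfx$node, "ShapeType")
      gextra <- gfx$extra
      if (is.na(st)) st <- "Rectangle"
      if (!st %in% SHAPE_TYPES) {
        gextra <- c(gextra, c(ShapeType = st))
        st <- "Rectangle"
      }
      notes <- parse_notes(ch)
      shapes[[length(shapes) + 1L]] <- shape_element(
        graph_id = id, shape_type = st, geometry = gfx$geom,
        extra_attrs = extra_attrs_of(ch, KNOWN_ATTRS$Shape),
        graphics_extra = gextra, extra_children = notes$extra_children)
    } else if (nm == "Group") {
      gid <- xml2::xml_attr(ch, "GroupId")
      if (is.na(gid)) {
        auto_counter <- auto_counter + 1L
        gid <- sprintf("auto%d", auto_counter)
      }
      lbl <- xml2::xml_attr(ch, "TextLabel")
      groups[[length(groups) + 1L]] <- group_element(
        graph_id = gid, members = character(),
        label = if (is.na(lbl)) NULL else lbl,
        extra_attrs = extra_attrs_of(ch, KNOWN_ATTRS$Group))
    } else {
      pw_extra_children <- c(pw_extra_children, as.character(ch))
    }
  }

  # attach collected GroupRef memberships
  groups <- lapply(groups, function(g) {
    g$members <- names(group_of)[group_of == g$graph_id]
    if (!length(g$members)) g$members <- character()
    g
  })

  org <- xml2::xml_attr(root, "Organism")
  ver <- xml2::xml_attr(root, "Version")
  p <- pathway(
    name = xml2::xml_attr(root, "Name") %|na|% "",
    organism = if (is.na(org)) NULL else org,
    version = if (is.na(ver)) NULL else ver,
    board_width = board_width, board_height = board_height,
    data_nodes = data_nodes, interactions = interactions, labels = labels,
    shapes = shapes, groups = groups,
    extra_attrs = extra_attrs_of(root, KNOWN_ATTRS$Pathway),
    extra_children = pw_extra_children)

  ids <- all_graph_ids(p)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(sprintf("duplicate graph id(s): %s", paste(dup, collapse = ", ")))
  }
  p
}

`%|na|%` <- function(x, y) if (length(x) != 1L || is.na(x)) y else x

attr_str <- function(...) {
  at <- c(...)
  if (!length(at)) return("")
  paste0(" ", paste0(names(at), "=\"", xml_escape(unname(at)), "\"",
                     collapse = " "))
}

indent <- function(lines, by = "  ") {
  if (!length(lines)) return(character())
  paste0(by, unlist(strsplit(lines, "\n", fixed = TRUE)))
}

notes_lines <- function(el) {
  c(sprintf("<Comment>%s</Comment>", xml_escape(el$comments)),
    sprintf("<BiopaxRef>%s</BiopaxRef>", xml_escape(el$literature_refs)))
}

xref_line <- function(xr) {
  if (is.null(xr)) {
    "<Xref Database=\"\" ID=\"\" />"
  } else {
    sprintf("<Xref Database=\"%s\" ID=\"%s\" />",
            xml_escape(xr$datasource), xml_escape(xr$identifier))
  }
}

box_graphics_line <- function(geom, extra, shape_type = NULL) {
  at <- c(CenterX = fmt_num(geom$center_x), CenterY = fmt_num(geom$center_y),
          Width = fmt_num(geom$width), Height = fmt_num(geom$height))
  if (!is.null(shape_type)) at <- c(at, ShapeType = shape_type)
  paste0("<Graphics", attr_str(at, extra), " />")
}

#' Write a pathway as GPML
#'
#' Serializes a [pathway()] to the GPML 2013a dialect.  Output is fully
#' deterministic: element classes are written in a fixed order (data nodes,
#' interactions, labels, shapes, groups), input order is preserved within
#' each class, and reals use the shortest decimal representation that parses
#' back to the identical value — so writing the same model twice yields
#' byte-identical documents and `read_gpml(write_gpml(p))` equals `p`.
#' Invariants are checked first via [validate_pathway()]; any error-level
#' issue aborts before output.
#'
#' @param p A [pathway()].
#' @param path Optional output file; when `NULL` the document is returned as
#'   a string.
#' @return The GPML document text (invisibly when `path` is given).
#' @export
write_gpml <- function(p, path = NULL) {
  issues <- validate_pathway(p)
  bad <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(bad)) {
    abort(paste0("pathway fails validation:\n",
                 paste0("- ", bad$message, collapse = "\n")))
  }

  group_of <- character()
  for (g in p$groups) for (m in g$members) group_of[[m]] <- g$graph_id
  gref <- function(id) {
    if (id %in% names(group_of)) c(GroupRef = group_of[[id]]) else character()
  }

  body <- c(
    paste0("<Graphics", attr_str(c(BoardWidth = fmt_num(p$board_width),
                                   BoardHeight = fmt_num(p$board_height))), " />"))

  for (n in p$data_nodes) {
    open <- paste0("<DataNode", attr_str(
      c(TextLabel = n$text_label, GraphId = n$graph_id, Type = n$node_type),
      gref(n$graph_id), n$extra_attrs), ">")
    body <- c(body, open,
              indent(c(notes_lines(n),
                       box_graphics_line(n$geometry, n$graphics_extra),
                       xref_line(n$xref), n$extra_children)),
              "</DataNode>")
  }
  for (i in p$interactions) {
    tag <- if (i$graphical_line) "GraphicalLine" else "Interaction"
    open <- paste0("<", tag, attr_str(c(GraphId = i$graph_id),
                                      gref(i$graph_id), i$extra_attrs), ">")
    np <- length(i$waypoints)
    pt_lines <- vapply(seq_len(np), function(k) {
      w <- i$waypoints[[k]]
      at <- c(X = fmt_num(w$x), Y = fmt_num(w$y))
      if (!is.na(w$anchor_ref)) at <- c(at, GraphRef = w$anchor_ref)
      if (k == 1L && i$start_arrow != "None") at <- c(at, ArrowHead = i$start_arrow)
      if (k == np && i$end_arrow != "None") at <- c(at, ArrowHead = i$end_arrow)
      paste0("<Point", attr_str(at, w$extra), " />")
    }, character(1))
    anchor_lines <- vapply(i$anchors, function(a) {
      paste0("<Anchor", attr_str(c(Position = fmt_num(a$position),
                                   GraphId = a$graph_id), a$extra), " />")
    }, character(1))
    gfx <- c(paste0("<Graphics", attr_str(i$graphics_extra), ">"),
             indent(c(pt_lines, anchor_lines)), "</Graphics>")
    inner <- c(notes_lines(i), gfx)
    if (!i$graphical_line) inner <- c(inner, xref_line(i$xref))
    body <- c(body, open, indent(c(inner, i$extra_children)),
              paste0("</", tag, ">"))
  }
  for (l in p$labels) {
    open <- paste0("<Label", attr_str(c(TextLabel = l$text, GraphId = l$graph_id),
                                      gref(l$graph_id), l$extra_attrs), ">")
    body <- c(body, open,
              indent(c(box_graphics_line(l$geometry, l$graphics_extra),
                       l$extra_children)),
              "</Label>")
  }
  for (s in p$shapes) {
    open <- paste0("<Shape", attr_str(c(GraphId = s$graph_id),
                                      gref(s$graph_id), s$extra_attrs), ">")
    body <- c(body, open,
              indent(c(box_graphics_line(s$geometry, s$graphics_extra,
                                         shape_type = s$shape_type),
                       s$extra_children)),
              "</Shape>")
  }
  for (g in p$groups) {
    at <- c(GroupId = g$graph_id)
    if (!is.null(g$label)) at <- c(at, TextLabel = g$label)
    body <- c(body, paste0("<Group", attr_str(at, g$extra_attrs), " />"))
  }
  body <- c(body, p$extra_children)

  root_at <- c(xmlns = GPML_NS_2013, Name = p$name)
  if (!is.null(p$organism)) root_at <- c(root_at, Organism = p$organism)
  if (!is.null(p$version)) root_at <- c(root_at, Version = p$version)
  root_at <- c(root_at, p$extra_attrs)

  txt <- paste0(paste(c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<Pathway", attr_str(root_at), ">"),
    indent(body),
    "</Pathway>"), collapse = "\n"), "\n")

  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}
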