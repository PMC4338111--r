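#' Render a pathway as SVG
#'
#' Draws the diagram: data nodes as outlined rectangles with their centered
#' text label, interactions as polylines with arrowhead or T-bar markers,
#' labels as text, shapes as rectangles/ellipses and groups as dashed
#' bounding boxes.  Every element becomes one `<g>` carrying its `graph_id`
#' as the SVG element id (data node groups additionally carry
#' `class="data-node"`).  When a scheme, dataset and mapper are supplied,
#' each data node's box is tiled with its [node_cells()] grid: scheme
#' columns split the width left to right, data rows split the height top to
#' bottom.  The canvas equals the drawing board, and identical inputs
#' always produce byte-identical output.
#'
#' Text is centered, never scaled to fit; overflow is clipped to the node
#' rectangle (deterministic without font metrics).
#'
#' @param p A [pathway()] (validated first; error-level issues abort).
#' @param scheme Optional [viz_scheme()].
#' @param dataset,mapper Dataset and mapper used to look up each node's
#'   rows; required when `scheme` is given.
#' @param path Optional output file.
#' @return The SVG document text (invisibly when `path` is given).
#' @export
render_svg <- function(p, scheme = NULL, dataset = NULL, mapper = NULL,
                       path = NULL) {
  issues <- validate_pathway(p)
  bad <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(bad)) {
    abort(paste0("pathway fails validation:\n",
                 paste0("- ", bad$message, collapse = "\n")))
  }
  if (!is.null(scheme) && is.null(dataset)) {
    abort("`dataset` is required when a scheme is supplied")
  }

  w <- fmt_num(p$board_width); h <- fmt_num(p$board_height)
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%s\"",
                   " height=\"%s\" viewBox=\"0 0 %s %s\""),
            w, h, w, h),
    "  font-family=\"sans-serif\" font-size=\"10\">",
    "<defs>",
    paste0("<marker id=\"arrow\" viewBox=\"0 0 10 10\" refX=\"9\" refY=\"5\"",
           " markerWidth=\"8\" markerHeight=\"8\" orient=\"auto-start-reverse\">",
           "<path d=\"M 0 0 L 10 5 L 0 10 z\" fill=\"black\" /></marker>"),
    paste0("<marker id=\"tbar\" viewBox=\"0 0 10 10\" refX=\"5\" refY=\"5\"",
           " markerWidth=\"8\" markerHeight=\"8\" orient=\"auto-start-reverse\">",
           "<path d=\"M 5 0 L 5 10\" stroke=\"black\" stroke-width=\"2\" /></marker>"),
    "</defs>",
    sprintf("<rect x=\"0\" y=\"0\" width=\"%s\" height=\"%s\" fill=\"white\" />",
            w, h))

  rect4 <- function(g) {
    c(x = fmt_num(g$center_x - g$width / 2), y = fmt_num(g$center_y - g$height / 2),
      w = fmt_num(g$width), h = fmt_num(g$height))
  }

  # groups first, as background boxes
  geom_of <- list()
  for (el in pathway_elements(p)) geom_of[[el$graph_id]] <- el
  for (g in p$groups) {
    xs <- numeric(); ys <- numeric()
    for (mid in g$members) {
      el <- geom_of[[mid]]
      if (is.null(el)) next
      if (!is.null(el$geometry)) {
        gg <- el$geometry
        xs <- c(xs, gg$center_x - gg$width / 2, gg$center_x + gg$width / 2)
        ys <- c(ys, gg$center_y - gg$height / 2, gg$center_y + gg$height / 2)
      } else if (!is.null(el$waypoints)) {
        xs <- c(xs, vapply(el$waypoints, `[[`, numeric(1), "x"))
        ys <- c(ys, vapply(el$waypoints, `[[`, numeric(1), "y"))
      }
    }
    if (!length(xs)) next
    out <- c(out, sprintf("<g id=\"%s\" class=\"group\">", xml_escape(g$graph_id)),
             sprintf(paste0("  <rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\"",
                            " fill=\"none\" stroke=\"#808080\"",
                            " stroke-dasharray=\"4 2\" />"),
                     fmt_num(min(xs) - 4), fmt_num(min(ys) - 4),
                     fmt_num(diff(range(xs)) + 8), fmt_num(diff(range(ys)) + 8)),
             "</g>")
  }

  # shapes behind nodes
  for (s in p$shapes) {
    r <- rect4(s$geometry)
    body <- switch(s$shape_type,
      Oval = sprintf(paste0("  <ellipse cx=\"%s\" cy=\"%s\" rx=\"%s\" ry=\"%s\"",
                            " fill=\"none\" stroke=\"black\" />"),
                     fmt_num(s$geometry$center_x), fmt_num(s$geometry$center_y),
                     fmt_num(s$geometry$width / 2), fmt_num(s$geometry$height / 2)),
      RoundedRectangle = sprintf(paste0("  <rect x=\"%s\" y=\"%s\" width=\"%s\"",
                                        " height=\"%s\" rx=\"10\" fill=\"none\"",
                                        " stroke=\"black\" />"),
                                 r["x"], r["y"], r["w"], r["h"]),
      Compartment = sprintf(paste0("  <rect x=\"%s\" y=\"%s\" width=\"%s\"",
                                   " height=\"%s\" rx=\"20\" fill=\"none\"",
                                   " stroke=\"#808080\" stroke-width=\"3\" />"),
                            r["x"], r["y"], r["w"], r["h"]),
      sprintf(paste0("  <rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\"",
                     " fill=\"none\" stroke=\"black\" />"),
              r["x"], r["y"], r["w"], r["h"]))
    out <- c(out, sprintf("<g id=\"%s\" class=\"shape\">", xml_escape(s$graph_id)),
             body, "</g>")
  }

  # interactions under the nodes
  marker_url <- function(arrow, which) {
    m <- switch(arrow, Arrow = "arrow", TBar = "tbar", NULL)
    if (is.null(m)) "" else sprintf(" marker-%s=\"url(#%s)\"", which, m)
  }
  for (i in p$interactions) {
    pts <- paste(vapply(i$waypoints, function(wp) {
      paste0(fmt_num(wp$x), ",", fmt_num(wp$y))
    }, character(1)), collapse = " ")
    out <- c(out,
      sprintf("<g id=\"%s\" class=\"interaction\">", xml_escape(i$graph_id)),
      sprintf("  <polyline points=\"%s\" fill=\"none\" stroke=\"black\"%s%s />",
              pts, marker_url(i$start_arrow, "start"),
              marker_url(i$end_arrow, "end")),
      "</g>")
  }

  # data nodes on top
  for (nd in p$data_nodes) {
    g <- nd$geometry
    r <- rect4(g)
    gid <- xml_escape(nd$graph_id)
    out <- c(out, sprintf("<g id=\"%s\" class=\"data-node\">", gid))
    if (!is.null(scheme)) {
      rows <- if (is.null(nd$xref)) {
        dataset$data[0, , drop = FALSE]
      } else {
        rows_for_xref(dataset, mapper, nd$xref)
      }
      cells <- node_cells(scheme, rows)
      nr <- nrow(cells); nc <- ncol(cells)
      x0 <- g$center_x - g$width / 2; y0 <- g$center_y - g$height / 2
      cw <- g$width / nc; ch <- g$height / nr
      for (ri in seq_len(nr)) for (ci in seq_len(nc)) {
        out <- c(out, sprintf(
          "  <rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\" class=\"cell\" />",
          fmt_num(x0 + (ci - 1) * cw), fmt_num(y0 + (ri - 1) * ch),
          fmt_num(cw), fmt_num(ch), cells[ri, ci]))
      }
    }
    out <- c(out,
      sprintf("  <clipPath id=\"clip-%s\"><rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" /></clipPath>",
              gid, r["x"], r["y"], r["w"], r["h"]),
      sprintf("  <rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\" stroke=\"black\" class=\"outline\" />",
              r["x"], r["y"], r["w"], r["h"],
              if (is.null(scheme)) "white" else "none"),
      sprintf(paste0("  <text x=\"%s\" y=\"%s\" text-anchor=\"middle\"",
                     " dominant-baseline=\"central\" clip-path=\"url(#clip-%s)\">%s</text>"),
              fmt_num(g$center_x), fmt_num(g$center_y), gid,
              xml_escape(nd$text_label)),
      "</g>")
  }

  # free labels
  for (l in p$labels) {
    out <- c(out,
      sprintf("<g id=\"%s\" class=\"label\">", xml_escape(l$graph_id)),
      sprintf(paste0("  <text x=\"%s\" y=\"%s\" text-anchor=\"middle\"",
                     " dominant-baseline=\"central\">%s</text>"),
              fmt_num(l$geometry$center_x), fmt_num(l$geometry$center_y),
              xml_escape(l$text)),
      "</g>")
  }

  out <- c(out, "</svg>")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}

#' Rasterize an SVG rendering to PNG
#'
#' Paints the rectangles and polylines of an SVG produced by
#' [render_svg()] onto a pixel array and writes it with the \pkg{png}
#' package.  This covers the geometry this package emits (node boxes, cell
#' fills, interaction lines, backgrounds); text is not rasterized.  The
#' raster is `round(board width * scale)` by `round(board height * scale)`
#' pixels.
#'
#' @param svg SVG document text (e.g. from [render_svg()]).
#' @param path Output PNG file.
#' @param scale Pixels per canvas unit.
#' @return `path`, invisibly.
#' @export
export_png <- function(svg, path, scale = 1) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("PNG export needs the 'png' package; the SVG output remains available")
  }
  doc <- xml2::read_xml(svg)   # malformed SVG errors here, before any output
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_root(doc)
  w <- round_half_up(as.numeric(xml2::xml_attr(root, "width")) * scale)
  h <- round_half_up(as.numeric(xml2::xml_attr(root, "height")) * scale)
  img <- array(1, dim = c(h, w, 3))

  fill_px <- function(x0, y0, x1, y1, rgb) {
    xlo <- max(1, floor(x0 * scale) + 1); xhi <- min(w, ceiling(x1 * scale))
    ylo <- max(1, floor(y0 * scale) + 1); yhi <- min(h, ceiling(y1 * scale))
    if (xlo > xhi || ylo > yhi) return(invisible())
    for (ch in 1:3) img[ylo:yhi, xlo:xhi, ch] <<- rgb[ch] / 255
  }

  rects <- xml2::xml_find_all(doc,
    ".//rect[not(ancestor::defs) and not(ancestor::clipPath)]")
  for (rc in rects) {
    fill <- xml2::xml_attr(rc, "fill")
    if (is.na(fill) || fill == "none") next
    rgb <- if (fill == "white") c(255, 255, 255) else parse_color(fill)
    x <- as.numeric(xml2::xml_attr(rc, "x"))
    y <- as.numeric(xml2::xml_attr(rc, "y"))
    rw <- as.numeric(xml2::xml_attr(rc, "width"))
    rh <- as.numeric(xml2::xml_attr(rc, "height"))
    fill_px(x, y, x + rw, y + rh, rgb)
  }
  for (pl in xml2::xml_find_all(doc, ".//polyline")) {
    pts <- strsplit(strsplit(xml2::xml_attr(pl, "points"), " ", fixed = TRUE)[[1]],
                    ",", fixed = TRUE)
    for (k in seq_len(length(pts) - 1L)) {
      a <- as.numeric(pts[[k]]); b <- as.numeric(pts[[k + 1L]])
      steps <- max(2L, ceiling(max(abs(b - a)) * scale) * 2L)
      t <- seq(0, 1, length.out = steps)
      px <- pmin(pmax(floor((a[1] + (b[1] - a[1]) * t) * scale) + 1L, 1L), w)
      py <- pmin(pmax(floor((a[2] + (b[2] - a[2]) * t) * scale) + 1L, 1L), h)
      for (ch in 1:3) img[cbind(py, px, ch)] <- 0
    }
  }
  png::writePNG(img, path)
  invisible(path)
}
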