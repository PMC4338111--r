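#' Colors, gradients and color rules
#'
#' Colors are `"#RRGGBB"` strings.  A gradient maps a numeric measurement
#' (e.g. a log2 fold change) to a color by channel-wise linear
#' interpolation between 2 or 3 anchors, e.g. blue at -2 over white at 0 to
#' red at +2; values outside the anchor range clamp to the nearest end
#' color.  Channels interpolate in plain integer-rounded RGB (half-up
#' rounding, no gamma correction), so expected colors in tests are exact.
#' A color rule paints a fixed color when its criterion evaluates exactly
#' true for the row; rules are tried in declared order, first match wins,
#' and an undefined criterion never matches.
#'
#' @name color-mapping
NULL

parse_color <- function(hex) {
  if (!grepl("^#[0-9A-Fa-f]{6}$", hex)) {
    abort(sprintf("invalid color '%s': expected #RRGGBB", hex))
  }
  strtoi(c(substr(hex, 2, 3), substr(hex, 4, 5), substr(hex, 6, 7)), 16L)
}

color_hex <- function(r, g, b) {
  ch <- pmin(pmax(c(r, g, b), 0), 255)
  sprintf("#%02X%02X%02X", ch[1], ch[2], ch[3])
}

#' @rdname color-mapping
#' @param values Anchor values, strictly increasing; length 2 or 3.
#' @param colors Anchor colors (`"#RRGGBB"`), parallel to `values`.
#' @return `gradient_spec()` returns an object of class `gradient_spec`.
#' @examples
#' g <- gradient_spec(c(-2, 0, 2), c("#0000FF", "#FFFFFF", "#FF0000"))
#' gradient_color(g, 0)    # anchor hit: white
#' gradient_color(g, 1)    # halfway white -> red
#' gradient_color(g, 5)    # clamped to red
#' @export
gradient_spec <- function(values, colors) {
  if (!length(values) %in% c(2L, 3L) || length(colors) != length(values)) {
    abort("a gradient needs 2 or 3 (value, color) anchors")
  }
  if (any(diff(values) <= 0)) abort("gradient anchor values must be strictly increasing")
  lapply(colors, parse_color)  # validate
  structure(list(values = as.numeric(values), colors = as.character(colors)),
            class = "gradient_spec")
}

#' @rdname color-mapping
#' @param g A `gradient_spec`.
#' @param v Numeric value to map (`NA` gives `NA`).
#' @export
gradient_color <- function(g, v) {
  if (is.na(v)) return(NA_character_)
  vals <- g$values
  if (v <= vals[1]) return(g$colors[1])
  k <- length(vals)
  if (v >= vals[k]) return(g$colors[k])
  i <- max(which(vals <= v))
  if (vals[i] == v) return(g$colors[i])
  t <- (v - vals[i]) / (vals[i + 1] - vals[i])
  c1 <- parse_color(g$colors[i]); c2 <- parse_color(g$colors[i + 1])
  ch <- round_half_up(c1 + (c2 - c1) * t)
  color_hex(ch[1], ch[2], ch[3])
}

#' @rdname color-mapping
#' @param criterion Criterion (object or text) deciding when the rule
#'   applies.
#' @param color Color painted when the criterion is exactly true.
#' @export
color_rule <- function(criterion, color) {
  parse_color(color)
  structure(list(criterion = as_criterion(criterion), color = color),
            class = "color_rule")
}

#' @rdname color-mapping
#' @param rules List of [color_rule()]s, tried in order.
#' @param row Named list or one-row data frame of column values.
#' @param no_match Color returned when no rule matches.
#' @export
rule_color <- function(rules, row, no_match) {
  for (rl in rules) {
    if (isTRUE(evaluate_criterion(rl$criterion, row))) return(rl$color)
  }
  no_match
}

#' Visualization schemes
#'
#' A scheme assigns each selected data column a visualization method —
#' a gradient for continuous values or an ordered color-rule list for
#' discrete categories — plus the fallback colors for unmeasured nodes and
#' for rows no rule matches.  Applied to a data node, the node box is split
#' into one vertical column per scheme column (left to right, scheme order)
#' and one horizontal row per matching data row (top to bottom, file
#' order), mirroring how multiple measurements for one gene are displayed
#' side by side.
#'
#' @param column_name Dataset column this visualization reads.
#' @param gradient A [gradient_spec()] (numeric columns only), or
#' @param rules a list of [color_rule()]s; exactly one of the two.
#' @return `column_viz()` returns a `column_viz`; `viz_scheme()` a
#'   `viz_scheme`.
#' @export
column_viz <- function(column_name, gradient = NULL, rules = NULL) {
  if (is.null(gradient) == is.null(rules)) {
    abort("supply exactly one of `gradient` or `rules`")
  }
  structure(list(column_name = column_name, gradient = gradient,
                 rules = rules),
            class = "column_viz")
}

#' @rdname column_viz
#' @param columns List of [column_viz()]s (at least one; distinct column
#'   names).
#' @param not_measured_color Fill for nodes without data and for missing
#'   values in gradient columns.
#' @param no_match_color Fill when no color rule matches.
#' @export
viz_scheme <- function(columns, not_measured_color = "#C0C0C0",
                       no_match_color = "#FFFFFF") {
  if (!length(columns)) abort("a scheme needs at least one column")
  nms <- vapply(columns, `[[`, character(1), "column_name")
  if (anyDuplicated(nms)) abort("scheme column names must be distinct")
  parse_color(not_measured_color); parse_color(no_match_color)
  structure(list(columns = columns, not_measured_color = not_measured_color,
                 no_match_color = no_match_color),
            class = "viz_scheme")
}

#' Color grid for one data node
#'
#' Computes the cell colors painted into a data node's box: one grid row
#' per matching data row (order preserved) and one grid column per scheme
#' column.  A node with no data gets a single row of the not-measured
#' color; a missing value in a gradient column colors that cell
#' not-measured while the other cells are still computed.
#'
#' @param scheme A [viz_scheme()].
#' @param rows Tibble of the node's data rows (possibly zero rows), e.g.
#'   from [rows_for_xref()].
#' @return A character matrix of `"#RRGGBB"` colors with dimensions
#'   `max(1, nrow(rows))` by `length(scheme$columns)`.
#' @export
node_cells <- function(scheme, rows) {
  k <- length(scheme$columns)
  nr <- if (is.null(rows)) 0L else nrow(rows)
  if (nr == 0L) {
    return(matrix(scheme$not_measured_color, nrow = 1L, ncol = k))
  }
  out <- matrix(NA_character_, nrow = nr, ncol = k)
  for (j in seq_len(k)) {
    cv <- scheme$columns[[j]]
    if (!is.null(cv$gradient)) {
      vals <- rows[[cv$column_name]]
      if (is.null(vals)) vals <- rep(NA_real_, nr)
      if (!is.numeric(vals)) {
        abort(sprintf("gradient on non-numeric column '%s'", cv$column_name))
      }
      for (i in seq_len(nr)) {
        col <- gradient_color(cv$gradient, vals[i])
        out[i, j] <- if (is.na(col)) scheme$not_measured_color else col
      }
    } else {
      for (i in seq_len(nr)) {
        out[i, j] <- rule_color(cv$rules, rows[i, , drop = FALSE],
                                scheme$no_match_color)
      }
    }
  }
  out
}

#' Read / write a visualization scheme as JSON
#'
#' The scheme file lists the visualized columns with their method
#' (`"gradient"` with `anchors` of `value`/`color`, or `"rules"` with
#' `criterion`/`color` pairs) plus `not_measured_color` and
#' `no_match_color`; colors are `"#RRGGBB"`.
#'
#' @param path JSON file path.
#' @return `read_scheme()` returns a [viz_scheme()].
#' @export
read_scheme <- function(path) {
  js <- jsonlite::read_json(path)
  columns <- lapply(js$columns, function(cj) {
    if (identical(cj$method, "gradient")) {
      column_viz(cj$name, gradient = gradient_spec(
        vapply(cj$anchors, function(a) as.numeric(a$value), numeric(1)),
        vapply(cj$anchors, function(a) a$color, character(1))))
    } else if (identical(cj$method, "rules")) {
      column_viz(cj$name, rules = lapply(cj$rules, function(r) {
        color_rule(r$criterion, r$color)
      }))
    } else {
      abort(sprintf("unknown visualization method '%s'", cj$method))
    }
  })
  viz_scheme(columns,
             not_measured_color = js$not_measured_color %||% "#C0C0C0",
             no_match_color = js$no_match_color %||% "#FFFFFF")
}

#' @rdname read_scheme
#' @param scheme A [viz_scheme()].
#' @export
write_scheme <- function(scheme, path) {
  columns <- lapply(scheme$columns, function(cv) {
    if (!is.null(cv$gradient)) {
      list(name = cv$column_name, method = "gradient",
           anchors = lapply(seq_along(cv$gradient$values), function(i) {
             list(value = cv$gradient$values[i], color = cv$gradient$colors[i])
           }))
    } else {
      list(name = cv$column_name, method = "rules",
           rules = lapply(cv$rules, function(r) {
             list(criterion = r$criterion$source_text, color = r$color)
           }))
    }
  })
  jsonlite::write_json(
    list(columns = columns,
         not_measured_color = scheme$not_measured_color,
         no_match_color = scheme$no_match_color),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
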