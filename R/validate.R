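#' Validate a pathway
#'
#' Checks the structural invariants of a [pathway()] and reports every
#' violation rather than stopping at the first: graph ids must be unique
#' across all element lists (interaction anchors included), element boxes
#' must have positive width and height, interactions need at least two
#' waypoints and every waypoint attachment (`anchor_ref`) must resolve to an
#' existing graph id, group members must resolve, and the drawing board
#' should cover the bounding box of all elements (a warning, since some
#' editors let content hang over the edge).
#'
#' @param p A [pathway()].
#' @return A tibble with columns `severity` (`"error"` or `"warning"`),
#'   `graph_id` and `message`; zero rows when all invariants hold.
#' @examples
#' validate_pathway(pathway("empty"))
#' @export
validate_pathway <- function(p) {
  sev <- character(); gid <- character(); msg <- character()
  issue <- function(severity, graph_id, message) {
    sev <<- c(sev, severity); gid <<- c(gid, graph_id); msg <<- c(msg, message)
  }

  ids <- all_graph_ids(p)
  for (d in unique(ids[duplicated(ids)])) {
    issue("error", d, sprintf("duplicate graph id '%s'", d))
  }

  boxed <- c(p$data_nodes, p$labels, p$shapes)
  for (el in boxed) {
    g <- el$geometry
    if (!is.finite(g$width) || g$width <= 0) {
      issue("error", el$graph_id,
            sprintf("element '%s' has non-positive width", el$graph_id))
    }
    if (!is.finite(g$height) || g$height <= 0) {
      issue("error", el$graph_id,
            sprintf("element '%s' has non-positive height", el$graph_id))
    }
  }

  for (i in p$interactions) {
    if (length(i$waypoints) < 2L) {
      issue("error", i$graph_id,
            sprintf("interaction '%s' has fewer than 2 waypoints", i$graph_id))
    }
    for (w in i$waypoints) {
      if (!is.na(w$anchor_ref) && !w$anchor_ref %in% ids) {
        issue("error", i$graph_id,
              sprintf("interaction '%s' references unknown graph id '%s'",
                      i$graph_id, w$anchor_ref))
      }
    }
  }

  for (g in p$groups) {
    for (m in setdiff(g$members, ids)) {
      issue("error", g$graph_id,
            sprintf("group '%s' contains unknown member '%s'", g$graph_id, m))
    }
  }

  bb <- pathway_bbox(p)
  if (!is.null(bb) &&
      (bb[["x_max"]] > p$board_width || bb[["y_max"]] > p$board_height)) {
    issue("warning", NA_character_,
          "element bounding box exceeds the drawing board")
  }

  tibble(severity = sev, graph_id = gid, message = msg)
}

#' Load a directory of GPML files as a pathway collection
#'
#' Reads every `*.gpml` file in `dir` (sorted by filename, C locale) into a
#' collection.  A file that fails to parse is skipped with a warning rather
#' than aborting the whole load, so one broken file does not block the
#' analysis of a downloaded collection.
#'
#' @param dir Directory containing `.gpml` files.
#' @return A `pathway_collection`: an ordered list of pathways with their
#'   source filenames (`$files`, `$pathways`); failed files are listed in
#'   `$failures`.
#' @export
load_collection <- function(dir) {
  if (!dir.exists(dir)) abort(sprintf("directory '%s' does not exist", dir))
  files <- sort(list.files(dir, pattern = "\\.gpml$"), method = "radix")
  pws <- list(); kept <- character(); failures <- character()
  for (f in files) {
    p <- tryCatch(read_gpml(file.path(dir, f)), error = function(e) e)
    if (inherits(p, "error")) {
      warn(sprintf("skipping '%s': %s", f, conditionMessage(p)))
      failures <- c(failures, f)
    } else {
      pws[[length(pws) + 1L]] <- p
      kept <- c(kept, f)
    }
  }
  if (!length(files)) warn(sprintf("no .gpml files found in '%s'", dir))
  pathway_collection(pws, kept, failures)
}

#' @rdname load_collection
#' @param pathways List of [pathway()] objects.
#' @param files Character vector of source filenames (unique), parallel to
#'   `pathways`.
#' @param failures Filenames that failed to parse, if any.
#' @export
pathway_collection <- function(pathways, files, failures = character()) {
  if (length(pathways) != length(files)) {
    abort("`pathways` and `files` must have the same length")
  }
  if (anyDuplicated(files)) abort("collection filenames must be unique")
  structure(list(files = as.character(files), pathways = pathways,
                 failures = failures),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %d pathway(s)\n", length(x$pathways)))
  if (length(x$failures)) {
    cat(sprintf("  %d file(s) failed to parse\n", length(x$failures)))
  }
  invisible(x)
}

#' @export
length.pathway_collection <- function(x) length(x$pathways)
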