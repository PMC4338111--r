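blue_white_red <- function() {
  gradient_spec(c(-2, 0, 2), c("#0000FF", "#FFFFFF", "#FF0000"))
}

test_that("gradient anchors map exactly; outside values clamp; midpoints interpolate", {
  g <- blue_white_red()
  expect_equal(gradient_color(g, -2), "#0000FF")
  expect_equal(gradient_color(g, 0), "#FFFFFF")
  expect_equal(gradient_color(g, 2), "#FF0000")
  expect_equal(gradient_color(g, 5), "#FF0000")
  expect_equal(gradient_color(g, -9), "#0000FF")
  # white -> red at t = 0.5: channels 127.5 round half-up to 128 = 0x80
  expect_equal(gradient_color(g, 1), "#FF8080")
  expect_equal(gradient_color(g, -1), "#8080FF")
  expect_true(is.na(gradient_color(g, NA)))
  expect_error(gradient_spec(c(0, 0), c("#000000", "#FFFFFF")),
               "strictly increasing")
  expect_error(gradient_spec(c(0, 1), c("#000000", "red")), "invalid color")
})

test_that("gradients are continuous to one quantization step", {
  set.seed(5)
  for (rep in 1:20) {
    vals <- sort(runif(3, -10, 10))
    if (any(diff(vals) < 0.1)) next
    g <- gradient_spec(vals, c("#102030", "#F0E0D0", "#004080"))
    v <- runif(50, vals[1] - 1, vals[3] + 1)
    step <- min(diff(vals)) / 512
    for (x in v) {
      c1 <- pathora:::parse_color(gradient_color(g, x))
      c2 <- pathora:::parse_color(gradient_color(g, x + step))
      expect_true(all(abs(c1 - c2) <= 1))
    }
  }
})

test_that("color rules are first-match-wins and undefined never matches", {
  rules <- list(
    color_rule("[pvalue] < 0.01", "#006400"),
    color_rule("[pvalue] < 0.05", "#66CC66"),
    color_rule("[pvalue] >= 0.05", "#DDDDDD"))
  expect_equal(rule_color(rules, list(pvalue = 0.005), "#FFFFFF"), "#006400")
  expect_equal(rule_color(rules, list(pvalue = 0.03), "#FFFFFF"), "#66CC66")
  expect_equal(rule_color(rules, list(pvalue = 0.5), "#FFFFFF"), "#DDDDDD")
  expect_equal(rule_color(rules, list(pvalue = NA_real_), "#FFFFFF"), "#FFFFFF")
  expect_equal(rule_color(list(), list(pvalue = 0.03), "#FFFFFF"), "#FFFFFF")
})

test_that("node cell grids have one row per measurement and one column per viz", {
  scheme <- default_scheme()
  rows2 <- tibble::tibble(datasource = "S", identifier = c("g", "g"),
                          log2FC = c(1, -2), pvalue = c(0.005, 0.5))
  cells <- node_cells(scheme, rows2)
  expect_equal(dim(cells), c(2L, 2L))
  expect_equal(cells[1, 1], "#FF8080")
  expect_equal(cells[1, 2], "#006400")
  expect_equal(cells[2, 1], "#0000FF")
  expect_equal(cells[2, 2], "#DDDDDD")

  # unmeasured node: a single row of the not-measured color
  none <- node_cells(scheme, rows2[0, ])
  expect_equal(dim(none), c(1L, 2L))
  expect_true(all(none == scheme$not_measured_color))

  # missing value in a gradient column colors only that cell not-measured
  rows_na <- tibble::tibble(datasource = "S", identifier = "g",
                            log2FC = NA_real_, pvalue = 0.005)
  cells_na <- node_cells(scheme, rows_na)
  expect_equal(cells_na[1, 1], scheme$not_measured_color)
  expect_equal(cells_na[1, 2], "#006400")
})

test_that("grid dimensions are always max(1, rows) by columns", {
  scheme <- default_scheme()
  for (nr in 0:4) {
    rows <- tibble::tibble(datasource = rep("S", nr),
                           identifier = rep("g", nr),
                           log2FC = rep(0.5, nr), pvalue = rep(0.5, nr))
    expect_equal(dim(node_cells(scheme, rows)), c(max(1L, nr), 2L))
  }
})

test_that("schemes round-trip through their JSON file format", {
  tf <- withr::local_tempfile(fileext = ".json")
  write_scheme(default_scheme(), tf)
  back <- read_scheme(tf)
  expect_equal(back$not_measured_color, "#C0C0C0")
  expect_length(back$columns, 2L)
  expect_equal(back$columns[[1]]$gradient$values, c(-2, 0, 2))
  expect_equal(back$columns[[2]]$rules[[2]]$color, "#66CC66")
  expect_equal(back$columns[[2]]$rules[[1]]$criterion$source_text,
               "[pvalue] < 0.01")
})

test_that("SVG output has one identified group per element and is deterministic", {
  p <- pathway("three", data_nodes = list(
    node_at("n1", "a", 60, 40, xref("Entrez Gene", "1")),
    node_at("n2", "b", 160, 40),
    node_at("n3", "c", 260, 40, xref("Entrez Gene", "3"))))
  svg <- render_svg(p)
  expect_equal(length(gregexpr('class="data-node"', svg)[[1]]), 3L)
  expect_match(svg, 'id="n2"', fixed = TRUE)
  expect_identical(render_svg(p), svg)

  bad <- p; bad$data_nodes[[1]]$geometry$width <- 0
  expect_error(render_svg(bad), "fails validation")
})

test_that("a scheme tiles each node with its cell grid inside the outline", {
  p <- pathway("one", data_nodes = list(
    node_at("n1", "g", 60, 40, xref("S", "g"))))
  d <- omics_dataset(tibble::tibble(
    datasource = "S", identifier = c("g", "g"),
    log2FC = c(1, -1), pvalue = c(0.005, 0.5)))
  svg <- render_svg(p, scheme = default_scheme(), dataset = d, mapper = NULL)
  node_part <- sub('.*<g id="n1"', "", svg)
  expect_equal(length(gregexpr('class="cell"', node_part)[[1]]), 4L)  # 2x2
  expect_equal(length(gregexpr('class="outline"', node_part)[[1]]), 1L)
  expect_match(node_part, 'fill="#FF8080"', fixed = TRUE)
  # interactions render as polylines with arrow markers
  svg2 <- render_svg(tiny_pathway())
  expect_match(svg2, "<polyline")
  expect_match(svg2, 'marker-end="url(#arrow)"', fixed = TRUE)
})

test_that("PNG export matches board dimensions times scale", {
  p <- pathway("sized", board_width = 300, board_height = 200,
               data_nodes = list(node_at("n1", "g", 60, 40, xref("S", "g"))))
  svg <- render_svg(p)
  tf <- withr::local_tempfile(fileext = ".png")
  export_png(svg, tf, scale = 1)
  expect_equal(dim(png::readPNG(tf))[1:2], c(200L, 300L))
  export_png(svg, tf, scale = 2)
  expect_equal(dim(png::readPNG(tf))[1:2], c(400L, 600L))
  tf2 <- withr::local_tempfile(fileext = ".png")
  expect_error(export_png("<svg", tf2))
  expect_false(file.exists(tf2))
})
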