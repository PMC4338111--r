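test_that("a data node annotation survives read: the KNG1 / Entrez Gene 3827 case", {
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<Pathway xmlns="http://pathvisio.org/GPML/2013a" Name="ACE inhibitor pathway">\n',
    '  <Graphics BoardWidth="300" BoardHeight="200" />\n',
    '  <DataNode TextLabel="KNG1" GraphId="abc12" Type="GeneProduct">\n',
    '    <Graphics CenterX="100" CenterY="50" Width="80" Height="20" />\n',
    '    <Xref Database="Entrez Gene" ID="3827" />\n',
    '  </DataNode>\n',
    '</Pathway>\n')
  p <- read_gpml(doc)
  expect_length(p$data_nodes, 1L)
  expect_true(xref_equal(p$data_nodes[[1]]$xref, xref("Entrez Gene", "3827")))
  expect_equal(p$data_nodes[[1]]$text_label, "KNG1")
})

test_that("read errors are specific: malformed XML, foreign namespace, duplicate ids", {
  expect_error(read_gpml("<Pathway>\n<DataNode>\n</Oops>\n</Pathway>"),
               "malformed XML.*line 2")
  expect_error(read_gpml("<Pathway><oops</Pathway>"), "malformed XML")
  expect_error(read_gpml('<Pathway xmlns="http://example.org/not-gpml" Name="x"/>'),
               "unsupported GPML dialect")
  dup <- paste0(
    '<Pathway xmlns="http://pathvisio.org/GPML/2013a" Name="dup">',
    '<Graphics BoardWidth="100" BoardHeight="100" />',
    '<DataNode TextLabel="a" GraphId="n1" Type="GeneProduct">',
    '<Graphics CenterX="10" CenterY="10" Width="10" Height="10" /><Xref Database="" ID="" /></DataNode>',
    '<DataNode TextLabel="b" GraphId="n1" Type="GeneProduct">',
    '<Graphics CenterX="30" CenterY="10" Width="10" Height="10" /><Xref Database="" ID="" /></DataNode>',
    '</Pathway>')
  expect_error(read_gpml(dup), "duplicate graph id.*n1")
})

test_that("the older 2010a namespace is accepted and normalized", {
  doc <- paste0(
    '<Pathway xmlns="http://genmapp.org/GPML/2010a" Name="old">',
    '<Graphics BoardWidth="100" BoardHeight="100" />',
    '<DataNode TextLabel="x" GraphId="n1" Type="Protein">',
    '<Graphics CenterX="10" CenterY="10" Width="10" Height="10" />',
    '<Xref Database="Ensembl" ID="ENSG1" /></DataNode></Pathway>')
  p <- read_gpml(doc)
  expect_equal(p$data_nodes[[1]]$node_type, "Protein")
  # writing always emits the 2013a dialect
  expect_match(write_gpml(p), "http://pathvisio.org/GPML/2013a", fixed = TRUE)
})

test_that("writing an empty pathway yields a minimal valid document", {
  txt <- write_gpml(pathway("Empty"))
  expect_match(txt, "<Pathway[^>]*Name=\"Empty\"")
  expect_match(txt, "BoardWidth=")
  expect_identical(read_gpml(txt)$name, "Empty")
})

test_that("element counts and unannotated nodes are written per convention", {
  p <- pathway("three", data_nodes = list(
    node_at("n1", "a", 60, 40, xref("Entrez Gene", "1")),
    node_at("n2", "b", 160, 40),
    node_at("n3", "c", 260, 40, xref("Entrez Gene", "3"))))
  txt <- write_gpml(p)
  expect_equal(length(gregexpr("<DataNode ", txt)[[1]]), 3L)
  # a node without annotation still carries an empty Xref element
  expect_match(txt, '<Xref Database="" ID="" />', fixed = TRUE)
})

test_that("writing an invalid pathway aborts before any output", {
  p <- tiny_pathway()
  p$data_nodes[[1]]$geometry$width <- -5
  expect_error(write_gpml(p), "fails validation")
})

test_that("unknown attributes and elements round-trip verbatim", {
  doc <- paste0(
    '<Pathway xmlns="http://pathvisio.org/GPML/2013a" Name="extras" Author="Someone" Data-Source="WikiPathways">',
    '<Graphics BoardWidth="200" BoardHeight="100" />',
    '<DataNode TextLabel="g" GraphId="n1" Type="GeneProduct" CustomFlag="yes">',
    '<Graphics CenterX="50" CenterY="50" Width="40" Height="20" ZOrder="32768" FontSize="10" />',
    '<Xref Database="Entrez Gene" ID="7" /></DataNode>',
    '<InfoBox CenterX="0" CenterY="0" />',
    '</Pathway>')
  p <- read_gpml(doc)
  out <- write_gpml(p)
  expect_match(out, 'Author="Someone"', fixed = TRUE)
  expect_match(out, 'CustomFlag="yes"', fixed = TRUE)
  expect_match(out, 'ZOrder="32768"', fixed = TRUE)
  expect_match(out, "<InfoBox", fixed = TRUE)
  expect_identical(read_gpml(out), p)
})

test_that("random pathways round-trip field-for-field with byte-deterministic output", {
  for (seed in 1:25) {
    p <- generate_random_pathway(seed)
    t1 <- write_gpml(p)
    p2 <- read_gpml(t1)
    expect_identical(p2, p, label = sprintf("model (seed %d)", seed))
    expect_identical(write_gpml(p2), t1, label = sprintf("bytes (seed %d)", seed))
  }
})

test_that("comments and literature references are preserved on data nodes", {
  p <- pathway("notes", data_nodes = list(
    data_node("n1", "g", "GeneProduct", geometry(50, 50, 40, 20),
              comments = c("first note", "second note"),
              literature_refs = c("ref1", "ref2"))))
  p2 <- read_gpml(write_gpml(p))
  expect_equal(p2$data_nodes[[1]]$comments, c("first note", "second note"))
  expect_equal(p2$data_nodes[[1]]$literature_refs, c("ref1", "ref2"))
})

test_that("collection loading sorts by filename and tolerates broken files", {
  dir <- withr::local_tempdir()
  write_gpml(tiny_pathway(), file.path(dir, "b.gpml"))
  write_gpml(pathway("Other"), file.path(dir, "a.gpml"))
  writeLines("<not-xml", file.path(dir, "c.gpml"))
  coll <- NULL
  expect_warning(coll <- load_collection(dir), "skipping 'c.gpml'")
  expect_equal(coll$files, c("a.gpml", "b.gpml"))
  expect_equal(coll$failures, "c.gpml")
  expect_equal(coll$pathways[[2]]$name, "Tiny")

  empty <- withr::local_tempdir()
  coll0 <- NULL
  expect_warning(coll0 <- load_collection(empty), "no .gpml files")
  expect_length(coll0, 0L)
})

test_that("a generated fixture directory loads completely in filename order", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(n_pathways = 6, genes_per_pathway = 4,
                       gene_universe = 30, seed = 11)
  write_fixtures(spec, dir)
  coll <- load_collection(file.path(dir, "pathways"))
  expect_length(coll, 6L)
  expect_equal(coll$files, sprintf("synthetic-%03d.gpml", 1:6))
  for (p in coll$pathways) {
    iss <- validate_pathway(p)
    expect_equal(nrow(iss[iss$severity == "error", ]), 0L)
    expect_equal(nrow(annotated_xrefs(p)), 4L)
  }
})
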