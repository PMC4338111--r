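test_that("zscore matches the hand cases: zero numerator and degenerate variance", {
  expect_identical(zscore(n = 10, r = 2, N = 100, R = 20), 0)
  expect_true(is.na(zscore(n = 5, r = 0, N = 50, R = 0)))   # R = 0
  expect_true(is.na(zscore(n = 0, r = 0, N = 50, R = 10)))  # n = 0
  expect_true(is.na(zscore(n = 50, r = 10, N = 50, R = 10)))# n = N
  expect_true(is.na(zscore(n = 5, r = 5, N = 50, R = 50)))  # R = N
  expect_error(zscore(n = 5, r = 6, N = 50, R = 10), "0 <= r <= n")
  expect_error(zscore(n = 60, r = 1, N = 50, R = 10), "0 <= r <= n")
})

test_that("zscore agrees with the enumerated hypergeometric moments", {
  set.seed(88)
  for (rep in 1:200) {
    N <- sample(2:2000, 1)
    R <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    r <- sample(max(0, n - (N - R)):min(n, R), 1)
    expect_equal(zscore(n, r, N, R), zscore_oracle(n, r, N, R),
                 tolerance = 1e-12,
                 label = sprintf("n=%d r=%d N=%d R=%d", n, r, N, R))
  }
})

test_that("both algebraic forms of the finite-population factor give identical Z", {
  ns <- c(); Ns <- c()
  for (N in c(2, 3, 10, 47, 100, 500, 1000)) {
    ns <- c(ns, 2:N); Ns <- c(Ns, rep(N, N - 1))
  }
  f1 <- 1 - (ns - 1) / (Ns - 1)
  f2 <- (Ns - ns) / (Ns - 1)
  expect_true(all(abs(f1 - f2) <= 1e-12))
})

test_that("Z is positive iff observed exceeds expected, and increases with r", {
  set.seed(12)
  for (rep in 1:50) {
    N <- sample(10:500, 1); R <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    rs <- max(0, n - (N - R)):min(n, R)
    zs <- zscore(rep(n, length(rs)), rs, rep(N, length(rs)), rep(R, length(rs)))
    expected <- n * R / N
    expect_true(all((zs > 0) == (rs > expected)))
    expect_true(all((zs < 0) == (rs < expected)))
    if (length(zs) > 1) expect_true(all(diff(zs) > 0))
  }
})

test_that("pathway counts follow the gene-level rules", {
  p <- tiny_pathway()
  d <- tiny_dataset()
  cnt <- pathway_counts(p, d, NULL, demo_criterion)
  expect_equal(cnt, c(total = 4, n = 3, r = 1))

  # nodes without any xref contribute nothing
  bare <- pathway("bare", data_nodes = list(node_at("n1", "x", 50, 50)))
  expect_equal(pathway_counts(bare, d, NULL, demo_criterion),
               c(total = 0, n = 0, r = 0))

  # duplicated annotation on two nodes collapses to one gene
  dup <- pathway("dup", data_nodes = list(
    node_at("n1", "KNG1", 60, 40, xref("Entrez Gene", "3827")),
    node_at("n2", "KNG1b", 160, 40, xref("Entrez Gene", "3827"))))
  expect_equal(pathway_counts(dup, d, NULL, demo_criterion),
               c(total = 1, n = 1, r = 1))

  # several rows for one gene never inflate counts; any true row is positive
  multi <- omics_dataset(tibble::tibble(
    datasource = "Entrez Gene", identifier = c("3827", "3827"),
    log2FC = c(0.1, 2), pvalue = c(0.9, 0.001)))
  expect_equal(pathway_counts(dup, multi, NULL, demo_criterion),
               c(total = 1, n = 1, r = 1))
})

test_that("the mapper lets rows keyed in another system reach the node", {
  p <- tiny_pathway()
  d <- omics_dataset(tibble::tibble(
    datasource = "HGNC", identifier = "KNG1", log2FC = 2, pvalue = 0.001))
  expect_equal(pathway_counts(p, d, kng1_mapper(), demo_criterion),
               c(total = 4, n = 1, r = 1))
  expect_equal(pathway_counts(p, d, NULL, demo_criterion),
               c(total = 4, n = 0, r = 0))
})

test_that("global counts use the union over pathways and ignore pathway-less genes", {
  coll <- pathway_collection(
    list(tiny_pathway(),
         pathway("second", data_nodes = list(
           node_at("m1", "KNG1", 60, 40, xref("Entrez Gene", "3827")),
           node_at("m2", "NEW", 160, 40, xref("Entrez Gene", "4790"))))),
    c("tiny.gpml", "second.gpml"))
  # dataset measures 5 genes; 4790 has no row, 9999 is in no pathway
  d <- omics_dataset(tibble::tibble(
    datasource = "Entrez Gene",
    identifier = c("3827", "1636", "183", "5972", "9999"),
    log2FC = c(1.8, 0.2, -0.4, 3, 2.5),
    pvalue = c(0.003, 0.6, 0.2, 0.001, 0.001)))
  gc <- global_counts(coll, d, NULL, demo_criterion)
  expect_equal(gc, c(N = 4, R = 2))  # 9999 ignored; shared 3827 counted once
})

test_that("run_ora ranks by Z with undefined scores last and name tie-breaks", {
  coll <- pathway_collection(
    list(tiny_pathway(),
         pathway("Alpha copy", data_nodes = list(
           node_at("a1", "KNG1", 60, 40, xref("Entrez Gene", "3827")),
           node_at("a2", "ACE", 160, 40, xref("Entrez Gene", "1636")))),
         pathway("Beta copy", data_nodes = list(
           node_at("b1", "KNG1", 60, 40, xref("Entrez Gene", "3827")),
           node_at("b2", "ACE", 160, 40, xref("Entrez Gene", "1636"))))),
    c("tiny.gpml", "alpha.gpml", "beta.gpml"))
  rep <- run_ora(coll, tiny_dataset(), NULL, demo_criterion)
  rows <- tidy(rep)
  # identical pathways score identically and order alphabetically
  i_alpha <- which(rows$pathway == "Alpha copy")
  i_beta <- which(rows$pathway == "Beta copy")
  expect_equal(rows$zscore[i_alpha], rows$zscore[i_beta])
  expect_lt(i_alpha, i_beta)
  expect_equal(glance(rep)$N, 3L)
  expect_equal(glance(rep)$R, 1L)
})

test_that("a criterion nothing meets yields all-undefined Z with a warning", {
  coll <- pathway_collection(list(tiny_pathway()), "tiny.gpml")
  expect_warning(rep <- run_ora(coll, tiny_dataset(), NULL, "[log2FC] > 100"),
                 "R = 0")
  expect_true(all(is.na(tidy(rep)$zscore)))
  expect_equal(rep$R, 0L)
})

test_that("an unparseable criterion aborts before any counting", {
  coll <- pathway_collection(list(tiny_pathway()), "tiny.gpml")
  expect_error(run_ora(coll, tiny_dataset(), NULL, "[log2FC] >"), "syntax error")
})

test_that("report files round-trip counts exactly and format Z to two decimals", {
  coll <- pathway_collection(
    list(tiny_pathway(),
         pathway("Alpha copy", data_nodes = list(
           node_at("a1", "KNG1", 60, 40, xref("Entrez Gene", "3827")),
           node_at("a2", "ACE", 160, 40, xref("Entrez Gene", "1636"))))),
    c("tiny.gpml", "alpha.gpml"))
  rep <- run_ora(coll, tiny_dataset(), NULL, demo_criterion)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_ora_report(rep, tf)
  lines <- readLines(tf)
  expect_equal(lines[1],
               "pathway\tfile\ttotal\tmeasured\tpositive\tzscore\tzscore_exact")
  expect_equal(length(lines), nrow(tidy(rep)) + 1L)
  expect_match(lines[2], "\t[0-9]+\\.[0-9]{2}\t")
  back <- read_ora_report(tf)
  expect_equal(back$total, tidy(rep)$total)
  expect_equal(back$measured, tidy(rep)$measured)
  expect_equal(back$positive, tidy(rep)$positive)
  expect_equal(back$zscore, tidy(rep)$zscore, tolerance = 1e-15)

  # undefined Z is written as the literal NA
  suppressWarnings(rep0 <- run_ora(coll, tiny_dataset(), NULL, "[log2FC] > 100"))
  write_ora_report(rep0, tf)
  expect_match(readLines(tf)[2], "\tNA\tNA$")
})

test_that("autoplot returns a ggplot of the ranked report", {
  coll <- pathway_collection(list(tiny_pathway()), "tiny.gpml")
  rep <- run_ora(coll, tiny_dataset(), NULL, demo_criterion)
  expect_s3_class(autoplot(rep), "ggplot")
})
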