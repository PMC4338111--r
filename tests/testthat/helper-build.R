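# Small in-code fixtures shared by the unit tests.

node_at <- function(id, label, x, y, xr = NULL, type = "GeneProduct") {
  data_node(id, label, type, geometry(x, y, 80, 20), xref = xr)
}

# Four annotated gene nodes (one xref duplicated on two nodes would be a
# variant built in the test that needs it).
tiny_pathway <- function() {
  pathway("Tiny", organism = "Synthetic", version = "1",
          data_nodes = list(
            node_at("n1", "KNG1", 60, 40, xref("Entrez Gene", "3827")),
            node_at("n2", "ACE", 160, 40, xref("Entrez Gene", "1636")),
            node_at("n3", "AGT", 260, 40, xref("Entrez Gene", "183")),
            node_at("n4", "REN", 360, 40, xref("Entrez Gene", "5972"))),
          interactions = list(
            interaction("e1",
                        list(waypoint(60, 40), waypoint(160, 40)),
                        end_arrow = "Arrow")))
}

# Dataset covering three of the four tiny_pathway genes; gene 3827 is the
# only one passing |log2FC| > 1 AND pvalue < 0.05.
tiny_dataset <- function() {
  omics_dataset(tibble::tibble(
    datasource = "Entrez Gene",
    identifier = c("3827", "1636", "183"),
    log2FC = c(1.8, 0.2, -0.4),
    pvalue = c(0.003, 0.6, 0.2)))
}

kng1_mapper <- function() {
  load_mapping_table(paste(
    "source_system\tsource_id\ttarget_system\ttarget_id",
    "HGNC\tKNG1\tEntrez Gene\t3827",
    sep = "\n"))
}

demo_criterion <- "ABS([log2FC]) > 1 AND [pvalue] < 0.05"
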