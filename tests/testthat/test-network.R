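write_map <- function(df) {
  p <- tempfile(fileext = ".tsv")
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

test_that("ortholog maps load, deduplicate and validate", {
  p <- write_map(data.frame(yeast_gene = "MKK1", human_gene = "MAP2K5",
                            source = "homologene"))
  m <- load_ortholog_map(p)
  expect_equal(nrow(m), 1)
  expect_equal(m$human_gene, "MAP2K5")
  p2 <- write_map(data.frame(yeast_gene = c("MKK1", "MKK1"),
                             human_gene = c("MAP2K5", "MAP2K5"),
                             source = c("inparanoid", "inparanoid")))
  expect_warning(m2 <- load_ortholog_map(p2), "duplicate")
  expect_equal(nrow(m2), 1)
  p3 <- write_map(data.frame(yeast_gene = character(0),
                             human_gene = character(0),
                             source = character(0)))
  expect_equal(nrow(load_ortholog_map(p3)), 0)
})

suppressor_ztable <- function(queries, yeast_genes, labels) {
  data.frame(strain_id = paste0("s", seq_along(yeast_genes)),
             yeast_gene = yeast_genes, query = queries, label = labels,
             stringsAsFactors = FALSE)
}

test_that("only suppressors generate interactions, expanded per ortholog", {
  zt <- suppressor_ztable(c("OPTN", "ANG", "OPTN", "OPTN"),
                          c("MKK1", "MKK1", "YDL001W", "YDL002W"),
                          c("suppressor", "suppressor", "enhancer",
                            "suppressor"))
  omap <- data.frame(yeast_gene = c("MKK1", "YDL001W"),
                     human_gene = c("MAP2K5", "HGENE1"),
                     source = "inparanoid", stringsAsFactors = FALSE)
  mp <- map_suppressors(zt, omap)
  # MKK1 suppresses both queries -> two edges to the shared partner;
  # the enhancer contributes nothing even though it has an ortholog
  expect_equal(nrow(mp$interactions), 2)
  expect_setequal(mp$interactions$query_gene, c("OPTN", "ANG"))
  expect_true(all(mp$interactions$partner == "MAP2K5"))
  expect_true(all(mp$interactions$evidence == "genetic_suppression"))
  # the ortholog-less suppressor lands in the unmapped report
  expect_equal(mp$unmapped$yeast_gene, "YDL002W")
  # a yeast gene with two orthologs yields two edges, one per source
  omap2 <- rbind(omap, data.frame(yeast_gene = "MKK1",
                                  human_gene = "MAP2K1",
                                  source = "homologene"))
  mp2 <- map_suppressors(zt[1, ], omap2)
  expect_equal(nrow(mp2$interactions), 2)
  expect_setequal(mp2$interactions$partner, c("MAP2K5", "MAP2K1"))
})

test_that("networks deduplicate nodes and record typed edges", {
  ints <- data.frame(query_gene = c("A", "B", "A"),
                     partner = c("P", "P", "P"),
                     yeast_gene = "YG1", evidence = "genetic_suppression",
                     source = "inparanoid", stringsAsFactors = FALSE)
  net <- build_network(ints)  # duplicate row collapses
  expect_equal(igraph::vcount(net), 3)
  expect_equal(igraph::ecount(net), 2)
  expect_equal(unname(igraph::degree(net)["P"]), 2)
  expect_setequal(igraph::V(net)$type[igraph::V(net)$name == "P"],
                  "human_ortholog")
  # empty interaction list -> empty network
  empty <- build_network(ints[0, ])
  expect_equal(igraph::vcount(empty), 0)
  # imported edges pass through; unknown endpoints become ortholog nodes
  imp <- data.frame(source = "P", target = "NEW", type = "ppi")
  net2 <- build_network(ints, imported_edges = imp)
  expect_equal(igraph::vcount(net2), 4)
  expect_setequal(igraph::E(net2)$type,
                  c("genetic_suppression", "imported"))
  expect_equal(igraph::V(net2)$type[igraph::V(net2)$name == "NEW"],
               "human_ortholog")
})

test_that("exports agree across formats and GraphML round-trips", {
  ints <- data.frame(query_gene = c("OPTN", "ANG"), partner = "MAP2K5",
                     yeast_gene = "MKK1", evidence = "genetic_suppression",
                     source = "inparanoid", stringsAsFactors = FALSE)
  net <- build_network(ints)
  gml <- tempfile(fileext = ".graphml")
  sif <- tempfile(fileext = ".sif")
  tsv <- tempfile(fileext = ".tsv")
  export_network(net, gml, "graphml")
  export_network(net, sif, "sif")
  export_network(net, tsv, "tsv")
  sif_lines <- readLines(sif)
  expect_equal(length(sif_lines), 2)
  expect_true(all(grepl("\tgenetic_suppression\t", sif_lines)))
  tsv_df <- read.delim(tsv)
  expect_equal(nrow(tsv_df), 2)
  expect_setequal(unique(c(tsv_df$from, tsv_df$to)),
                  c("OPTN", "ANG", "MAP2K5"))
  net_back <- import_network(gml)
  expect_equal(igraph::vcount(net_back), igraph::vcount(net))
  expect_equal(igraph::ecount(net_back), nrow(tsv_df))
  # canonical-byte stability of export -> import -> export
  gml2 <- tempfile(fileext = ".graphml")
  export_network(net_back, gml2, "graphml")
  expect_identical(readLines(gml), readLines(gml2))
  expect_error(export_network(net, tempfile(), "gexf"))
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  universe <- letters[1:10]
  # closed form: drawing 3 from 10 with a 5-gene category, all 3 hits
  res <- enrich_categories(c("a", "b", "c"),
                           list(cat = letters[1:5]), universe)
  expect_equal(res$p_value, choose(5, 3) / choose(10, 3))
  expect_equal(res$p_value, bf_enrich_p(3, letters[1:5], universe, 3))
  # category equal to the universe is uninformative
  expect_equal(enrich_categories("a", list(all = universe),
                                 universe)$p_value, 1)
  # zero hits -> upper tail at >= 0 is 1
  res0 <- enrich_categories(c("f", "g"), list(cat = letters[1:3]),
                            universe)
  expect_equal(res0$p_value[res0$hits == 0], 1)
  expect_error(enrich_categories(character(0), list(cat = "a"), universe),
               "empty")
  expect_error(enrich_categories("zz", list(cat = "a"), universe),
               "subset")
  expect_warning(enrich_categories("a", list(off = c("xx", "yy")),
                                   universe), "no overlap")
})

test_that("enrichment p-values are BH-adjusted and ordered", {
  set.seed(6)
  universe <- paste0("g", 1:15)
  ann <- list(c1 = sample(universe, 6), c2 = sample(universe, 3),
              c3 = sample(universe, 9))
  genes <- sample(universe, 5)
  res <- enrich_categories(genes, ann, universe)
  expect_equal(res$p_value, sort(res$p_value))
  expect_true(all(res$q_value >= res$p_value - 1e-15))
  expect_true(all(res$q_value <= 1))
  # oracle agreement on every category
  for (i in seq_len(nrow(res)))
    expect_equal(res$p_value[i],
                 bf_enrich_p(res$hits[i], ann[[res$category[i]]],
                             universe, length(genes)),
                 tolerance = 1e-12)
  # fixing the draw size, one extra hit can only sharpen the category
  for (k in 0:4)
    expect_gte(phyper(k - 1, 6, 9, 5, lower.tail = FALSE),
               phyper(k, 6, 9, 5, lower.tail = FALSE))
})
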