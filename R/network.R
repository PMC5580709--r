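#' Load a yeast-to-human ortholog map
#'
#' Tab-separated with header `yeast_gene  human_gene  source`; the source
#' tags where the ortholog call came from (e.g. inparanoid, homologene).
#' Duplicate triples are collapsed with a warning; identifiers are opaque
#' case-sensitive strings (no symbol normalization is attempted).
#'
#' @param path ortholog map TSV.
#' @return data.frame with columns `yeast_gene`, `human_gene`, `source`.
#' @export
load_ortholog_map <- function(path) {
  df <- read_tsv_strict(path, c("yeast_gene", "human_gene", "source"),
                        "ortholog map")
  bad <- which(!nzchar(df$yeast_gene) | !nzchar(df$human_gene))
  if (length(bad))
    stop("malformed ortholog map row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "))
  dup <- duplicated(df[, c("yeast_gene", "human_gene", "source")])
  if (any(dup)) {
    warning(sum(dup), " duplicate ortholog triple(s) collapsed")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Map yeast toxicity suppressors to human interaction partners
#'
#' Genetic interactions are defined by suppression: every strain labelled
#' `suppressor` for a query links that (human) query gene to the human
#' ortholog(s) of the deleted yeast gene. Enhancer and no-effect strains
#' contribute nothing. A yeast suppressor with several orthologs yields
#' one interaction per ortholog, each carrying its source. Suppressors
#' without any ortholog entry are collected in an `unmapped` report, not
#' dropped silently.
#'
#' @param ztable a labelled Z-table (from `modifier_screen$ztable` or
#'   [read_ztable()]).
#' @param ortholog_map data.frame from [load_ortholog_map()].
#' @return list with `interactions` (data.frame `query_gene`, `partner`,
#'   `yeast_gene`, `evidence`, `source`) and `unmapped` (data.frame
#'   `query_gene`, `yeast_gene`).
#' @export
map_suppressors <- function(ztable, ortholog_map) {
  sup <- ztable[ztable$label == "suppressor", , drop = FALSE]
  hit <- merge(sup[, c("query", "yeast_gene")], ortholog_map,
               by = "yeast_gene")
  interactions <- data.frame(query_gene = hit$query,
                             partner = hit$human_gene,
                             yeast_gene = hit$yeast_gene,
                             evidence = rep("genetic_suppression",
                                            nrow(hit)),
                             source = hit$source,
                             stringsAsFactors = FALSE)
  interactions <- interactions[order(interactions$query_gene,
                                     interactions$partner,
                                     interactions$yeast_gene), ,
                               drop = FALSE]
  rownames(interactions) <- NULL
  un <- sup[!(sup$yeast_gene %in% ortholog_map$yeast_gene),
            c("query", "yeast_gene"), drop = FALSE]
  names(un)[1] <- "query_gene"
  rownames(un) <- NULL
  list(interactions = interactions, unmapped = un)
}

#' Build a typed disease-gene interaction network
#'
#' Nodes are disease (query) genes and human orthologs of yeast
#' suppressors; edges carry evidence type `genetic_suppression`.
#' Externally supplied edges (e.g. known protein-protein interactions)
#' are passed through with type `imported`; an imported endpoint unknown
#' to the screen is added as a `human_ortholog` node. Insertion is
#' idempotent: duplicate interaction rows collapse to a single edge, and
#' a partner shared by several queries appears once with degree >= 2.
#'
#' @param interactions data.frame from [map_suppressors()].
#' @param imported_edges optional data.frame `source`, `target`, `type`.
#' @return an [igraph::graph] with vertex attribute `type`
#'   (`disease_gene` / `human_ortholog`) and edge attributes `type`,
#'   `yeast_gene` (provenance; `NA` for imported edges).
#' @export
build_network <- function(interactions, imported_edges = NULL) {
  if (nrow(interactions)) {
    self <- interactions$query_gene == interactions$partner
    if (any(self)) interactions <- interactions[!self, , drop = FALSE]
  }
  nodes <- data.frame(
    name = c(unique(interactions$query_gene),
             setdiff(unique(interactions$partner),
                     unique(interactions$query_gene))),
    stringsAsFactors = FALSE)
  nodes$type <- c(rep("disease_gene",
                      length(unique(interactions$query_gene))),
                  rep("human_ortholog",
                      nrow(nodes) -
                        length(unique(interactions$query_gene))))
  edges <- unique(data.frame(from = interactions$query_gene,
                             to = interactions$partner,
                             type = rep("genetic_suppression",
                                        nrow(interactions)),
                             yeast_gene = interactions$yeast_gene,
                             stringsAsFactors = FALSE))
  # one edge per (query, partner, yeast provenance); duplicates collapsed
  if (!is.null(imported_edges) && nrow(imported_edges)) {
    extra <- setdiff(unique(c(imported_edges$source,
                              imported_edges$target)), nodes$name)
    if (length(extra)) {
      log_line("network", imported_new_nodes = length(extra))
      nodes <- rbind(nodes, data.frame(name = extra,
                                       type = "human_ortholog",
                                       stringsAsFactors = FALSE))
    }
    edges <- rbind(edges,
                   unique(data.frame(from = imported_edges$source,
                                     to = imported_edges$target,
                                     type = "imported",
                                     yeast_gene = NA_character_,
                                     stringsAsFactors = FALSE)))
  }
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = nodes)
}

canonical_network_tables <- function(net) {
  v <- data.frame(name = igraph::V(net)$name, type = igraph::V(net)$type,
                  stringsAsFactors = FALSE)
  v <- v[order(v$name), , drop = FALSE]
  el <- igraph::as_data_frame(net, what = "edges")
  if (!nrow(el))
    el <- data.frame(from = character(0), to = character(0),
                     type = character(0), yeast_gene = character(0))
  swap <- el$from > el$to
  tmp <- el$from[swap]; el$from[swap] <- el$to[swap]; el$to[swap] <- tmp
  el <- el[order(el$from, el$to, el$type,
                 ifelse(is.na(el$yeast_gene), "", el$yeast_gene)), ,
           drop = FALSE]
  rownames(v) <- rownames(el) <- NULL
  list(nodes = v, edges = el)
}

#' Export an interaction network
#'
#' Writes the network in a Cytoscape-readable format: GraphML (canonical
#' node/edge ordering, byte-stable across an export-import-export round
#' trip), SIF (`source  relation  target` with relation tokens
#' `genetic_suppression` / `imported`), or an edge-list TSV.
#'
#' @param net an igraph network from [build_network()].
#' @param path output file.
#' @param format `"graphml"`, `"sif"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  ct <- canonical_network_tables(net)
  if (format == "graphml") {
    canon <- igraph::graph_from_data_frame(ct$edges, directed = FALSE,
                                           vertices = ct$nodes)
    igraph::write_graph(canon, path, format = "graphml")
  } else if (format == "sif") {
    lines <- if (nrow(ct$edges))
      paste(ct$edges$from, ct$edges$type, ct$edges$to, sep = "\t")
    else character(0)
    writeLines(lines, path)
  } else {
    write_tsv(ct$edges, path)
  }
  invisible(path)
}

#' Import a GraphML interaction network
#'
#' @param path GraphML file written by [export_network()].
#' @return an igraph network.
#' @export
import_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Hypergeometric category enrichment
#'
#' Tests each annotation category for over-representation among a hit
#' list drawn from a gene universe: the p-value is the hypergeometric
#' upper-tail probability of observing at least the seen overlap, and
#' q-values are Benjamini-Hochberg adjusted across categories. A generic
#' stand-in for proprietary pathway-enrichment summaries; users supply
#' their own category-to-gene annotation.
#'
#' @param genes hit gene list (must be a subset of `universe`).
#' @param annotation named list: category -> character vector of genes.
#' @param universe background gene set.
#' @return data.frame `category`, `hits`, `category_size`,
#'   `universe_size`, `drawn`, `p_value`, `q_value`, sorted by p-value.
#' @examples
#' enrich_categories(c("a", "b", "c"),
#'                   list(cat1 = c("a", "b", "c", "d", "e")),
#'                   letters[1:10])
#' @export
enrich_categories <- function(genes, annotation, universe) {
  genes <- unique(genes)
  universe <- unique(universe)
  if (!length(genes)) stop("empty gene list")
  if (!all(genes %in% universe))
    stop("genes must be a subset of the universe")
  rows <- lapply(names(annotation), function(cat) {
    set <- intersect(unique(annotation[[cat]]), universe)
    if (!length(set)) {
      warning("category '", cat, "' has no overlap with the universe; ",
              "skipped")
      return(NULL)
    }
    k <- length(intersect(genes, set))
    data.frame(category = cat, hits = k, category_size = length(set),
               universe_size = length(universe), drawn = length(genes),
               p_value = phyper(k - 1L, length(set),
                                length(universe) - length(set),
                                length(genes), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(category = character(0), hits = integer(0),
                      category_size = integer(0), universe_size = integer(0),
                      drawn = integer(0), p_value = numeric(0),
                      q_value = numeric(0)))
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
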