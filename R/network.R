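# Interactome ingestion and per-node network properties. Graphs are plain
# undirected igraph objects; all user-facing results are tibbles.

#' Read a protein-protein interaction edge list
#'
#' Reads a two-column (optionally three: a score, which is dropped — the
#' graph is unweighted) tab-separated edge list into a simple undirected
#' graph: self-loops are removed and duplicate or reversed-duplicate edges
#' merged. The numbers of dropped loops and merged duplicates are recorded
#' in graph attributes `n_loops_dropped` and `n_duplicates_merged`.
#'
#' @param path Path to the edge-list file (`#` comments allowed).
#' @return An undirected simple `igraph` object with vertex attribute
#'   `name` (uppercased gene symbols).
#' @export
read_edge_list <- function(path) {
  lines <- readr::read_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L) {
    stop_dg(sprintf("Malformed edge at line %d: need two tab-separated gene columns.",
                    bad[[1L]]), "dualgene_format_error")
  }
  a <- normalize_symbols(vapply(parts, `[[`, "", 1L))
  b <- normalize_symbols(vapply(parts, `[[`, "", 2L))
  interaction_network(tibble(from = a, to = b))
}

#' Build a simple undirected interaction network from an edge table
#'
#' @param edges Data frame with columns `from` and `to` (gene symbols).
#' @param nodes Optional character vector of additional (possibly isolated)
#'   node names to include.
#' @return Simple undirected `igraph` object.
#' @export
interaction_network <- function(edges, nodes = NULL) {
  stopifnot(all(c("from", "to") %in% names(edges)))
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = if (is.null(nodes)) NULL else
      unique(c(nodes, edges$from, edges$to))
  )
  n_loops <- sum(igraph::which_loop(g))
  g2 <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g2$n_loops_dropped <- n_loops
  g2$n_duplicates_merged <- igraph::ecount(g) - n_loops - igraph::ecount(g2)
  g2
}

#' Attach gene-set labels to network vertices
#'
#' @param network `igraph` object with vertex names.
#' @param partition Tibble (`gene_id`, `set_label`). Vertices absent from
#'   the partition get label `NCRG`.
#' @return The network with a `set_label` vertex attribute.
#' @export
label_network <- function(network, partition) {
  lab <- setNames(as.character(partition$set_label), partition$gene_id)
  v <- igraph::V(network)$name
  got <- unname(lab[v])
  got[is.na(got)] <- "NCRG"
  igraph::set_vertex_attr(network, "set_label", value = got)
}

#' Per-node network metrics
#'
#' Degree, local clustering coefficient (0 for nodes of degree < 2),
#' core number and the MCODE-style vertex weight.
#'
#' @param network Simple undirected `igraph` object.
#' @return Tibble (`gene_id`, `degree`, `clustering`, `core_number`,
#'   `mcode_weight`[, `set_label`]).
#' @export
node_metrics <- function(network) {
  cc <- unname(igraph::transitivity(network, type = "localundirected",
                                    isolates = "zero"))
  out <- tibble(
    gene_id = igraph::V(network)$name,
    degree = as.integer(igraph::degree(network)),
    clustering = cc,
    core_number = as.integer(igraph::coreness(network)),
    mcode_weight = mcode_weights(network)
  )
  if (!is.null(igraph::vertex_attr(network, "set_label"))) {
    out$set_label <- igraph::V(network)$set_label
  }
  out
}

#' Extract the dual-role-gene neighborhood network
#'
#' The sub-network containing every POTSF-labelled node plus its direct
#' neighbors. By default the subgraph is induced on that node set (all
#' edges among retained nodes); `induced = FALSE` keeps only edges with at
#' least one POTSF endpoint.
#'
#' @param network Labelled `igraph` (see [label_network()]).
#' @param induced Keep all edges among the retained nodes (default) or only
#'   POTSF-incident edges.
#' @return `igraph` sub-network (empty if the network has no POTSF node).
#' @export
potsf_neighborhood <- function(network, induced = TRUE) {
  lab <- igraph::vertex_attr(network, "set_label")
  if (is.null(lab)) {
    stop_dg("Network has no set_label vertex attribute; run label_network().",
            "dualgene_domain_error")
  }
  seeds <- which(lab == "POTSF")
  if (length(seeds) == 0L) {
    return(igraph::induced_subgraph(network, integer(0)))
  }
  nbrs <- unique(unlist(igraph::adjacent_vertices(network, seeds)))
  keep <- sort(unique(c(seeds, nbrs)))
  sub <- igraph::induced_subgraph(network, keep)
  if (!induced) {
    drop <- igraph::E(sub)[!igraph::ends(sub, igraph::E(sub))[, 1] %in%
                             igraph::V(network)$name[seeds] &
                           !igraph::ends(sub, igraph::E(sub))[, 2] %in%
                             igraph::V(network)$name[seeds]]
    sub <- igraph::delete_edges(sub, drop)
  }
  sub
}

#' Summarise node composition of a network by gene set
#'
#' @param network Labelled `igraph`.
#' @return Tibble (`set_label`, `n_nodes`).
#' @export
network_composition <- function(network) {
  lab <- igraph::vertex_attr(network, "set_label")
  tibble(set_label = lab) %>%
    count(.data$set_label, name = "n_nodes") %>%
    arrange(desc(.data$n_nodes))
}
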