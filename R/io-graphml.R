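#' Export a molecular network to GraphML
#'
#' Nodes carry mass/RT/abundance attributes and edges carry their type
#' (`msms` or `binding`) and score, so the file loads directly into Cytoscape
#' or any GraphML-aware tool.
#'
#' @param network A `molecular_network` (see [build_network()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  g <- as_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert a molecular network to an igraph graph
#' @param network A `molecular_network`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(network) {
  nodes <- network$nodes
  edges <- network$edges
  if (nrow(edges)) {
    igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  } else {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, nrow(nodes), name = nodes$id)
    for (col in setdiff(names(nodes), "id")) {
      g <- igraph::set_vertex_attr(g, col, value = nodes[[col]])
    }
    g
  }
}

#' Read a GraphML network written by [write_graphml()]
#' @param path GraphML path.
#' @return A `molecular_network`.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("GraphML file not found: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  edges <- igraph::as_data_frame(g, what = "edges")
  if (nrow(nodes)) {
    names(nodes)[names(nodes) == "name"] <- "id"
    rownames(nodes) <- NULL
  } else {
    nodes <- data.frame(id = character(0))
  }
  molecular_network(nodes, edges)
}
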