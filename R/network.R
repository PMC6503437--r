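#' Gene interaction networks
#'
#' A `gene_network` is an undirected, unweighted, simple graph over gene
#' identifiers, optionally annotated with the subset of nodes that are assayed
#' in an expression study. Edge direction and interaction type are
#' deliberately ignored: distances are hop counts on the undirected graph.
#'
#' @param edges a two-column matrix or data frame of gene-id pairs (character).
#' @param assayed character vector of node ids present in the expression data
#'   (a subset of the graph's nodes); may be set later via
#'   [restrict_to_network()].
#' @return an object of class `gene_network` wrapping an [igraph::graph]
#'   with node names, plus the assayed-node annotation.
#' @examples
#' net <- gene_network(cbind(c("A", "B", "C"), c("B", "C", "D")))
#' network_nodes(net)
#' @export
gene_network <- function(edges, assayed = character()) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) {
    stop("edges must have exactly two columns (one edge per row)")
  }
  storage.mode(edges) <- "character"
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  new_gene_network(g, assayed)
}

new_gene_network <- function(graph, assayed = character()) {
  nodes <- igraph::V(graph)$name
  assayed <- intersect(as.character(assayed), nodes)
  structure(list(graph = graph, assayed = assayed), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf(
    "<gene_network> %d nodes, %d edges, %d assayed%s\n",
    network_size(x), igraph::ecount(x$graph), length(x$assayed),
    if (igraph::is_connected(x$graph)) ", connected" else ""
  ))
  invisible(x)
}

#' @rdname gene_network
#' @param net a `gene_network`.
#' @export
network_nodes <- function(net) igraph::V(net$graph)$name

#' @rdname gene_network
#' @export
network_size <- function(net) igraph::vcount(net$graph)

#' Node degrees of a gene network
#' @param net a `gene_network`.
#' @return named integer vector of degrees.
#' @export
network_degree <- function(net) {
  setNames(igraph::degree(net$graph), network_nodes(net))
}

#' Merge pathway edge lists into one global network
#'
#' Pathway databases partition interactions into overlapping pathways; taking
#' the graph union removes those artificial boundaries: an edge belongs to the
#' global network if it occurs in at least one pathway. Self-loops and
#' duplicate edges (in either orientation) are dropped.
#'
#' @param pathway_edge_lists a list of two-column matrices/data frames, one
#'   per pathway, each row an undirected edge between two gene ids.
#' @return a `gene_network` over the union of all edges.
#' @examples
#' g <- build_union_graph(list(
#'   cbind(c("A", "B"), c("B", "C")),
#'   cbind(c("B", "C"), c("C", "D"))
#' ))
#' network_size(g) # 4
#' @export
build_union_graph <- function(pathway_edge_lists) {
  if (!is.list(pathway_edge_lists)) pathway_edge_lists <- list(pathway_edge_lists)
  if (length(pathway_edge_lists) == 0L) stop("no edges")
  mats <- lapply(seq_along(pathway_edge_lists), function(k) {
    m <- as.matrix(pathway_edge_lists[[k]])
    if (ncol(m) != 2L) {
      stop(sprintf("pathway %d: malformed edge record (expected 2 endpoints, got %d columns)",
                   k, ncol(m)))
    }
    storage.mode(m) <- "character"
    m
  })
  all_edges <- do.call(rbind, mats)
  if (nrow(all_edges) == 0L) stop("no edges")
  gene_network(all_edges)
}

#' Largest connected component of a gene network
#'
#' The analysis domain of the method: geodesic distances are only defined
#' within one component, so the graph is reduced to its largest. Ties in
#' component size are broken deterministically in favor of the component
#' containing the lexicographically smallest node id.
#'
#' @param net a `gene_network`.
#' @return a connected `gene_network`; the assayed annotation is carried over
#'   (intersected with the surviving nodes).
#' @export
largest_connected_component <- function(net) {
  if (network_size(net) == 0L) stop("empty network")
  comp <- igraph::components(net$graph)
  top <- which(comp$csize == max(comp$csize))
  if (length(top) > 1L) {
    nodes <- network_nodes(net)
    first_node <- vapply(top, function(k) min(nodes[comp$membership == k]), "")
    top <- top[order(first_node)][1L]
  }
  keep <- which(comp$membership == top)
  sub <- igraph::induced_subgraph(net$graph, keep)
  new_gene_network(sub, net$assayed)
}

#' All-pairs geodesic distances on a connected network
#'
#' Breadth-first-search hop counts for every ordered node pair, plus the
#' network diameter D (the maximum distance, which later bounds the radius
#' scan and scales the Bonferroni threshold).
#'
#' @param net a connected `gene_network` (apply
#'   [largest_connected_component()] first).
#' @return a `distance_oracle`: list with the integer distance matrix `d`
#'   (dimnames = node ids), `diameter`, and `nodes`.
#' @export
geodesic_distances <- function(net) {
  if (!igraph::is_connected(net$graph)) {
    stop("network is disconnected; reduce to the largest connected component first")
  }
  d <- igraph::distances(net$graph, algorithm = "unweighted")
  storage.mode(d) <- "integer"
  nodes <- network_nodes(net)
  dimnames(d) <- list(nodes, nodes)
  structure(
    list(d = d, diameter = max(d), nodes = nodes),
    class = "distance_oracle"
  )
}

#' @export
print.distance_oracle <- function(x, ...) {
  cat(sprintf("<distance_oracle> %d nodes, diameter %d\n",
              length(x$nodes), x$diameter))
  invisible(x)
}

#' Geodesic neighborhood of a gene
#'
#' All genes at hop distance 1..r from the center gene i. The center itself is
#' excluded: its self-correlation is identically 1 and its own differential
#' expression sits at distance 0, so including it would only add a constant to
#' both test statistics.
#'
#' @param oracle a `distance_oracle` from [geodesic_distances()].
#' @param i center gene id.
#' @param r neighborhood radius, an integer in `1..diameter`.
#' @param within optional character vector; restrict the returned set to these
#'   ids (e.g. the assayed genes).
#' @return character vector of gene ids with `0 < d_ij <= r`.
#' @export
neighborhood <- function(oracle, i, r, within = NULL) {
  if (!i %in% oracle$nodes) stop(sprintf("gene '%s' is not in the network component", i))
  r <- as.integer(r)
  if (length(r) != 1L || is.na(r) || r < 1L || r > oracle$diameter) {
    stop(sprintf("radius must be in 1..%d (the network diameter)", oracle$diameter))
  }
  di <- oracle$d[i, ]
  out <- oracle$nodes[di > 0L & di <= r]
  if (!is.null(within)) out <- intersect(out, within)
  out
}

#' Read a network from an edge-list or SIF file
#'
#' Accepts two-column tab/whitespace-delimited edge lists (one edge per line)
#' and three-column SIF (`nodeA  relation  nodeB`; the relation is ignored).
#' Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return a `gene_network`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop(sprintf("network file not found: %s", path))
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no edges")
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  bad <- which(nf != 2L & nf != 3L)
  if (length(bad)) {
    stop(sprintf("malformed edge record on line %d: '%s' (expected 2 endpoints)",
                 bad[1L], lines[bad[1L]]))
  }
  edges <- t(vapply(fields, function(f) {
    if (length(f) == 2L) f else f[c(1L, 3L)]  # SIF: drop the relation column
  }, character(2L)))
  gene_network(edges)
}

#' Write a network as a two-column edge list
#' @param net a `gene_network`.
#' @param path output file path.
#' @export
write_network <- function(net, path) {
  el <- igraph::as_edgelist(net$graph)
  writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), path)
  invisible(path)
}
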