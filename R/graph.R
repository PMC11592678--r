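# Graph container, I/O, connectivity queries and the two built-in toy networks.
#
# A "network" throughout the package is a named, undirected, simple igraph
# object. Node labels are opaque strings (numeric-looking labels are never
# coerced); the canonical form of an edge orders its endpoints
# lexicographically on the string labels.

#' Build a validated undirected simple network from an edge table
#'
#' @param u,v character vectors of equal length giving edge endpoints.
#' @param dedupe collapse duplicate (and reversed-duplicate) edges instead of
#'   failing. Default `TRUE`.
#' @return A named undirected simple `igraph` object.
#' @export
#' @examples
#' make_network(c("a", "b"), c("b", "c"))
make_network <- function(u, v, dedupe = TRUE) {
  u <- as.character(u)
  v <- as.character(v)
  if (length(u) != length(v)) stop("endpoint vectors differ in length")
  loops <- u == v
  if (any(loops)) {
    stop("self-loop on node '", u[which(loops)[1]], "' is not allowed")
  }
  key <- edge_key(u, v)
  if (anyDuplicated(key)) {
    if (!dedupe) stop("parallel edges present (e.g. ", key[duplicated(key)][1], ")")
    keep <- !duplicated(key)
    u <- u[keep]
    v <- v[keep]
  }
  g <- igraph::graph_from_edgelist(cbind(u, v), directed = FALSE)
  validate_network(g)
  g
}

#' Validate the network contract
#'
#' Checks that a graph is a named, undirected, simple igraph object with at
#' least one node. All user-facing functions call this on entry.
#'
#' @param g an igraph object.
#' @return `g`, invisibly.
#' @export
validate_network <- function(g) {
  if (!igraph::is_igraph(g)) stop("not an igraph object")
  if (igraph::is_directed(g)) stop("network must be undirected")
  if (igraph::vcount(g) < 1) stop("network must have at least one node")
  if (is.null(igraph::V(g)$name)) stop("network nodes must be named")
  if (anyDuplicated(igraph::V(g)$name)) stop("node names must be unique")
  if (!igraph::is_simple(g)) stop("network must be simple (no loops or parallel edges)")
  invisible(g)
}

#' Canonical edge key
#'
#' Orders the two endpoint labels lexicographically and joins them with `"|"`.
#' Canonicalization is idempotent and symmetric: `edge_key(u, v) == edge_key(v, u)`.
#'
#' @param u,v character vectors of endpoint labels.
#' @return character vector of canonical keys.
#' @export
edge_key <- function(u, v) {
  u <- as.character(u)
  v <- as.character(v)
  paste(pmin(u, v), pmax(u, v), sep = "|")
}

#' Canonical edge table of a network
#'
#' @param g a validated network.
#' @return data.frame with character columns `u`, `v` (u < v lexicographically),
#'   one row per edge, in igraph edge order.
#' @export
network_edges <- function(g) {
  validate_network(g)
  if (igraph::ecount(g) == 0) {
    return(data.frame(u = character(), v = character(), stringsAsFactors = FALSE))
  }
  en <- igraph::ends(g, igraph::E(g), names = TRUE)
  data.frame(u = pmin(en[, 1], en[, 2]), v = pmax(en[, 1], en[, 2]),
             stringsAsFactors = FALSE)
}

# resolve a user-supplied edge (length-2 vector) to canonical endpoints,
# erroring when absent from the graph
resolve_edge <- function(g, edge) {
  if (length(edge) != 2) stop("an edge is a length-2 vector of node labels")
  i <- as.character(edge[1])
  j <- as.character(edge[2])
  nodes <- igraph::V(g)$name
  if (!(i %in% nodes) || !(j %in% nodes)) {
    stop("edge (", i, ", ", j, "): endpoint not in network")
  }
  if (!igraph::are_adjacent(g, i, j)) {
    stop("edge (", i, ", ", j, ") is not an edge of the network")
  }
  c(i, j)
}

# named adjacency list (character neighbor labels), used by the local indices
adjacency_names <- function(g) {
  al <- igraph::as_adj_list(g, mode = "all")
  nodes <- igraph::V(g)$name
  out <- lapply(al, function(x) nodes[as.integer(x)])
  names(out) <- nodes
  out
}

#' Read a network from an edge-list (or GraphML/GML) file
#'
#' Plain-text edge lists have one edge per line: two whitespace- (or
#' `delimiter`-) separated node labels; extra tokens are ignored, lines
#' beginning with `#` are comments. Files ending in `.graphml` or `.gml` are
#' read with the corresponding igraph reader instead.
#'
#' Duplicate lines (including reversed duplicates) collapse to a single edge
#' when `dedupe = TRUE` (the default) and are an error otherwise. Self-loop
#' lines are always rejected: every index in this package assumes a simple
#' graph.
#'
#' @param path file to read.
#' @param delimiter optional single-character field delimiter; default splits
#'   on runs of spaces/tabs.
#' @param dedupe collapse duplicate edges (default `TRUE`).
#' @return a validated network.
#' @export
load_edge_list <- function(path, delimiter = NULL, dedupe = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("graphml", "gml")) {
    g <- igraph::read_graph(path, format = ext)
    if (igraph::is_directed(g)) g <- igraph::as.undirected(g, mode = "collapse")
    if (is.null(igraph::V(g)$name)) {
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    }
    g <- igraph::simplify(g)
    validate_network(g)
    return(g)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop("no edges in file: ", path)
  split_re <- if (is.null(delimiter)) "[ \t]+" else delimiter
  toks <- strsplit(trimws(lines[idx]), split_re, fixed = FALSE)
  bad <- which(vapply(toks, length, integer(1)) < 2)
  if (length(bad) > 0) {
    stop("malformed edge on line ", idx[bad[1]], ": '", lines[idx[bad[1]]], "'")
  }
  u <- vapply(toks, `[`, character(1), 1)
  v <- vapply(toks, `[`, character(1), 2)
  loops <- which(u == v)
  if (length(loops) > 0) {
    stop("self-loop on line ", idx[loops[1]], ": '", lines[idx[loops[1]]], "'")
  }
  make_network(u, v, dedupe = dedupe)
}

#' Write a network as a plain-text edge list
#'
#' One canonical edge per line (`u v`, endpoints lexicographically ordered).
#' Round-trips with [load_edge_list()] to an identical graph. Optional header
#' lines are written as `#` comments.
#'
#' @param g a validated network.
#' @param path output file.
#' @param header optional character vector of comment lines (without `#`).
#' @export
write_edge_list <- function(g, path, header = NULL) {
  validate_network(g)
  ed <- network_edges(g)
  lines <- character(0)
  if (!is.null(header)) lines <- paste("#", header)
  lines <- c(lines, paste(ed$u, ed$v))
  writeLines(lines, path)
  invisible(path)
}

# Edge lists of the two built-in worked examples. The clustered toy network
# has 13 nodes and 14 edges with a single triangle {1,2,7} whose three edges
# tie two hub-centred communities together; the triangle-free variant drops
# edge (2,7), leaving (1,2) as the unique bridge between the communities.
toy_edges_clustered <- function() {
  rbind(
    c("1", "7"), c("2", "7"), c("1", "4"), c("1", "5"), c("1", "6"),
    c("1", "13"), c("1", "2"), c("2", "8"), c("2", "9"), c("2", "11"),
    c("4", "3"), c("13", "3"), c("9", "10"), c("11", "12")
  )
}

#' Built-in toy network with one triangle across two communities
#'
#' A 13-node, 14-edge sparse network in which the three edges (1,2), (1,7),
#' (2,7) form the only triangle and jointly bridge two hub-centred
#' communities; removing (1,2) together with either of the other two splits
#' the network into two large components. Used throughout the documentation
#' and tests as the worked example where local overlap indices (SN, FN, EN)
#' see the triangle but misrank the true bridge (1,2), which only the hybrid
#' index ranks first.
#'
#' @return a validated 13-node network.
#' @export
#' @examples
#' g <- toy_clustered_network()
#' igraph::vcount(g); igraph::ecount(g)
toy_clustered_network <- function() {
  e <- toy_edges_clustered()
  make_network(e[, 1], e[, 2])
}

#' Built-in triangle-free toy network
#'
#' The same 13-node network as [toy_clustered_network()] minus edge (2,7):
#' 13 edges and no triangle. Every neighborhood-overlap index (SN, FN, EN) is
#' identically zero here, so only path-based (global) information can rank the
#' bridge (1,2) first.
#'
#' @return a validated 13-node network.
#' @export
toy_triangle_free_network <- function() {
  e <- toy_edges_clustered()
  keep <- !(e[, 1] == "2" & e[, 2] == "7")
  make_network(e[keep, 1], e[keep, 2])
}

#' Connected components as a node partition
#'
#' @param g a validated network.
#' @return a list of character vectors, one per component, ordered by
#'   decreasing size (ties by smallest member label); every node appears in
#'   exactly one component.
#' @export
connected_components <- function(g) {
  validate_network(g)
  memb <- igraph::components(g)$membership
  comps <- split(names(memb), memb)
  comps <- lapply(comps, sort)
  ord <- order(-vapply(comps, length, integer(1)),
               vapply(comps, `[`, character(1), 1))
  unname(comps[ord])
}

#' Fraction of nodes in the largest connected component
#'
#' The connectivity-degradation statistic: the size of the largest component
#' divided by `total_nodes`, the node count of the *original* (pre-removal)
#' network. Isolated nodes count as components of size 1.
#'
#' @param g a validated network (possibly a percolation remnant).
#' @param total_nodes normalizing node count; defaults to `vcount(g)`.
#' @return a fraction in `(0, 1]`.
#' @export
largest_component_fraction <- function(g, total_nodes = igraph::vcount(g)) {
  validate_network(g)
  if (total_nodes < 1) stop("total_nodes must be a positive integer")
  mx <- max(igraph::components(g)$csize)
  if (total_nodes < mx) stop("total_nodes smaller than the largest component")
  mx / total_nodes
}

#' Single-source geodesic counts (BFS)
#'
#' Breadth-first search from `source` recording, for every node, the geodesic
#' distance, the number of distinct shortest paths from the source, and the
#' set of predecessors on those paths. Unreachable nodes have `NA` distance
#' and count. This is the per-source table that dependency accumulation (see
#' [edge_betweenness()]) is built on.
#'
#' @param g a validated network.
#' @param source a node label.
#' @return a list of class `"path_count_table"` with elements `source`,
#'   `dist` (named integer, `NA` = unreachable), `sigma` (named numeric path
#'   counts, `NA` = unreachable) and `predecessors` (named list of character
#'   vectors).
#' @export
shortest_path_counts <- function(g, source) {
  validate_network(g)
  nodes <- igraph::V(g)$name
  s <- match(as.character(source), nodes)
  if (is.na(s)) stop("unknown source node '", source, "'")
  n <- length(nodes)
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  dist <- rep(NA_integer_, n)
  sigma <- rep(0, n)
  preds <- vector("list", n)
  dist[s] <- 0L
  sigma[s] <- 1
  queue <- integer(n)
  queue[1] <- s
  qhead <- 1L
  qtail <- 1L
  while (qhead <= qtail) {
    v <- queue[qhead]
    qhead <- qhead + 1L
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        qtail <- qtail + 1L
        queue[qtail] <- w
      }
      if (!is.na(dist[w]) && dist[w] == dist[v] + 1L) {
        sigma[w] <- sigma[w] + sigma[v]
        preds[[w]] <- c(preds[[w]], v)
      }
    }
  }
  sigma[is.na(dist)] <- NA_real_
  names(dist) <- nodes
  names(sigma) <- nodes
  predecessors <- lapply(preds, function(p) if (is.null(p)) character(0) else nodes[p])
  names(predecessors) <- nodes
  structure(list(source = nodes[s], dist = dist, sigma = sigma,
                 predecessors = predecessors),
            class = "path_count_table")
}

#' @export
print.path_count_table <- function(x, ...) {
  reach <- sum(!is.na(x$dist))
  cat("Geodesic counts from node '", x$source, "': ", reach, " reachable node(s), ",
      "eccentricity ", max(x$dist, na.rm = TRUE), "\n", sep = "")
  invisible(x)
}
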