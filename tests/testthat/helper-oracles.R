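# Shared fixtures and independent oracles for the test suite.
# The oracles deliberately avoid the package's own computation paths:
# betweenness is recomputed by enumerating every geodesic with
# igraph::all_shortest_paths, geodesic counts by exhaustive path search, and
# the motif metric by a from-scratch subset classifier.

random_network <- function(n, p, seed) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

# seeded wrapper so helper calls stay reproducible without touching callers' RNG
seeded_random_network <- function(n, p, seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  random_network(n, p, seed)
}

all_geodesics <- function(g, from, to) {
  p <- igraph::all_shortest_paths(g, from = from, to = to)
  if (!is.null(p$res)) p$res else p$vpaths
}

# brute-force pair-normalized edge betweenness: enumerate every geodesic of
# every unordered pair and tally the per-pair fraction using each edge
brute_force_eb <- function(g) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  ed <- critedge::network_edges(g)
  keys <- critedge::edge_key(ed$u, ed$v)
  acc <- stats::setNames(numeric(length(keys)), keys)
  if (n >= 2) {
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        paths <- suppressWarnings(all_geodesics(g, nodes[a], nodes[b]))
        if (length(paths) == 0) next
        npaths <- length(paths)
        for (pth in paths) {
          vs <- igraph::as_ids(pth)
          if (length(vs) < 2) next
          ek <- critedge::edge_key(vs[-length(vs)], vs[-1])
          for (k in ek) acc[k] <- acc[k] + 1 / npaths
        }
      }
    }
  }
  acc / (n * (n - 1) / 2)
}

# exhaustive geodesic count from `source` to every node (DFS over all simple
# paths of minimal length), independent of the BFS/sigma machinery
brute_force_sigma <- function(g, source) {
  nodes <- igraph::V(g)$name
  d <- igraph::distances(g, v = source)[1, nodes]
  vapply(nodes, function(t) {
    if (t == source) return(1)
    if (!is.finite(d[t])) return(NA_real_)
    length(all_geodesics(g, source, t))
  }, numeric(1))
}

# independent motif-based edge importance: classify every 4-subset containing
# both endpoints by its induced edge count/pattern, and recompute the mean
# path lengths from an explicitly rebuilt contracted edge list
brute_force_ei <- function(g, i, j) {
  nodes <- igraph::V(g)$name
  amat <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  rownames(amat) <- colnames(amat) <- nodes
  others <- setdiff(nodes, c(i, j))
  tri <- 0L; emptyq <- 0L; diag_out <- 0L; diag_in <- 0L; fullq <- 0L
  for (u in others) if (amat[i, u] == 1 && amat[j, u] == 1) tri <- tri + 1L
  if (length(others) >= 2) {
    prs <- utils::combn(others, 2)
    for (k in seq_len(ncol(prs))) {
      u <- prs[1, k]; w <- prs[2, k]
      sub <- amat[c(i, j, u, w), c(i, j, u, w)]
      ne <- sum(sub) / 2
      deg_in_sub <- rowSums(sub)
      if (ne == 6) fullq <- fullq + 1L
      else if (ne == 5) {
        # K4 minus one edge; the chord joins the two degree-3 vertices
        chord_pair <- names(deg_in_sub)[deg_in_sub == 3]
        if (setequal(chord_pair, c(i, j))) diag_in <- diag_in + 1L
        else diag_out <- diag_out + 1L
      } else if (ne == 4 && all(deg_in_sub == 2)) {
        emptyq <- emptyq + 1L  # 4-cycle; contains edge (i,j) since amat[i,j]=1
      }
    }
  }
  ki <- sum(amat[i, ]); kj <- sum(amat[j, ])
  denom <- max(min(ki, kj) - 1, 0) + 4 * (ki - 1) * (kj - 1)
  if (denom == 0) return(0)
  mean_geo <- function(edges_u, edges_v, vnames) {
    gg <- igraph::graph_from_edgelist(cbind(edges_u, edges_v), directed = FALSE)
    gg <- igraph::simplify(gg)
    miss <- setdiff(vnames, igraph::V(gg)$name)
    if (length(miss)) gg <- igraph::add_vertices(gg, length(miss), name = miss)
    dm <- igraph::distances(gg)
    vals <- dm[upper.tri(dm)]
    mean(vals[is.finite(vals)])
  }
  ed <- critedge::network_edges(g)
  L <- mean_geo(ed$u, ed$v, nodes)
  cu <- ifelse(ed$u == j, i, ed$u)
  cv <- ifelse(ed$v == j, i, ed$v)
  keep <- cu != cv
  Lp <- if (sum(keep) == 0 || length(nodes) <= 2) 0 else
    mean_geo(cu[keep], cv[keep], setdiff(nodes, j))
  (tri + emptyq + diag_out + diag_in + fullq) / denom * abs(L - Lp)
}

expect_score <- function(tab, u, v, expected, tol = 1e-10) {
  key <- critedge::edge_key(u, v)
  got <- tab$score[critedge::edge_key(tab$u, tab$v) == key]
  expect_length(got, 1)
  expect_equal(got, expected, tolerance = tol)
}
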