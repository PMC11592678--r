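# Edge betweenness by Brandes-style dependency accumulation.
#
# For every unordered node pair {s,t} each edge receives the fraction of the
# s-t geodesics that traverse it; the per-edge total is divided by
# N(N-1)/2 so scores live in [0,1]. Pairs in different components contribute
# nothing, while N stays the full node count. Accumulation runs one BFS per
# source and sweeps the shortest-path DAG level by level (vectorized within a
# level), so the whole edge set is scored in one O(N*E) pass.

brandes_accumulate <- function(g) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (m == 0) return(numeric(0))
  en <- igraph::ends(g, igraph::E(g), names = FALSE)
  src <- c(en[, 1], en[, 2])
  dst <- c(en[, 2], en[, 1])
  eid <- c(seq_len(m), seq_len(m))
  f <- factor(src, levels = seq_len(n))
  adj_nb <- split(dst, f)
  adj_eid <- split(eid, f)

  eb <- numeric(m)
  dist <- integer(n)
  sigma <- numeric(n)
  delta <- numeric(n)
  queue <- integer(n)
  dag_v <- integer(2L * m)
  dag_w <- integer(2L * m)
  dag_e <- integer(2L * m)

  for (s in seq_len(n)) {
    dist[] <- -1L
    sigma[] <- 0
    dist[s] <- 0L
    sigma[s] <- 1
    queue[1] <- s
    qhead <- 1L
    qtail <- 1L
    nd <- 0L
    while (qhead <= qtail) {
      v <- queue[qhead]
      qhead <- qhead + 1L
      nbs <- adj_nb[[v]]
      if (length(nbs) == 0) next
      eids <- adj_eid[[v]]
      newly <- dist[nbs] < 0L
      if (any(newly)) {
        nw <- nbs[newly]
        dist[nw] <- dist[v] + 1L
        queue[(qtail + 1L):(qtail + length(nw))] <- nw
        qtail <- qtail + length(nw)
      }
      on_path <- dist[nbs] == dist[v] + 1L
      if (any(on_path)) {
        ws <- nbs[on_path]
        sigma[ws] <- sigma[ws] + sigma[v]
        k <- length(ws)
        dag_v[(nd + 1L):(nd + k)] <- v
        dag_w[(nd + 1L):(nd + k)] <- ws
        dag_e[(nd + 1L):(nd + k)] <- eids[on_path]
        nd <- nd + k
      }
    }
    if (nd == 0L) next
    delta[] <- 0
    dv <- dag_v[seq_len(nd)]
    dw <- dag_w[seq_len(nd)]
    de <- dag_e[seq_len(nd)]
    lev <- dist[dw]
    for (L in sort(unique(lev), decreasing = TRUE)) {
      sel <- lev == L
      contrib <- sigma[dv[sel]] / sigma[dw[sel]] * (1 + delta[dw[sel]])
      eb[de[sel]] <- eb[de[sel]] + contrib
      agg <- rowsum(contrib, dv[sel])
      ix <- as.integer(rownames(agg))
      delta[ix] <- delta[ix] + agg[, 1]
    }
  }
  # every unordered pair was visited from both endpoints
  eb / 2
}

#' Edge betweenness of every edge (pair-normalized)
#'
#' For each edge, the sum over unordered node pairs \{s,t\} of
#' \eqn{n(s,t,e)/n(s,t)} — the fraction of s-t geodesics using the edge —
#' divided by \eqn{N(N-1)/2}. Unreachable pairs contribute 0; `N` is always
#' the full node count, so scores on disconnected graphs stay comparable.
#'
#' Computed with dependency accumulation over per-source BFS geodesic counts
#' (one pass for all edges), not by per-pair path enumeration.
#'
#' @param g a validated network with at least 2 nodes.
#' @return an [edge_score_table] with method `"EB"`; the unnormalized per-edge
#'   totals (geodesic-fraction sums over unordered pairs) are kept in
#'   `attr(x, "unnormalized")`.
#' @export
#' @examples
#' eb <- edge_betweenness(toy_triangle_free_network())
#' head(rank_edges(eb), 3)  # the bridge (1,2) comes first
edge_betweenness <- function(g) {
  validate_network(g)
  n <- igraph::vcount(g)
  if (n < 2) stop("edge betweenness needs at least 2 nodes")
  raw <- brandes_accumulate(g)
  ed <- network_edges(g)
  tab <- new_edge_score_table(ed$u, ed$v, raw / (n * (n - 1) / 2), method = "EB")
  attr(tab, "unnormalized") <- raw
  tab
}
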