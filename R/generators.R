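# Seeded random-graph generators (ER, BA, WS) and topology summaries,
# so the percolation benchmark is exercisable without external downloads.
# Nodes are labelled "1".."n"; the same (spec, seed) always yields the same
# graph. Each generator restores the caller's RNG state on exit.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(expr)
}

label_nodes <- function(g, n) {
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

#' Erdos-Renyi G(n, p) random graph
#'
#' Each of the n(n-1)/2 node pairs is an edge independently with probability
#' `p`; the expected edge count is binomial, `C(n,2) * p`.
#'
#' @param n number of nodes (>= 1).
#' @param p edge probability in `[0, 1]`.
#' @param seed integer seed; the same seed reproduces the same graph.
#' @return a validated network with nodes `"1"..."n"`.
#' @export
erdos_renyi <- function(n, p, seed = 1L) {
  if (n < 1 || p < 0 || p > 1) stop("invalid ER parameters: need n >= 1, 0 <= p <= 1")
  g <- with_seed(seed, igraph::sample_gnp(n, p))
  validate_network(label_nodes(g, n))
}

#' Barabasi-Albert preferential-attachment graph
#'
#' Growth starts from `m` isolated seed nodes. Each arriving node attaches
#' `m` edges to distinct existing nodes chosen with probability proportional
#' to current degree; the first arrival, facing an all-zero-degree seed set,
#' attaches uniformly (i.e. to all `m` seeds). The edge count is therefore
#' exactly `m * (n - m)` for every seed.
#'
#' @param n number of nodes.
#' @param m edges per arriving node, `1 <= m < n`.
#' @param seed integer seed.
#' @return a validated network with nodes `"1"..."n"`.
#' @export
barabasi_albert <- function(n, m, seed = 1L) {
  if (m < 1 || m >= n) stop("invalid BA parameters: need 1 <= m < n")
  with_seed(seed, {
    total <- m * (n - m)
    eu <- integer(total)
    ev <- integer(total)
    deg <- integer(n)
    k <- 0L
    for (t in (m + 1L):n) {
      existing <- seq_len(t - 1L)
      targets <- if (all(deg[existing] == 0L)) {
        if (length(existing) == m) existing else sample(existing, m)
      } else {
        sample(existing, m, prob = deg[existing])
      }
      idx <- k + seq_len(m)
      eu[idx] <- t
      ev[idx] <- targets
      deg[t] <- deg[t] + m
      deg[targets] <- deg[targets] + 1L
      k <- k + m
    }
    make_network(as.character(eu), as.character(ev), dedupe = FALSE)
  })
}

#' Watts-Strogatz small-world graph
#'
#' A ring lattice in which every node connects to its `k` nearest neighbors
#' (`k/2` on each side); each lattice edge is then rewired with probability
#' `p`, replacing its far endpoint with a uniformly chosen node that is
#' neither the near endpoint nor already adjacent to it. Rewiring preserves
#' the edge count, so E = n*k/2 always.
#'
#' @param n number of nodes.
#' @param k even number of ring neighbors per node, `0 < k < n`.
#' @param p rewiring probability in `[0, 1]`.
#' @param seed integer seed.
#' @return a validated network with nodes `"1"..."n"`.
#' @export
watts_strogatz <- function(n, k, p, seed = 1L) {
  if (k <= 0 || k >= n || k %% 2 != 0) stop("invalid WS parameters: need even k, 0 < k < n")
  if (p < 0 || p > 1) stop("invalid WS parameters: need 0 <= p <= 1")
  with_seed(seed, {
    half <- k %/% 2
    adj <- vector("list", n)  # adjacency sets maintained during rewiring
    eu <- integer(n * half)
    ev <- integer(n * half)
    idx <- 0L
    for (d in seq_len(half)) {
      for (i in seq_len(n)) {
        idx <- idx + 1L
        j <- ((i + d - 1L) %% n) + 1L
        eu[idx] <- i
        ev[idx] <- j
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
    for (e in seq_len(idx)) {
      if (stats::runif(1) < p) {
        i <- eu[e]
        jold <- ev[e]
        cand <- setdiff(seq_len(n), c(i, adj[[i]]))
        if (length(cand) == 0) next  # node saturated, keep the lattice edge
        jnew <- cand[sample.int(length(cand), 1L)]
        ev[e] <- jnew
        adj[[i]] <- c(setdiff(adj[[i]], jold), jnew)
        adj[[jold]] <- setdiff(adj[[jold]], i)
        adj[[jnew]] <- c(adj[[jnew]], i)
      }
    }
    make_network(as.character(eu), as.character(ev), dedupe = FALSE)
  })
}

#' Topology summary of a network
#'
#' The standard per-network descriptors: node count N, edge count E, mean
#' degree \eqn{\langle k \rangle = 2E/N}, clustering coefficient C (average
#' local coefficient, nodes of degree < 2 contributing 0; the global
#' transitivity variant is reported alongside), and degree assortativity r
#' (Pearson correlation of endpoint degrees over edges, counted once in each
#' orientation). On regular graphs the degree variance is zero and r is
#' undefined, reported as `NA`.
#'
#' @param g a validated network with at least 2 nodes.
#' @return a list of class `network_summary` with elements `N`, `E`,
#'   `mean_degree`, `clustering`, `transitivity`, `assortativity`.
#' @export
network_summary <- function(g) {
  validate_network(g)
  N <- igraph::vcount(g)
  if (N < 2) stop("summary needs at least 2 nodes")
  E <- igraph::ecount(g)
  deg <- igraph::degree(g)
  r <- if (stats::var(deg) == 0 || E == 0) NA_real_ else
    suppressWarnings(igraph::assortativity_degree(g, directed = FALSE))
  structure(list(
    N = N, E = E,
    mean_degree = 2 * E / N,
    clustering = igraph::transitivity(g, type = "localaverage", isolates = "zero"),
    transitivity = igraph::transitivity(g, type = "global"),
    assortativity = r
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("Network summary: N = ", x$N, ", E = ", x$E,
      ", <k> = ", format(x$mean_degree, digits = 5),
      ", C = ", format(x$clustering, digits = 4),
      ", r = ", if (is.na(x$assortativity)) "undefined (regular graph)"
                else format(x$assortativity, digits = 4), "\n", sep = "")
  invisible(x)
}
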