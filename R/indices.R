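# Edge importance indices.
#
# Per-edge scorers for the local overlap family (FN, SN, EN), the classical
# baselines (DP, BN, DI, EI) and the composite global-local hybrid GLHC.
# All scores follow the convention HIGHER = MORE IMPORTANT; ranked tables are
# sorted descending.

#' Edge score table
#'
#' A data.frame with character columns `u`, `v` (canonical endpoint order) and
#' a numeric `score` column, one row per edge of the scored graph, carrying the
#' scoring `method` and any weight constants as attributes.
#'
#' @param u,v canonical endpoints.
#' @param score numeric scores.
#' @param method method name.
#' @param weights optional named numeric vector of weight constants in force.
#' @return an object of class `edge_score_table`.
#' @export
new_edge_score_table <- function(u, v, score, method, weights = NULL) {
  stopifnot(length(u) == length(v), length(u) == length(score))
  out <- data.frame(u = as.character(u), v = as.character(v),
                    score = as.numeric(score), stringsAsFactors = FALSE)
  structure(out, method = method, weights = weights,
            class = c("edge_score_table", "data.frame"))
}

#' @export
print.edge_score_table <- function(x, n = 6, ...) {
  cat("Edge scores (", attr(x, "method"), "), ", nrow(x), " edges\n", sep = "")
  w <- attr(x, "weights")
  if (!is.null(w)) cat("weights:", paste(names(w), w, sep = "=", collapse = ", "), "\n")
  print.data.frame(head(as.data.frame(x), n), row.names = FALSE)
  if (nrow(x) > n) cat("...\n")
  invisible(x)
}

#' Round scores half-away-from-zero for presentation
#'
#' Scores are always computed and stored at full precision; this helper
#' reproduces the two-decimal presentation used in summary tables (0.375
#' becomes 0.38, never 0.37).
#'
#' @param x numeric vector or an [edge_score_table].
#' @param digits decimal places (default 2).
#' @export
round_half_up <- function(x, digits = 2) {
  if (inherits(x, "edge_score_table")) {
    x$score <- round_half_up(x$score, digits)
    return(x)
  }
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Local neighborhood context of an edge
#'
#' The sets that drive every local index of an edge (i, j):
#' \describe{
#'   \item{`N_i_excl_j`, `N_j_excl_i`}{first-order neighbors of one endpoint
#'     with the other endpoint removed.}
#'   \item{`NN_i_excl_j`, `NN_j_excl_i`}{second-order reachable sets: endpoints
#'     `w != i` of two-step walks `i - u - w` whose intermediate `u` is not
#'     `j`. The far endpoint may be `j` itself or a first-order neighbor of
#'     `i`; only walks *through* `j` are barred. This is the unique reading
#'     under which the published reference scores of the built-in toy network
#'     are reproduced.}
#'   \item{`n_i_ex_j`, `n_j_ex_i`}{counts of neighbors of one endpoint
#'     (excluding the other) that are not adjacent to the other; the
#'     ingredients of diffusion intensity.}
#' }
#'
#' @param g a validated network.
#' @param edge length-2 vector of node labels; must be an edge of `g`.
#' @return a list of class `edge_local_context`.
#' @export
local_context <- function(g, edge) {
  validate_network(g)
  e <- resolve_edge(g, edge)
  i <- e[1]; j <- e[2]
  adj <- adjacency_names(g)
  Ni <- setdiff(adj[[i]], j)
  Nj <- setdiff(adj[[j]], i)
  two_step <- function(from, via_excl, nbrs) {
    if (length(nbrs) == 0) return(character(0))
    setdiff(unique(unlist(adj[nbrs], use.names = FALSE)), from)
  }
  structure(list(
    i = i, j = j,
    N_i_excl_j = sort(Ni),
    N_j_excl_i = sort(Nj),
    NN_i_excl_j = sort(two_step(i, j, Ni)),
    NN_j_excl_i = sort(two_step(j, i, Nj)),
    n_i_ex_j = sum(!(Ni %in% adj[[j]])),
    n_j_ex_i = sum(!(Nj %in% adj[[i]]))
  ), class = "edge_local_context")
}

#' @export
print.edge_local_context <- function(x, ...) {
  cat("Local context of edge (", x$i, ", ", x$j, ")\n", sep = "")
  cat("  N_{i/j}:", paste(x$N_i_excl_j, collapse = " "), "\n")
  cat("  N_{j/i}:", paste(x$N_j_excl_i, collapse = " "), "\n")
  cat("  NN_{i/j}:", paste(x$NN_i_excl_j, collapse = " "), "\n")
  cat("  NN_{j/i}:", paste(x$NN_j_excl_i, collapse = " "), "\n")
  cat("  n_{i ex j} =", x$n_i_ex_j, ", n_{j ex i} =", x$n_j_ex_i, "\n")
  invisible(x)
}

jaccard <- function(a, b) {
  un <- union(a, b)
  if (length(un) == 0) return(0)  # empty-union convention
  length(intersect(a, b)) / length(un)
}

#' First-order neighborhood index (FN)
#'
#' Jaccard similarity of the endpoints' neighbor sets after removing each
#' other: \eqn{FN(e_{ij}) = |N_{i/j} \cap N_{j/i}| / |N_{i/j} \cup N_{j/i}|},
#' 0 when the union is empty.
#'
#' @inheritParams local_context
#' @return a score in `[0, 1]`.
#' @export
first_order_index <- function(g, edge) {
  ctx <- local_context(g, edge)
  jaccard(ctx$N_i_excl_j, ctx$N_j_excl_i)
}

#' Second-order neighborhood index (SN)
#'
#' Jaccard similarity of the two-step reachable sets of the endpoints, where a
#' two-step walk from one endpoint may not pass *through* the other endpoint
#' as its intermediate node (see [local_context()] for the exact convention).
#' Low SN flags potential inter-community bridges; within the composite
#' indices the score is used with the descending-rank convention shared by
#' every index here.
#'
#' @inheritParams local_context
#' @return a score in `[0, 1]`.
#' @export
second_order_index <- function(g, edge) {
  ctx <- local_context(g, edge)
  jaccard(ctx$NN_i_excl_j, ctx$NN_j_excl_i)
}

#' Enhanced neighborhood index (EN)
#'
#' Weighted combination of the two local overlap indices,
#' \eqn{EN = w_{sn}\,SN + w_{fn}\,FN}, defaulting to the experimentally
#' derived constants \eqn{2\,SN + 3\,FN}.
#'
#' @inheritParams local_context
#' @param w_sn,w_fn non-negative weights (defaults 2 and 3).
#' @return a non-negative score.
#' @export
enhanced_neighborhood <- function(g, edge, w_sn = 2, w_fn = 3) {
  if (w_sn < 0 || w_fn < 0) stop("weights must be non-negative")
  w_sn * second_order_index(g, edge) + w_fn * first_order_index(g, edge)
}

#' Degree product (DP)
#'
#' \eqn{DP(e_{ij}) = k_i k_j}, the product of the endpoint degrees.
#'
#' @inheritParams local_context
#' @export
degree_product <- function(g, edge) {
  validate_network(g)
  e <- resolve_edge(g, edge)
  deg <- igraph::degree(g)
  unname(deg[e[1]] * deg[e[2]])
}

# largest-clique sizes per node and per edge, from one exact maximal-clique
# enumeration (Bron-Kerbosch with pivoting via igraph); exponential worst case,
# intended for desk-scale graphs
clique_size_tables <- function(g) {
  cl <- igraph::max_cliques(g)
  nodes <- igraph::V(g)$name
  node_best <- stats::setNames(rep(1L, length(nodes)), nodes)
  edge_best <- new.env(parent = emptyenv())
  for (memb in cl) {
    nm <- nodes[as.integer(memb)]
    s <- length(nm)
    node_best[nm] <- pmax(node_best[nm], s)
    if (s >= 2) {
      prs <- utils::combn(sort(nm), 2)
      for (k in seq_len(ncol(prs))) {
        key <- paste(prs[1, k], prs[2, k], sep = "|")
        old <- edge_best[[key]]
        if (is.null(old) || old < s) assign(key, s, envir = edge_best)
      }
    }
  }
  list(node = node_best, edge = edge_best)
}

#' Bridgeness (BN)
#'
#' \eqn{BN(e_{ij}) = S_i S_j / S_e}, where \eqn{S_i}, \eqn{S_j} are the sizes
#' of the largest cliques containing each endpoint and \eqn{S_e} the size of
#' the largest clique containing the whole edge. Clique sizes come from exact
#' maximal-clique enumeration (exponential worst case; fine at desk scale).
#'
#' @inheritParams local_context
#' @return a score `>= 1`.
#' @export
bridgeness <- function(g, edge) {
  validate_network(g)
  e <- resolve_edge(g, edge)
  ct <- clique_size_tables(g)
  se <- ct$edge[[paste(min(e), max(e), sep = "|")]]
  unname(ct$node[e[1]] * ct$node[e[2]] / se)
}

#' Diffusion intensity (DI)
#'
#' \eqn{DI(e_{ij}) = (n_{i\,ex\,j} + n_{j\,ex\,i}) / 2}: the mean number of
#' exclusive neighbors — neighbors of one endpoint (other endpoint excluded)
#' not adjacent to the other endpoint.
#'
#' @inheritParams local_context
#' @return a non-negative score.
#' @export
diffusion_intensity <- function(g, edge) {
  ctx <- local_context(g, edge)
  (ctx$n_i_ex_j + ctx$n_j_ex_i) / 2
}

# ---- motif-based edge importance (EI) --------------------------------------

# classify all 4-node motifs containing edge (i,j); adj is adjacency_names(g)
ei_motif_counts <- function(adj, i, j) {
  Ni <- setdiff(adj[[i]], j)
  Nj <- setdiff(adj[[j]], i)
  tri_act <- length(intersect(Ni, Nj))
  empty_q <- 0L; diag_outer <- 0L; diag_inner <- 0L; full_q <- 0L
  cand <- setdiff(union(Ni, Nj), c(i, j))
  if (length(cand) >= 2) {
    prs <- utils::combn(cand, 2)
    for (k in seq_len(ncol(prs))) {
      u <- prs[1, k]; w <- prs[2, k]
      au <- u %in% adj[[i]]; bu <- u %in% adj[[j]]
      aw <- w %in% adj[[i]]; bw <- w %in% adj[[j]]
      uw <- w %in% adj[[u]]
      ne <- au + bu + aw + bw + uw
      if (ne == 5L) {
        full_q <- full_q + 1L                      # K4 through the edge
      } else if (ne == 4L) {
        if (!uw) diag_inner <- diag_inner + 1L     # chord is (i,j) itself
        else diag_outer <- diag_outer + 1L         # (i,j) lies on the 4-cycle
      } else if (ne == 3L && uw &&
                 ((au && bw && !aw && !bu) || (aw && bu && !au && !bw))) {
        empty_q <- empty_q + 1L                    # chordless 4-cycle
      }
    }
  }
  list(tri_act = tri_act, empty_quad_act = empty_q, diag_quad1_act = diag_outer,
       diag_quad2_act = diag_inner, full_quad_act = full_q)
}

mean_path_length_after_contraction <- function(g, i, j) {
  n <- igraph::vcount(g)
  ii <- match(i, igraph::V(g)$name)
  jj <- match(j, igraph::V(g)$name)
  mapping <- seq_len(n)
  mapping[jj] <- ii
  # re-number to consecutive ids as contract() requires
  mapping <- match(mapping, sort(unique(mapping)))
  gc <- igraph::simplify(igraph::contract(g, mapping))
  if (igraph::vcount(gc) < 2) return(0)  # single-node convention
  igraph::mean_distance(gc, unconnected = TRUE)
}

#' Motif components of the edge importance metric (EI)
#'
#' Exhaustive enumeration of the 3- and 4-node motifs containing an edge —
#' triangles, chordless ("empty") 4-cycles, singly chorded ("diagonal")
#' 4-cycles split by whether the edge is the chord (inner) or a cycle edge
#' (outer), and complete 4-cliques — together with degree-based maxima
#' (\eqn{\min(k_i,k_j)-1} for triangles, \eqn{(k_i-1)(k_j-1)} per
#' quadrilateral class) and the mean geodesic distances over connected pairs
#' before (`L`) and after (`L_prime`) contracting the edge (endpoints merged,
#' self-loop dropped, parallel edges collapsed).
#'
#' @inheritParams local_context
#' @return a list of class `ei_components`.
#' @export
ei_components <- function(g, edge) {
  validate_network(g)
  e <- resolve_edge(g, edge)
  adj <- adjacency_names(g)
  act <- ei_motif_counts(adj, e[1], e[2])
  deg <- igraph::degree(g)
  ki <- unname(deg[e[1]]); kj <- unname(deg[e[2]])
  qmax <- (ki - 1) * (kj - 1)
  L <- if (igraph::vcount(g) < 2) 0 else igraph::mean_distance(g, unconnected = TRUE)
  structure(c(act, list(
    tri_max = max(min(ki, kj) - 1, 0),
    empty_quad_max = qmax, diag_quad1_max = qmax,
    diag_quad2_max = qmax, full_quad_max = qmax,
    L = L,
    L_prime = mean_path_length_after_contraction(g, e[1], e[2])
  )), class = "ei_components")
}

#' Edge importance metric (EI)
#'
#' Ratio of realized to maximal motif counts around the edge, scaled by the
#' shift in mean geodesic distance caused by contracting it:
#' \deqn{EI = \frac{N'_\Delta + N'_\alpha + N'_\eta + N'_\beta + N'_\blacksquare}
#'                 {N_\Delta + N_\alpha + N_\eta + N_\beta + N_\blacksquare}
#'            \times |L - L'|}
#' 0 when the maxima sum is 0. See [ei_components()] for the motif classes
#' and conventions; this metric is a comparison baseline and its motif-maxima
#' reading is one concrete, documented choice among several consistent ones.
#'
#' @inheritParams local_context
#' @return a non-negative score.
#' @export
edge_importance_ei <- function(g, edge) {
  comp <- ei_components(g, edge)
  denom <- comp$tri_max + comp$empty_quad_max + comp$diag_quad1_max +
    comp$diag_quad2_max + comp$full_quad_max
  if (denom == 0) return(0)
  num <- comp$tri_act + comp$empty_quad_act + comp$diag_quad1_act +
    comp$diag_quad2_act + comp$full_quad_act
  num / denom * abs(comp$L - comp$L_prime)
}

# ---- composite and dispatcher ----------------------------------------------

# internal: FN and SN for every edge in one pass over a shared adjacency list
all_local_scores <- function(g) {
  adj <- adjacency_names(g)
  ed <- network_edges(g)
  fn <- numeric(nrow(ed))
  sn <- numeric(nrow(ed))
  two_step <- function(from, nbrs) {
    if (length(nbrs) == 0) return(character(0))
    setdiff(unique(unlist(adj[nbrs], use.names = FALSE)), from)
  }
  for (r in seq_len(nrow(ed))) {
    i <- ed$u[r]; j <- ed$v[r]
    Ni <- setdiff(adj[[i]], j)
    Nj <- setdiff(adj[[j]], i)
    fn[r] <- jaccard(Ni, Nj)
    sn[r] <- jaccard(two_step(i, Ni), two_step(j, Nj))
  }
  list(edges = ed, fn = fn, sn = sn)
}

#' Global-local hybrid centrality (GLHC) of every edge
#'
#' The composite index
#' \eqn{GLHC = w_{eb}\,EB + w_{sn}\,SN + w_{fn}\,FN} with default weights
#' (3, 1, 3/2), i.e. \eqn{3\,EB + \tfrac{1}{2}\,EN}. Edge betweenness
#' supplies the global (cross-community) signal and the two overlap indices
#' the local (intra-community) signal; a single betweenness pass is shared
#' across all edges.
#'
#' @param g a validated network with at least 2 nodes.
#' @param w_eb,w_sn,w_fn non-negative weights (defaults 3, 1, 3/2).
#' @return an [edge_score_table] with method `"GLHC"`.
#' @export
#' @examples
#' head(rank_edges(glhc(toy_clustered_network())), 3)
glhc <- function(g, w_eb = 3, w_sn = 1, w_fn = 3 / 2) {
  validate_network(g)
  if (any(c(w_eb, w_sn, w_fn) < 0)) stop("weights must be non-negative")
  eb <- edge_betweenness(g)
  loc <- all_local_scores(g)
  stopifnot(identical(loc$edges$u, eb$u), identical(loc$edges$v, eb$v))
  new_edge_score_table(eb$u, eb$v,
                       w_eb * eb$score + w_sn * loc$sn + w_fn * loc$fn,
                       method = "GLHC",
                       weights = c(w_eb = w_eb, w_sn = w_sn, w_fn = w_fn))
}

#' Score every edge of a network under one method
#'
#' Dispatcher over all implemented edge-importance indices.
#'
#' @param g a validated network.
#' @param method one of `"FN"`, `"SN"`, `"EN"`, `"EB"`, `"DP"`, `"BN"`,
#'   `"DI"`, `"EI"`, `"GLHC"` (case-insensitive).
#' @param ... weight overrides passed to [enhanced_neighborhood()] or [glhc()].
#' @return an [edge_score_table] covering every edge.
#' @export
score_all_edges <- function(g, method, ...) {
  validate_network(g)
  methods <- c("FN", "SN", "EN", "EB", "DP", "BN", "DI", "EI", "GLHC")
  method <- toupper(method)
  if (length(method) != 1 || !(method %in% methods)) {
    stop("unknown method '", method, "'; valid methods: ",
         paste(methods, collapse = ", "))
  }
  if (method == "EB") return(edge_betweenness(g))
  if (method == "GLHC") return(glhc(g, ...))
  ed <- network_edges(g)
  if (method %in% c("FN", "SN", "EN")) {
    loc <- all_local_scores(g)
    w <- list(...)
    w_sn <- if (is.null(w$w_sn)) 2 else w$w_sn
    w_fn <- if (is.null(w$w_fn)) 3 else w$w_fn
    score <- switch(method,
      FN = loc$fn,
      SN = loc$sn,
      EN = w_sn * loc$sn + w_fn * loc$fn)
    weights <- if (method == "EN") c(w_sn = w_sn, w_fn = w_fn) else NULL
    return(new_edge_score_table(ed$u, ed$v, score, method, weights))
  }
  if (method == "DP") {
    deg <- igraph::degree(g)
    return(new_edge_score_table(ed$u, ed$v, unname(deg[ed$u] * deg[ed$v]), "DP"))
  }
  if (method == "BN") {
    ct <- clique_size_tables(g)
    score <- vapply(seq_len(nrow(ed)), function(r) {
      se <- ct$edge[[paste(ed$u[r], ed$v[r], sep = "|")]]
      unname(ct$node[ed$u[r]] * ct$node[ed$v[r]] / se)
    }, numeric(1))
    return(new_edge_score_table(ed$u, ed$v, score, "BN"))
  }
  if (method == "DI") {
    adj <- adjacency_names(g)
    score <- vapply(seq_len(nrow(ed)), function(r) {
      i <- ed$u[r]; j <- ed$v[r]
      Ni <- setdiff(adj[[i]], j)
      Nj <- setdiff(adj[[j]], i)
      (sum(!(Ni %in% adj[[j]])) + sum(!(Nj %in% adj[[i]]))) / 2
    }, numeric(1))
    return(new_edge_score_table(ed$u, ed$v, score, "DI"))
  }
  # EI
  score <- vapply(seq_len(nrow(ed)), function(r) {
    edge_importance_ei(g, c(ed$u[r], ed$v[r]))
  }, numeric(1))
  new_edge_score_table(ed$u, ed$v, score, "EI")
}

#' Write an edge score table (or ranked list) to CSV
#'
#' Columns `node_u`, `node_v`, `score` and, when present, `rank`.
#'
#' @param x an [edge_score_table] or ranked edge list.
#' @param path output file.
#' @param round optional decimal places for presentation rounding
#'   (half-away-from-zero); scores are written at full precision by default.
#' @export
write_scores_csv <- function(x, path, round = NULL) {
  df <- as.data.frame(x)
  names(df)[names(df) == "u"] <- "node_u"
  names(df)[names(df) == "v"] <- "node_v"
  if (!is.null(round)) df$score <- round_half_up(df$score, round)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
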