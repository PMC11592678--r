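# Edge percolation evaluation: rank edges, remove them one by one in ranked
# order, track the largest connected component, and summarize with the
# robustness R and ranking-monotonicity M statistics.

#' Rank edges by descending score
#'
#' Ties are broken deterministically by canonical edge key (ascending) under
#' the default `"canonical"` policy; the `"random"` policy shuffles tied
#' blocks with a seeded RNG for sensitivity analysis.
#'
#' @param scores an [edge_score_table].
#' @param tie_policy `"canonical"` (default) or `"random"`.
#' @param seed RNG seed for the `"random"` policy.
#' @return the score table reordered (most important first) with a `rank`
#'   column, class `ranked_edge_list`. Equal scores share their min rank.
#' @export
rank_edges <- function(scores, tie_policy = c("canonical", "random"), seed = 1L) {
  if (!inherits(scores, "edge_score_table")) stop("scores must be an edge_score_table")
  if (nrow(scores) == 0) stop("empty score table")
  tie_policy <- match.arg(tie_policy)
  if (tie_policy == "canonical") {
    # radix = C-locale collation, identical on every platform
    ord <- order(-scores$score, scores$u, scores$v, method = "radix")
  } else {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    ord <- order(-scores$score, stats::runif(nrow(scores)))
  }
  out <- scores[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$rank <- rank(-out$score, ties.method = "min")
  attr(out, "method") <- attr(scores, "method")
  attr(out, "weights") <- attr(scores, "weights")
  attr(out, "tie_policy") <- tie_policy
  class(out) <- c("ranked_edge_list", "edge_score_table", "data.frame")
  out
}

#' Simulate edge percolation under a fixed removal order
#'
#' Removes the edges of `g` one at a time in the order given (most important
#' first), recording after each removal the fraction \eqn{\xi_l} of nodes in
#' the largest surviving component (relative to the original node count N).
#' The input graph is never mutated. Internally the curve is computed by
#' replaying the removals backwards with a union-find structure, which is
#' exact for a static order and costs nearly linear time in E.
#'
#' @param g a validated network with at least one edge.
#' @param order a [rank_edges()] result, or any data.frame with columns
#'   `u`, `v` forming a permutation of the edge set of `g`.
#' @return a list of class `percolation_curve` with elements `xi` (length E),
#'   `removed_fraction` (`l/E`), `E`, `N` and the removal `method` if known.
#' @export
percolate <- function(g, order) {
  validate_network(g)
  ed <- network_edges(g)
  E <- nrow(ed)
  if (E == 0) stop("network has no edges to percolate")
  if (!is.data.frame(order) || !all(c("u", "v") %in% names(order))) {
    stop("order must be a data.frame with columns u, v")
  }
  okeys <- edge_key(order$u, order$v)
  if (length(okeys) != E || !setequal(okeys, edge_key(ed$u, ed$v)) ||
      anyDuplicated(okeys)) {
    stop("order is not a permutation of the network's edge set")
  }
  nodes <- igraph::V(g)$name
  N <- length(nodes)
  iu <- match(pmin(order$u, order$v), nodes)
  iv <- match(pmax(order$u, order$v), nodes)

  parent <- seq_len(N)
  csize <- rep(1L, N)
  largest <- 1L
  xi <- numeric(E)
  xi[E] <- largest / N       # all edges gone: only singletons
  if (E > 1) {
    for (t in E:2) {         # re-add edges in reverse removal order
      a <- iu[t]
      while (parent[a] != a) { parent[a] <- parent[parent[a]]; a <- parent[a] }
      b <- iv[t]
      while (parent[b] != b) { parent[b] <- parent[parent[b]]; b <- parent[b] }
      if (a != b) {
        if (csize[a] < csize[b]) { tmp <- a; a <- b; b <- tmp }
        parent[b] <- a
        csize[a] <- csize[a] + csize[b]
        if (csize[a] > largest) largest <- csize[a]
      }
      xi[t - 1] <- largest / N
    }
  }
  structure(list(xi = xi, removed_fraction = seq_len(E) / E, E = E, N = N,
                 method = attr(order, "method")),
            class = "percolation_curve")
}

#' @export
print.percolation_curve <- function(x, ...) {
  cat("Percolation curve (", if (is.null(x$method)) "custom order" else x$method,
      "): E = ", x$E, ", N = ", x$N,
      ", R = ", format(mean(x$xi), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Robustness of a removal order
#'
#' \eqn{R = \frac{1}{E} \sum_{l=1}^{E} \xi_l}: the mean largest-component
#' fraction over all removal steps. Lower R means the ranking dismantles the
#' network faster, i.e. identifies critical edges more accurately.
#'
#' @param curve a [percolate()] result.
#' @return a value in `[1/N, 1]`.
#' @export
robustness <- function(curve) {
  if (!inherits(curve, "percolation_curve")) stop("curve must be a percolation_curve")
  if (curve$E == 0) stop("empty curve")
  mean(curve$xi)
}

#' Connectivity degradation curve
#'
#' The percolation curve re-expressed as (fraction of edges removed,
#' largest-component fraction) pairs, with a step-0 anchor for the intact
#' network prepended — suitable for plotting degradation trajectories.
#'
#' @inheritParams percolate
#' @return data.frame with columns `fraction_removed`, `lcc_fraction`.
#' @export
degradation_curve <- function(g, order) {
  validate_network(g)
  curve <- percolate(g, order)
  data.frame(
    fraction_removed = c(0, curve$removed_fraction),
    lcc_fraction = c(largest_component_fraction(g), curve$xi)
  )
}

#' Ranking monotonicity
#'
#' \eqn{M = \left[1 - \frac{\sum_i b_i (b_i - 1)}{E (E - 1)}\right]^2}, where
#' the \eqn{b_i} are the sizes of groups of edges sharing exactly the same
#' score. M is 1 when every edge gets a distinct score and 0 when all scores
#' coincide. Grouping uses the full-precision scores with an absolute
#' tolerance of `tol` (never the 2-decimal presentation values, which would
#' manufacture ties).
#'
#' @param scores an [edge_score_table] with at least 2 edges.
#' @param tol absolute tolerance for score equality (default `1e-9`).
#' @return a list of class `monotonicity_result`: `M`, `tie_group_sizes`, `E`.
#' @export
monotonicity <- function(scores, tol = 1e-9) {
  if (!inherits(scores, "edge_score_table")) stop("scores must be an edge_score_table")
  E <- nrow(scores)
  if (E < 2) stop("monotonicity needs at least 2 edges")
  s <- sort(scores$score, decreasing = TRUE)
  newgrp <- c(TRUE, diff(s) < -tol)
  b <- as.integer(table(cumsum(newgrp)))
  M <- (1 - sum(b * (b - 1)) / (E * (E - 1)))^2
  structure(list(M = M, tie_group_sizes = sort(b, decreasing = TRUE), E = E,
                 method = attr(scores, "method")),
            class = "monotonicity_result")
}

#' @export
print.monotonicity_result <- function(x, ...) {
  cat("Monotonicity M = ", format(x$M, digits = 4), " (", x$E, " edges, ",
      length(x$tie_group_sizes), " distinct score groups)\n", sep = "")
  invisible(x)
}

#' Full percolation evaluation of one scoring method
#'
#' One-shot pipeline: score all edges, rank them once (static ranking),
#' percolate in that order, and report robustness R, monotonicity M and the
#' full curve. An optional `recompute = TRUE` mode re-scores the shrinking
#' graph after every removal (much slower; provided for sensitivity analysis,
#' the standard protocol is the static ranking).
#'
#' @param g a validated network with at least one edge.
#' @param method a method name accepted by [score_all_edges()].
#' @param tie_policy,seed passed to [rank_edges()].
#' @param recompute re-rank after every removal (default `FALSE`).
#' @param ... weight overrides for the scorer.
#' @return a list of class `method_evaluation`: `method`, `R`, `M`, `curve`,
#'   `ranking`, `E`, `N`.
#' @export
evaluate_method <- function(g, method, tie_policy = "canonical", seed = 1L,
                            recompute = FALSE, ...) {
  validate_network(g)
  scores <- score_all_edges(g, method, ...)
  ranking <- rank_edges(scores, tie_policy = tie_policy, seed = seed)
  if (!recompute) {
    curve <- percolate(g, ranking)
  } else {
    curve <- percolate_recompute(g, method, tie_policy, seed, ...)
  }
  M <- if (nrow(scores) >= 2) monotonicity(scores)$M else NA_real_
  structure(list(method = attr(scores, "method"), R = robustness(curve),
                 M = M, curve = curve, ranking = ranking,
                 E = curve$E, N = curve$N,
                 intact = largest_component_fraction(g)),
            class = "method_evaluation")
}

# adaptive variant: re-score the remaining graph before every removal
percolate_recompute <- function(g, method, tie_policy, seed, ...) {
  N <- igraph::vcount(g)
  E <- igraph::ecount(g)
  xi <- numeric(E)
  h <- g
  for (l in seq_len(E)) {
    sc <- score_all_edges(h, method, ...)
    top <- rank_edges(sc, tie_policy = tie_policy, seed = seed)[1, ]
    h <- igraph::delete_edges(h, paste(top$u, top$v, sep = "|"))
    xi[l] <- max(igraph::components(h)$csize) / N
  }
  structure(list(xi = xi, removed_fraction = seq_len(E) / E, E = E, N = N,
                 method = paste0(method, " (recomputed)")),
            class = "percolation_curve")
}

#' @export
print.method_evaluation <- function(x, ...) {
  cat("Method ", x$method, ": R = ", format(x$R, digits = 4),
      ", M = ", format(x$M, digits = 4),
      "  (N = ", x$N, ", E = ", x$E, ")\n", sep = "")
  invisible(x)
}

#' Serialize a method evaluation
#'
#' Writes the degradation curve as CSV (`fraction_removed`, `lcc_fraction`)
#' and a JSON summary `{method, R, M, E, N}`.
#'
#' @param ev an [evaluate_method()] result.
#' @param curve_path,summary_path output files (either may be `NULL` to skip).
#' @export
write_evaluation <- function(ev, curve_path = NULL, summary_path = NULL) {
  if (!inherits(ev, "method_evaluation")) stop("ev must be a method_evaluation")
  if (!is.null(curve_path)) {
    df <- data.frame(fraction_removed = c(0, ev$curve$removed_fraction),
                     lcc_fraction = c(ev$intact, ev$curve$xi))
    utils::write.csv(df, curve_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(summary_path)) {
    jsonlite::write_json(list(method = ev$method, R = ev$R, M = ev$M,
                              E = ev$E, N = ev$N),
                         summary_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(ev)
}
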