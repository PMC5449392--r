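#' The canonical centrality measure names
#'
#' The eleven node centralities used for consensus ranking, in canonical
#' order: degree, closeness, radiality, shortest-path betweenness,
#' current-flow betweenness, current-flow closeness (information
#' centrality), centroid value, PageRank, vulnerability, stress, and
#' eigenvector centrality. The canonical order decides which member of a
#' perfectly correlated group is retained by
#' [prune_redundant_measures()].
#'
#' @return Character vector of the eleven measure names.
#' @export
centrality_measures <- function() {
  c("degree", "closeness", "radiality", "betweenness", "cf_betweenness",
    "cf_closeness", "centroid", "pagerank", "vulnerability", "stress",
    "eigenvector")
}

#' Compute node centralities on a connected gene network
#'
#' Computes per-gene scores for any subset of the eleven canonical
#' centrality measures (see [centrality_measures()]). Definitions, for a
#' connected unweighted graph with `n` nodes, distances `d` in hops and
#' diameter `Delta`:
#'
#' * `degree`: number of neighbours.
#' * `closeness`: `(n - 1) / sum_u d(v, u)`.
#' * `radiality`: `sum_u (Delta + 1 - d(v, u)) / (n - 1)`.
#' * `betweenness`: shortest-path betweenness; each unordered pair `(s, t)`
#'   contributes its pair dependency `sigma_st(v) / sigma_st`.
#' * `cf_betweenness`: Newman's current-flow (random-walk) betweenness via
#'   the Laplacian pseudo-inverse; endpoints of a pair carry throughput 1;
#'   normalized by the number of pairs.
#' * `cf_closeness`: information centrality,
#'   `(n - 1) / sum_t R(v, t)` with `R` the effective resistance.
#' * `centroid`: `min_u (gamma_v(u) - gamma_u(v))` where `gamma_v(u)`
#'   counts nodes strictly closer to `v` than to `u`.
#' * `pagerank`: damping 0.85, uniform teleport.
#' * `vulnerability`: `(E - E_v) / E`, the relative drop in global
#'   efficiency when `v` is removed (`E_v` is averaged over the remaining
#'   `n - 1` nodes, so leaf removal can make it negative).
#' * `stress`: number of shortest paths passing through `v`, over unordered
#'   pairs.
#' * `eigenvector`: principal eigenvector of the adjacency matrix,
#'   nonnegative, L2-normalized (deterministic power iteration on
#'   `A + I`, tolerance 1e-12).
#'
#' Edge scores are used only during network construction; all measures
#' treat the graph as unweighted.
#'
#' @param net A connected `gene_network`.
#' @param measures Character vector, a subset of [centrality_measures()].
#' @return Tibble with a `gene` column and one numeric column per measure,
#'   in canonical measure order.
#' @export
compute_centralities <- function(net, measures = centrality_measures()) {
  g <- as_igraph(net)
  unknown <- setdiff(measures, centrality_measures())
  if (length(unknown) > 0) {
    abort(sprintf("unknown centrality measure(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  measures <- intersect(centrality_measures(), measures)  # canonical order
  if (!igraph::is_connected(g)) {
    abort(paste("network must be connected: closeness, radiality,",
                "current-flow and vulnerability centralities are undefined",
                "on disconnected graphs"))
  }
  n <- igraph::vcount(g)
  genes <- igraph::V(g)$name
  el <- igraph::as_edgelist(g, names = FALSE)
  el0_from <- as.integer(el[, 1] - 1L)
  el0_to <- as.integer(el[, 2] - 1L)

  need_dist <- any(c("closeness", "radiality", "centroid") %in% measures)
  D <- if (need_dist) igraph::distances(g, weights = NA) else NULL
  need_lap <- any(c("cf_betweenness", "cf_closeness") %in% measures)
  Tm <- if (need_lap) laplacian_pinv(g) else NULL

  out <- tibble::tibble(gene = genes)
  for (ms in measures) {
    out[[ms]] <- unname(switch(
      ms,
      degree = as.numeric(igraph::degree(g)),
      closeness = (n - 1) / rowSums(D),
      radiality = (max(D) + 1) - rowSums(D) / (n - 1),
      betweenness = as.numeric(igraph::betweenness(g, directed = FALSE,
                                                   weights = NA)),
      cf_betweenness = cf_betweenness_impl(g, Tm, el0_from, el0_to),
      cf_closeness = cf_closeness_impl(Tm),
      centroid = {
        Di <- D; storage.mode(Di) <- "integer"
        as.numeric(centroid_kernel(Di))
      },
      pagerank = as.numeric(igraph::page_rank(g, damping = 0.85,
                                              weights = NA)$vector),
      vulnerability = as.numeric(vulnerability_kernel(n, el0_from, el0_to)),
      stress = as.numeric(stress_kernel(n, el0_from, el0_to)),
      eigenvector = eigenvector_impl(g)
    ))
  }
  out
}

# Moore-Penrose pseudo-inverse of the graph Laplacian, via the identity
# L^+ = (L + J/n)^{-1} - J/n valid for connected graphs (J = all-ones).
laplacian_pinv <- function(g) {
  n <- igraph::vcount(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  L <- diag(rowSums(A)) - A
  solve(L + 1 / n) - 1 / n
}

# Newman's current-flow betweenness. For a unit s->t current the node
# potentials are phi = T[, s] - T[, t]; the throughput of v not in {s, t}
# is half the absolute current over its incident edges, and endpoints
# carry 1. Summing |phi_v - phi_w| over all pairs for one edge (v, w)
# reduces, with x = T[v, ] - T[w, ] sorted ascending, to
# sum_k x_(k) * (2k - n - 1).
cf_betweenness_impl <- function(g, Tm, from0, to0) {
  n <- nrow(Tm)
  raw <- numeric(n)
  for (e in seq_along(from0)) {
    v <- from0[e] + 1L
    w <- to0[e] + 1L
    x <- sort(Tm[v, ] - Tm[w, ])
    s_e <- sum(x * (2 * seq_len(n) - n - 1))
    raw[v] <- raw[v] + s_e
    raw[w] <- raw[w] + s_e
  }
  (raw / 2 + (n - 1) / 2) / (n * (n - 1) / 2)
}

# Information centrality from effective resistances:
# sum_{t != v} R(v, t) = n * T_vv + trace(T) - 2 * rowSums(T)[v].
cf_closeness_impl <- function(Tm) {
  n <- nrow(Tm)
  (n - 1) / (n * diag(Tm) + sum(diag(Tm)) - 2 * rowSums(Tm))
}

# Principal eigenvector of A, computed by power iteration on A + I (the
# shift guarantees convergence on bipartite graphs); deterministic start.
eigenvector_impl <- function(g, tol = 1e-12, max_iter = 100000L) {
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  n <- nrow(A)
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    v_new <- as.numeric(A %*% v) + v
    v_new <- v_new / sqrt(sum(v_new^2))
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      break
    }
    v <- v_new
  }
  abs(v)  # Perron vector is nonnegative; fix any residual signs
}
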