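#' Build the filtered largest-component gene network
#'
#' Constructs the disease-candidate interaction network: edges are retained
#' when their confidence score is at or above `score_cutoff` and both
#' endpoints belong to the candidate-gene `universe`; self-loops are
#' dropped; parallel edges are collapsed keeping the maximum score (the
#' strongest evidence for the interaction); finally the largest connected
#' component of the surviving graph is selected. A size tie between
#' components is broken in favour of the component containing the
#' lexicographically smallest gene identifier.
#'
#' @param interactions Tibble of scored interactions with columns `gene_a`,
#'   `gene_b`, `score` (see [read_interactions()]).
#' @param universe Character vector of candidate gene identifiers.
#' @param score_cutoff Minimum confidence score, in `[0, 1]`. The study
#'   default of 0.63 corresponds to the second quartile of the HIPPIE score
#'   distribution.
#' @return A `gene_network` object: the connected simple graph plus its
#'   edge table (`gene_a`, `gene_b`, `score`).
#' @export
#' @examples
#' ints <- tibble::tibble(gene_a = c("a", "b", "d"), gene_b = c("b", "c", "e"),
#'                        score = c(0.9, 0.8, 0.7))
#' build_network(ints, universe = letters[1:5], score_cutoff = 0.63)
build_network <- function(interactions, universe, score_cutoff = 0.63) {
  assert_fraction(score_cutoff, "score_cutoff", closed_zero = TRUE)
  if (length(universe) == 0) abort("`universe` must be non-empty")
  assert_genes(universe, "universe")
  ed <- tibble::as_tibble(interactions)
  if (!all(c("gene_a", "gene_b", "score") %in% names(ed))) {
    abort("`interactions` needs columns gene_a, gene_b, score")
  }
  ed <- dplyr::filter(ed,
                      .data$score >= score_cutoff,
                      .data$gene_a %in% universe,
                      .data$gene_b %in% universe,
                      .data$gene_a != .data$gene_b)
  if (nrow(ed) == 0) abort("no edges survive the score cutoff and universe filter")
  # collapse parallel edges on the unordered pair, keeping the maximum score
  ed <- dplyr::mutate(ed,
                      lo = pmin(.data$gene_a, .data$gene_b),
                      hi = pmax(.data$gene_a, .data$gene_b))
  ed <- dplyr::summarise(dplyr::group_by(ed, .data$lo, .data$hi),
                         score = max(.data$score), .groups = "drop")
  g <- igraph::graph_from_data_frame(
    data.frame(from = ed$lo, to = ed$hi, score = ed$score),
    directed = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  big <- which(sizes == max(sizes))
  if (length(big) > 1) {
    # deterministic tie-break: component holding the smallest gene id
    first_gene <- vapply(big, function(ci) {
      min(igraph::V(g)$name[comp$membership == ci])
    }, "")
    big <- big[order(first_gene)[1]]
  }
  keep <- igraph::V(g)$name[comp$membership == big]
  g <- igraph::induced_subgraph(g, keep)
  ed <- dplyr::filter(ed, .data$lo %in% keep & .data$hi %in% keep)
  new_gene_network(g, dplyr::rename(ed, gene_a = "lo", gene_b = "hi"),
                   score_cutoff)
}

new_gene_network <- function(graph, edges, score_cutoff) {
  structure(list(graph = graph,
                 edges = dplyr::arrange(edges, .data$gene_a, .data$gene_b),
                 score_cutoff = score_cutoff),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d genes, %d interactions (score >= %s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              format(x$score_cutoff)))
  invisible(x)
}

#' Genes and edges of a gene network
#'
#' @param net A `gene_network`.
#' @return `network_genes()`: character vector of gene identifiers in the
#'   network; `network_edges()`: tibble of edges with retained scores.
#' @export
network_genes <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  igraph::V(net$graph)$name
}

#' @rdname network_genes
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  net$edges
}

#' Write a network as a simple three-column TSV
#'
#' @param net A `gene_network`.
#' @param path Output path.
#' @param header Optional `#`-prefixed header lines to prepend.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, header = NULL) {
  stopifnot(inherits(net, "gene_network"))
  writeLines(if (is.null(header)) character() else paste0("# ", header), path)
  readr::write_tsv(network_edges(net), path, col_names = FALSE, append = TRUE)
  invisible(path)
}

as_igraph <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  net$graph
}

#' Summarize the topology of a connected gene network
#'
#' Computes the eight whole-network descriptors used to characterize
#' scale-free disease-gene networks: mean degree, diameter and mean
#' shortest-path distance (unweighted hops), edge density, modularity of a
#' greedy modularity-maximizing partition, global efficiency (mean inverse
#' distance over ordered node pairs), mean local clustering coefficient
#' (zero for degree < 2 nodes), and the fitted power-law exponent of the
#' degree distribution (see [fit_power_law()]; `NA` with a warning when
#' fewer than three distinct degrees support the fit).
#'
#' @param net A connected `gene_network` with at least two nodes.
#' @param seed Integer seed fixed before community detection, so the
#'   partition (and hence modularity) is reproducible.
#' @return One-row tibble with columns `average_degree`, `diameter`,
#'   `average_distance`, `density`, `modularity`, `global_efficiency`,
#'   `average_clustering`, `powerlaw_exponent`.
#' @export
summarize_topology <- function(net, seed = 1L) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (n < 2) abort("need at least two nodes")
  if (!igraph::is_connected(g)) abort("network must be connected")
  D <- igraph::distances(g, weights = NA)
  off <- D[upper.tri(D)]
  set.seed(seed)
  cl <- igraph::cluster_fast_greedy(g, weights = NULL)
  expfit <- tryCatch(fit_power_law(degree_distribution_tbl(net))$exponent,
                     error = function(e) {
                       warn(paste("power-law fit skipped:", conditionMessage(e)))
                       NA_real_
                     })
  tibble::tibble(
    average_degree = 2 * m / n,
    diameter = max(off),
    average_distance = mean(off),
    density = 2 * m / (n * (n - 1)),
    modularity = igraph::modularity(cl),
    global_efficiency = mean(1 / off),
    average_clustering = igraph::transitivity(g, type = "localaverage",
                                              isolates = "zero"),
    powerlaw_exponent = expfit
  )
}

#' Empirical degree distribution of a network
#'
#' @param net A `gene_network`.
#' @return Tibble with columns `degree` and `fraction` (of nodes), one row
#'   per observed degree.
#' @export
degree_distribution_tbl <- function(net) {
  deg <- igraph::degree(as_igraph(net))
  tab <- table(deg)
  tibble::tibble(degree = as.numeric(names(tab)),
                 fraction = as.numeric(tab) / length(deg))
}

#' Fit a power-law exponent to a degree distribution
#'
#' Fits `P(K) = c * K^-gamma` by ordinary least squares on
#' `(log K, log P(K))` over degrees with positive frequency, the method
#' class used to display straight-line fits on log-log degree plots.
#' Degrees with zero frequency are excluded; at least three support points
#' are required.
#'
#' @param degree_histogram Tibble with columns `degree` and `fraction`
#'   (see [degree_distribution_tbl()]), or a named numeric vector mapping
#'   degree to fraction.
#' @return A `powerlaw_fit` object with elements `exponent` (gamma),
#'   `intercept` (log c), `model` (the underlying `lm`), and `data`.
#'   [tidy()] and [glance()] methods are provided.
#' @export
#' @examples
#' h <- tibble::tibble(degree = 1:5, fraction = (1:5)^-2 / sum((1:5)^-2))
#' fit_power_law(h)$exponent  # 2
fit_power_law <- function(degree_histogram) {
  if (is.numeric(degree_histogram) && !is.null(names(degree_histogram))) {
    degree_histogram <- tibble::tibble(
      degree = as.numeric(names(degree_histogram)),
      fraction = as.numeric(degree_histogram))
  }
  h <- tibble::as_tibble(degree_histogram)
  if (!all(c("degree", "fraction") %in% names(h))) {
    abort("`degree_histogram` needs columns degree and fraction")
  }
  h <- dplyr::filter(h, .data$fraction > 0, .data$degree > 0)
  if (nrow(h) < 3) abort("need at least three degrees with positive frequency")
  fit <- lm(log(fraction) ~ log(degree), data = h)
  structure(list(exponent = -unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 model = fit,
                 data = h),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> gamma = %.4f over %d degrees\n",
              x$exponent, nrow(x$data)))
  invisible(x)
}

#' @rdname fit_power_law
#' @param x A `powerlaw_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.powerlaw_fit <- function(x, ...) {
  tibble::tibble(term = c("log_intercept", "exponent"),
                 estimate = c(x$intercept, x$exponent))
}

#' @rdname fit_power_law
#' @exportS3Method generics::glance
glance.powerlaw_fit <- function(x, ...) {
  tibble::tibble(exponent = x$exponent,
                 r_squared = summary(x$model)$r.squared,
                 n_support = nrow(x$data))
}
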