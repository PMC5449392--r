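#' Rank genes by centrality scores
#'
#' Converts a gene-by-measure score table into two rank tables, with rank 1
#' assigned to the highest score:
#'
#' * fractional ranks: tied scores share the mean of their rank positions
#'   (these feed rank correlation);
#' * ordinal ranks: a strict permutation of `1..n`, ties broken by
#'   ascending gene identifier (these feed top-k selection and the
#'   consensus sum, which need a total order because several measures --
#'   degree, centroid -- take few unique values).
#'
#' @param scores Tibble with a `gene` column and one numeric column per
#'   measure (see [compute_centralities()]).
#' @return A `centrality_ranks` object: list with `fractional` and
#'   `ordinal` tibbles shaped like `scores`, plus `scores` itself.
#' @export
rank_table <- function(scores) {
  scores <- tibble::as_tibble(scores)
  if (!"gene" %in% names(scores)) abort("`scores` needs a `gene` column")
  if (anyDuplicated(scores$gene)) abort("duplicate gene identifiers")
  meas <- setdiff(names(scores), "gene")
  if (length(meas) == 0) abort("no measure columns")
  frac <- ord <- scores["gene"]
  for (ms in meas) {
    x <- scores[[ms]]
    if (!is.numeric(x) || any(!is.finite(x))) {
      abort(sprintf("non-finite scores in measure '%s'", ms))
    }
    frac[[ms]] <- rank(-x, ties.method = "average")
    ord[[ms]] <- order(order(-x, scores$gene))
  }
  structure(list(fractional = frac, ordinal = ord, scores = scores),
            class = "centrality_ranks")
}

#' @export
print.centrality_ranks <- function(x, ...) {
  cat(sprintf("<centrality_ranks> %d genes x %d measures\n",
              nrow(x$ordinal), ncol(x$ordinal) - 1))
  invisible(x)
}

#' Spearman rank correlation of two rankings
#'
#' For tie-free rankings this is `rho = 1 - 6 * sum(d^2) / (n (n^2 - 1))`
#' with `d` the per-gene rank difference; with ties it is computed as the
#' product-moment correlation of the fractional rank vectors, to which the
#' printed formula reduces in the tie-free case. The sums are evaluated
#' directly (not via [stats::cor()]), so library routines can serve as an
#' independent check.
#'
#' @param ranks_a,ranks_b Numeric vectors of fractional ranks over the same
#'   genes, in the same order.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
#' @examples
#' spearman_rho(c(1, 2, 3), c(3, 2, 1))  # -1
spearman_rho <- function(ranks_a, ranks_b) {
  if (length(ranks_a) != length(ranks_b)) abort("rank vectors differ in length")
  n <- length(ranks_a)
  if (n < 2) abort("need at least two genes")
  if (anyNA(ranks_a) || anyNA(ranks_b)) abort("missing ranks")
  va <- sum((ranks_a - mean(ranks_a))^2)
  vb <- sum((ranks_b - mean(ranks_b))^2)
  if (va == 0 || vb == 0) {
    abort("rank correlation undefined for a constant ranking")
  }
  no_ties <- !anyDuplicated(ranks_a) && !anyDuplicated(ranks_b)
  if (no_ties) {
    1 - 6 * sum((ranks_a - ranks_b)^2) / (n * (n^2 - 1))
  } else {
    sum((ranks_a - mean(ranks_a)) * (ranks_b - mean(ranks_b))) / sqrt(va * vb)
  }
}

#' Pairwise rank-correlation matrix of centrality measures
#'
#' Applies [spearman_rho()] to every pair of measures' fractional ranks.
#'
#' @param ranks A `centrality_ranks` object (see [rank_table()]).
#' @return Symmetric numeric matrix with unit diagonal, measures in
#'   canonical order as row/column names.
#' @export
rank_correlation_matrix <- function(ranks) {
  stopifnot(inherits(ranks, "centrality_ranks"))
  fr <- ranks$fractional
  meas <- setdiff(names(fr), "gene")
  k <- length(meas)
  rho <- diag(1, k)
  dimnames(rho) <- list(meas, meas)
  if (k > 1) {
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        rho[i, j] <- rho[j, i] <- spearman_rho(fr[[meas[i]]], fr[[meas[j]]])
      }
    }
  }
  rho
}

#' Drop perfectly rank-correlated centrality measures
#'
#' Groups measures that are pairwise rank-correlated at or above
#' `threshold` (grouping is transitive) and keeps only the first member of
#' each group in canonical order (see [centrality_measures()]). With the
#' default exact threshold, closeness and radiality collapse on every
#' connected graph -- both rankings are monotone in a node's total
#' distance -- reducing the canonical eleven measures to ten.
#'
#' @param rho Correlation matrix from [rank_correlation_matrix()].
#' @param threshold Correlation at or above which two measures are
#'   considered redundant, in `(0, 1]`; default `1.0` (a small numerical
#'   tolerance of 1e-12 absorbs floating-point error in exact ties).
#' @return Character vector of retained measure names, canonical order.
#' @export
prune_redundant_measures <- function(rho, threshold = 1.0) {
  assert_fraction(threshold, "threshold")
  meas <- rownames(rho)
  k <- length(meas)
  redundant <- (rho >= threshold - 1e-12)
  gr <- igraph::graph_from_adjacency_matrix(redundant, mode = "undirected",
                                            diag = FALSE)
  member <- igraph::components(gr)$membership
  keep <- !duplicated(member)  # first of each group in row (canonical) order
  meas[keep]
}

#' Rank-sum consensus ranking
#'
#' Sums each gene's ordinal ranks over the retained measures and orders
#' genes by ascending rank sum (rank-by-rank consensus scoring: combining
#' ordinal ranks needs no cross-measure normalization and no measure can
#' dominate). Ties in the rank sum are broken by ascending gene
#' identifier.
#'
#' @param ranks A `centrality_ranks` object.
#' @param measures Measures to include (default: all columns present);
#'   typically the output of [prune_redundant_measures()].
#' @return A `consensus_ranking` tibble with columns `gene`, `rank_sum`,
#'   `consensus_rank`, sorted by `consensus_rank`.
#' @export
consensus_ranking <- function(ranks, measures = NULL) {
  stopifnot(inherits(ranks, "centrality_ranks"))
  ord <- ranks$ordinal
  have <- setdiff(names(ord), "gene")
  measures <- measures %||% have
  missing <- setdiff(measures, have)
  if (length(missing) > 0) {
    abort(sprintf("measures not present in ranks: %s",
                  paste(missing, collapse = ", ")))
  }
  if (length(measures) == 0) abort("need at least one measure")
  out <- tibble::tibble(
    gene = ord$gene,
    rank_sum = rowSums(as.matrix(ord[measures]))
  )
  out <- dplyr::arrange(out, .data$rank_sum, .data$gene)
  out$consensus_rank <- seq_len(nrow(out))
  class(out) <- c("consensus_ranking", class(out))
  out
}

#' Select the top-ranked fraction of genes
#'
#' Returns the first `k` genes of a ranking, where `k` is `fraction * n`
#' under the chosen size policy (`"round"`, half-up, the default; or
#' `"floor"`).
#'
#' @param ranking A `consensus_ranking`, or a tibble with `gene` plus one
#'   rank column, or a named numeric vector of ordinal ranks.
#' @param fraction Proportion of genes to keep, in `(0, 1]`.
#' @param policy Size policy, `"round"` or `"floor"`.
#' @return Character vector of the selected genes in rank order.
#' @export
select_top_fraction <- function(ranking, fraction, policy = c("round", "floor")) {
  policy <- match.arg(policy)
  assert_fraction(fraction, "fraction")
  if (is.numeric(ranking) && !is.null(names(ranking))) {
    genes <- names(ranking)[order(ranking, names(ranking))]
  } else {
    tb <- tibble::as_tibble(ranking)
    if (!"gene" %in% names(tb)) abort("`ranking` needs a `gene` column")
    rank_col <- if ("consensus_rank" %in% names(tb)) "consensus_rank" else {
      cols <- setdiff(names(tb), c("gene", "rank_sum"))
      if (length(cols) != 1) abort("cannot identify the rank column")
      cols
    }
    genes <- tb$gene[order(tb[[rank_col]], tb$gene)]
  }
  n <- length(genes)
  k <- switch(policy, round = size_round(fraction * n), floor = floor(fraction * n))
  if (k < 1) abort("selection is empty at this fraction")
  genes[seq_len(k)]
}
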