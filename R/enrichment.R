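#' Two-list over-representation analysis against an ontology
#'
#' For each ontology term annotated (after propagation) to at least one
#' target gene, computes the hypergeometric upper-tail probability of
#' observing at least `b` target genes annotated to the term, given `B` of
#' the `N` background genes are: `p = sum_{k=b}^{min(n,B)}
#' C(B,k) C(N-B,n-k) / C(N,n)`. The enrichment ratio is `(b/n)/(B/N)`.
#' Terms with `p` below the threshold are returned sorted by ascending
#' `p`, ties broken by descending enrichment, then term identifier. No
#' multiple-testing correction is applied; thresholds act on raw p.
#'
#' @param target Character vector of target genes (e.g. known disease
#'   genes); must be a subset of `background`.
#' @param background Character vector of background genes.
#' @param ann An `annotation_map` (see [read_annotations()]).
#' @param p_threshold Raw p-value threshold, in `(0, 1)`; study default
#'   0.001.
#' @return Tibble with columns `term`, `name`, `namespace`, `b`, `n`, `B`,
#'   `N`, `enrichment`, `p`.
#' @export
enrich_two_list <- function(target, background, ann, p_threshold = 0.001) {
  stopifnot(inherits(ann, "annotation_map"))
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold >= 1) {
    abort("`p_threshold` must be in (0, 1)")
  }
  target <- unique(target)
  background <- unique(background)
  if (!all(target %in% background)) {
    abort("`target` must be a subset of `background`")
  }
  n <- length(target)
  N <- length(background)
  res <- term_counts(ann, target, background)
  res <- dplyr::filter(res, .data$b >= 1)
  res <- dplyr::mutate(res,
                       n = n, N = N,
                       enrichment = (.data$b / n) / (.data$B / N),
                       p = phyper(.data$b - 1, .data$B, N - .data$B, n,
                                  lower.tail = FALSE))
  res <- dplyr::filter(res, .data$p < p_threshold)
  res <- dplyr::arrange(res, .data$p, dplyr::desc(.data$enrichment), .data$term)
  dplyr::select(res, "term", "name", "namespace", "b", "n", "B", "N",
                "enrichment", "p")
}

term_counts <- function(ann, target, background) {
  terms <- names(ann$term_genes)
  B <- vapply(ann$term_genes, function(gs) sum(gs %in% background), 1L)
  b <- vapply(ann$term_genes, function(gs) sum(gs %in% target), 1L)
  info <- ann$dag$terms
  tibble::tibble(term = terms,
                 name = unname(setNames(info$name, info$term)[terms]),
                 namespace = unname(setNames(info$namespace, info$term)[terms]),
                 b = unname(b), B = unname(B)) |>
    dplyr::filter(.data$B >= 1)
}

#' Filter enriched terms by annotation size
#'
#' Keeps terms whose background annotation count `B` (measured after
#' ancestor propagation) lies in `[min_B, max_B]`, both bounds inclusive.
#' The study default `3 <= B <= 50` removes non-specific terms.
#'
#' @param results Enrichment tibble (see [enrich_two_list()]).
#' @param min_B,max_B Inclusive bounds on `B`.
#' @return The filtered tibble.
#' @export
filter_by_term_size <- function(results, min_B = 3, max_B = 50) {
  if (min_B > max_B) abort("`min_B` must not exceed `max_B`")
  dplyr::filter(results, .data$B >= min_B, .data$B <= max_B)
}

#' Keep the top fraction of enriched terms
#'
#' Keeps the first `floor(fraction * count)` terms by ascending p-value,
#' computed per namespace by default (the namespaces are disjoint DAGs),
#' or globally when `per_namespace = FALSE`.
#'
#' @param results Enrichment tibble sorted by ascending `p`.
#' @param fraction Fraction of terms to keep, in `(0, 1]`; study default
#'   0.20.
#' @param per_namespace Apply the fraction within each namespace?
#' @return The selected tibble (original p order preserved).
#' @export
select_top_terms <- function(results, fraction = 0.20, per_namespace = TRUE) {
  assert_fraction(fraction, "fraction")
  if (nrow(results) == 0) abort("no terms to select from")
  pick <- function(df) {
    k <- floor(fraction * nrow(df))
    utils::head(df[order(df$p, -df$enrichment, df$term), ], k)
  }
  out <- if (per_namespace) {
    dplyr::bind_rows(lapply(split(results, results$namespace), pick))
  } else {
    pick(results)
  }
  if (nrow(out) == 0) abort("selection is empty at this fraction")
  dplyr::arrange(out, .data$p, dplyr::desc(.data$enrichment), .data$term)
}

#' Prune semantically redundant enriched terms
#'
#' Greedy redundancy reduction within each namespace, in the spirit of
#' representative-term selection: repeatedly find the most similar
#' retained pair with similarity strictly above `sim_threshold` and
#' discard the member with the larger p-value (the less significant); on a
#' p tie, discard the member with the smaller information content (the
#' more general term); on a further tie, the lexicographically larger term
#' identifier. Stops when no pair exceeds the threshold. The result is a
#' subset of the input and pruning is idempotent.
#'
#' @param results Enrichment tibble sorted by ascending `p`.
#' @param dag An `ontology_dag`.
#' @param ic Named IC vector (see [read_annotations()]).
#' @param sim_threshold Similarity above which two terms are redundant;
#'   default 0.7 (a "medium" pruning strength for Lin similarity).
#' @param method Similarity method, `"lin"` (default) or `"resnik"`.
#' @return The pruned tibble.
#' @export
prune_redundant_terms <- function(results, dag, ic, sim_threshold = 0.7,
                                  method = c("lin", "resnik")) {
  method <- match.arg(method)
  if (nrow(results) <= 1) return(results)
  pruned <- lapply(split(results, results$namespace), function(df) {
    ids <- df$term
    k <- length(ids)
    if (k == 1) return(df)
    sim <- matrix(-Inf, k, k, dimnames = list(ids, ids))
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        s <- semantic_similarity(ids[i], ids[j], dag, ic, method)
        sim[i, j] <- sim[j, i] <- if (is.na(s)) -Inf else s
      }
    }
    alive <- rep(TRUE, k)
    p <- setNames(df$p, ids)
    repeat {
      live_sim <- sim[alive, alive, drop = FALSE]
      if (all(live_sim <= sim_threshold)) break
      idx <- which(live_sim == max(live_sim), arr.ind = TRUE)[1, ]
      pair <- rownames(live_sim)[idx]
      drop_id <- pick_redundant(pair, p, ic)
      alive[match(drop_id, ids)] <- FALSE
    }
    df[alive, ]
  })
  out <- dplyr::bind_rows(pruned)
  dplyr::arrange(out, .data$p, dplyr::desc(.data$enrichment), .data$term)
}

# which of a redundant pair to discard: larger p, then smaller ic,
# then larger term id
pick_redundant <- function(pair, p, ic) {
  p1 <- p[[pair[1]]]; p2 <- p[[pair[2]]]
  if (p1 != p2) return(pair[which.max(c(p1, p2))])
  i1 <- ic[[pair[1]]] %|NA|% -Inf
  i2 <- ic[[pair[2]]] %|NA|% -Inf
  if (i1 != i2) return(pair[which.min(c(i1, i2))])
  max(pair)
}

#' Expand enriched terms to their annotated network genes
#'
#' Union of the (propagated) annotated genes of the surviving terms,
#' intersected with the network's genes. This is the enrichment-derived
#' candidate pool (Set C of the prediction stage).
#'
#' @param results Enrichment tibble of surviving terms.
#' @param ann An `annotation_map`.
#' @param net A `gene_network`.
#' @return Character vector of genes (sorted).
#' @export
terms_to_genes <- function(results, ann, net) {
  stopifnot(inherits(ann, "annotation_map"))
  genes <- unique(unlist(ann$term_genes[results$term], use.names = FALSE))
  out <- sort(intersect(genes, network_genes(net)))
  if (length(out) == 0) abort("no network genes annotated to the surviving terms")
  out
}

#' Gene-set over-representation analysis
#'
#' Generic over-representation of a query gene list against named gene-set
#' collections (pathways, functional classes). For each set the observed
#' member count `b` is compared with the expected count `n * B / N`; a set
#' is reported when the observed exceeds the expected and the
#' hypergeometric upper-tail p-value is below the threshold (study default
#' 0.01). Sets with no query member are excluded.
#'
#' @param genes Query gene list; must be a subset of `universe`.
#' @param collections Named list of gene sets (see [read_gmt()]).
#' @param universe Background gene list.
#' @param p_threshold Raw p-value threshold; default 0.01.
#' @return Tibble with columns `set`, `observed`, `expected`, `n`, `B`,
#'   `N`, `enrichment`, `p`, sorted by ascending `p`.
#' @export
geneset_overrepresentation <- function(genes, collections, universe,
                                       p_threshold = 0.01) {
  genes <- unique(genes)
  universe <- unique(universe)
  if (length(universe) == 0) abort("`universe` must be non-empty")
  if (!all(genes %in% universe)) abort("`genes` must be a subset of `universe`")
  if (is.null(names(collections)) || any(!nzchar(names(collections)))) {
    abort("`collections` must be a named list of gene sets")
  }
  n <- length(genes)
  N <- length(universe)
  res <- purrr::map_dfr(names(collections), function(nm) {
    set <- intersect(collections[[nm]], universe)
    B <- length(set)
    b <- length(intersect(set, genes))
    tibble::tibble(set = nm, observed = b, expected = n * B / N,
                   n = n, B = B, N = N,
                   enrichment = if (B > 0) (b / n) / (B / N) else NA_real_,
                   p = if (B > 0) phyper(b - 1, B, N - B, n, lower.tail = FALSE)
                       else NA_real_)
  })
  res <- dplyr::filter(res, .data$observed > 0,
                       .data$observed > .data$expected,
                       .data$p < p_threshold)
  dplyr::arrange(res, .data$p, dplyr::desc(.data$enrichment), .data$set)
}
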