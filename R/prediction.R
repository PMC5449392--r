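#' Assemble the prediction sets and candidate genes
#'
#' Combines the three evidence sets of the guilt-by-association
#' prediction rule:
#'
#' * Set A: top-ranked genes of the consensus ranking;
#' * Set B: known disease genes present in the network (the known list is
#'   intersected with the network's genes);
#' * Set C: genes of the surviving enriched ontology terms in the network;
#' * Set D (the prediction): genes in both A and C but not in B;
#' * Sets E, F, G (diagnostics): the known genes that are top-ranked
#'   (`B` ∩ `A`), enrichment-supported (`B` ∩ `C`), or both.
#'
#' @param consensus_top Character vector of top-ranked genes (see
#'   [select_top_fraction()]); must lie in the network.
#' @param known Character vector of known disease genes (any universe).
#' @param enriched_genes Character vector of enrichment-derived genes (see
#'   [terms_to_genes()]); must lie in the network.
#' @param net A `gene_network`.
#' @return A `prediction_sets` object: list with elements `set_a` ...
#'   `set_g`. A [tidy()] method returns the set sizes.
#' @export
define_sets <- function(consensus_top, known, enriched_genes, net) {
  nodes <- network_genes(net)
  if (length(consensus_top) == 0) abort("Set A is empty")
  if (length(enriched_genes) == 0) abort("Set C is empty")
  if (!all(consensus_top %in% nodes)) abort("`consensus_top` has genes outside the network")
  if (!all(enriched_genes %in% nodes)) abort("`enriched_genes` has genes outside the network")
  a <- unique(consensus_top)
  b <- sort(intersect(unique(known), nodes))
  cc <- sort(unique(enriched_genes))
  d <- sort(setdiff(intersect(a, cc), b))
  if (length(intersect(a, cc)) == 0) {
    warn("Set A and Set C are disjoint; no candidates predicted")
  }
  structure(list(set_a = a, set_b = b, set_c = cc, set_d = d,
                 set_e = sort(intersect(b, a)),
                 set_f = sort(intersect(b, cc)),
                 set_g = sort(intersect(b, intersect(a, cc)))),
            class = "prediction_sets")
}

#' @export
print.prediction_sets <- function(x, ...) {
  sz <- vapply(x, length, 1L)
  cat("<prediction_sets>\n")
  cat(sprintf("  A (top-ranked): %d   B (known in network): %d   C (enriched-term): %d\n",
              sz[["set_a"]], sz[["set_b"]], sz[["set_c"]]))
  cat(sprintf("  D (candidates): %d   E: %d   F: %d   G: %d\n",
              sz[["set_d"]], sz[["set_e"]], sz[["set_f"]], sz[["set_g"]]))
  invisible(x)
}

#' @rdname define_sets
#' @param x A `prediction_sets` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.prediction_sets <- function(x, ...) {
  tibble::tibble(set = sub("^set_", "", names(x)) |> toupper(),
                 size = vapply(x, length, 1L))
}

#' Precision of a gene list against known disease genes
#'
#' Precision is the percentage of a selected gene list that belongs to the
#' known set: `100 * |selected ∩ known| / |selected|`, reported to two
#' decimals. Printed tables round half-up by default; a `"truncate"` mode
#' (drop digits beyond the second) is provided because published tables
#' use either convention.
#'
#' @param selected Non-empty character vector without duplicates.
#' @param known Character vector of known disease genes.
#' @param mode Rounding of the percentage: `"half_up"` (default) or
#'   `"truncate"`.
#' @return One-row tibble with columns `hits`, `total`, `precision`.
#' @export
#' @examples
#' precision(c("a", "b", "c", "d"), known = c("a", "x"))  # 25
precision <- function(selected, known, mode = c("half_up", "truncate")) {
  mode <- match.arg(mode)
  if (length(selected) == 0) abort("`selected` must be non-empty")
  if (anyDuplicated(selected)) abort("`selected` contains duplicates")
  hits <- sum(selected %in% known)
  tibble::tibble(hits = hits, total = length(selected),
                 precision = round_mode(100 * hits / length(selected),
                                        digits = 2, mode = mode))
}

#' Precision table across centralities, cutoff fractions and the consensus
#'
#' For each cutoff fraction, computes one precision row per centrality
#' measure's top-k list, one `"pooled"` row for the union of all measures'
#' top-k lists (total = union size), and one `"consensus"` row for the
#' consensus ranking's top-k list.
#'
#' @param ranks A `centrality_ranks` object (ordinal ranks are used).
#' @param consensus A `consensus_ranking`.
#' @param known Character vector of known disease genes.
#' @param fractions Cutoff fractions in `(0, 1]`; study defaults
#'   `c(0.02, 0.05, 0.07, 0.10)`.
#' @param measures Measures to tabulate (default: all in `ranks`).
#' @param policy,mode Size policy and rounding mode (see
#'   [select_top_fraction()], [precision()]).
#' @return Tibble with columns `label`, `fraction`, `hits`, `total`,
#'   `precision`.
#' @export
precision_table <- function(ranks, consensus, known,
                            fractions = c(0.02, 0.05, 0.07, 0.10),
                            measures = NULL, policy = "round",
                            mode = "half_up") {
  stopifnot(inherits(ranks, "centrality_ranks"))
  meas <- measures %||% setdiff(names(ranks$ordinal), "gene")
  out <- purrr::map_dfr(fractions, function(f) {
    lists <- lapply(meas, function(ms) {
      select_top_fraction(setNames(ranks$ordinal[[ms]], ranks$ordinal$gene),
                          f, policy = policy)
    })
    names(lists) <- meas
    lists$pooled <- unique(unlist(lists, use.names = FALSE))
    lists$consensus <- select_top_fraction(consensus, f, policy = policy)
    purrr::imap_dfr(lists, function(sel, label) {
      dplyr::bind_cols(tibble::tibble(label = label, fraction = f),
                       precision(sel, known, mode = mode))
    })
  })
  class(out) <- c("precision_tbl", class(out))
  out
}
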