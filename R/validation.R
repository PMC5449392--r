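#' Bin genes into equal slices of the consensus ranking
#'
#' Splits the consensus-ranked gene list into `n_bins` contiguous rank
#' slices: bin 1 holds the best-ranked genes. Sizes differ by at most one;
#' when `n` is not divisible, the remainder goes to the earliest bins.
#'
#' @param consensus A `consensus_ranking` (see [consensus_ranking()]).
#' @param n_bins Number of bins, at least 2; study default 10.
#' @return Tibble with columns `gene`, `consensus_rank`, `bin`, in
#'   consensus order (concatenating the bins reproduces the ranking).
#' @export
bin_by_rank <- function(consensus, n_bins = 10) {
  if (n_bins < 2) abort("`n_bins` must be at least 2")
  tb <- tibble::as_tibble(consensus)
  if (!all(c("gene", "consensus_rank") %in% names(tb))) {
    abort("`consensus` needs columns gene and consensus_rank")
  }
  n <- nrow(tb)
  if (n < n_bins) abort("fewer genes than bins")
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + rep(c(1L, 0L), c(extra, n_bins - extra))
  tb <- dplyr::arrange(tb, .data$consensus_rank)
  tb$bin <- rep(seq_len(n_bins), sizes)
  dplyr::select(tb, "gene", "consensus_rank", "bin")
}

#' Disease-association trend across rank bins
#'
#' Averages per-gene disease counts within each rank bin (genes missing
#' from the association table count 0, matching association extracts that
#' omit zero rows) and fits an ordinary least-squares line of mean count
#' against bin index. A negative slope with a high coefficient of
#' determination indicates that highly ranked (network-central) genes are
#' associated with more diseases. `r_squared` is defined as 0 when all bin
#' means are equal.
#'
#' @param bins Binned genes (see [bin_by_rank()]).
#' @param assoc Association counts: a tibble with columns `gene`, `count`
#'   (see [read_associations()]) or a named numeric vector.
#' @return A `bin_trend` object: `bins` (tibble of `bin`, `n_genes`,
#'   `mean_count`), `slope`, `intercept`, `r_squared`, and the underlying
#'   `lm` in `model`. [tidy()], [glance()] and [autoplot()] methods are
#'   provided.
#' @export
disease_trend <- function(bins, assoc) {
  tb <- tibble::as_tibble(bins)
  if (!all(c("gene", "bin") %in% names(tb))) {
    abort("`bins` needs columns gene and bin")
  }
  if (length(unique(tb$bin)) < 2) abort("need at least two bins")
  if (is.numeric(assoc) && !is.null(names(assoc))) {
    assoc <- tibble::tibble(gene = names(assoc), count = as.numeric(assoc))
  }
  assoc <- tibble::as_tibble(assoc)
  if (!all(c("gene", "count") %in% names(assoc))) {
    abort("`assoc` needs columns gene and count")
  }
  if (any(assoc$count < 0)) abort("negative disease counts")
  counts <- setNames(assoc$count, assoc$gene)
  tb$count <- unname(counts[tb$gene])
  tb$count[is.na(tb$count)] <- 0
  per_bin <- dplyr::summarise(dplyr::group_by(tb, .data$bin),
                              n_genes = dplyr::n(),
                              mean_count = mean(.data$count),
                              .groups = "drop")
  fit <- lm(mean_count ~ bin, data = per_bin)
  ss_tot <- sum((per_bin$mean_count - mean(per_bin$mean_count))^2)
  r2 <- if (ss_tot == 0) 0 else summary(fit)$r.squared
  structure(list(bins = per_bin,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 model = fit),
            class = "bin_trend")
}

#' @export
print.bin_trend <- function(x, ...) {
  cat(sprintf("<bin_trend> %d bins; slope %.3f, R^2 %.3f\n",
              nrow(x$bins), x$slope, x$r_squared))
  invisible(x)
}

#' @rdname disease_trend
#' @param x A `bin_trend` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.bin_trend <- function(x, ...) x$bins

#' @rdname disease_trend
#' @exportS3Method generics::glance
glance.bin_trend <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n_bins = nrow(x$bins))
}

#' @rdname disease_trend
#' @param object A `bin_trend` object.
#' @exportS3Method ggplot2::autoplot
autoplot.bin_trend <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$bin, y = .data$mean_count)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_continuous(breaks = object$bins$bin) +
    ggplot2::labs(x = "consensus-rank bin (1 = top-ranked)",
                  y = "mean diseases per gene",
                  subtitle = sprintf("slope %.3f, R² = %.2f",
                                     object$slope, object$r_squared)) +
    ggplot2::theme_minimal()
}
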