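#' Read a scored interaction edge list
#'
#' Parses a tab-separated edge list of protein-protein interactions with a
#' confidence score in `[0, 1]` per edge. Two dialects are supported:
#'
#' * `"simple3col"`: `idA <tab> idB <tab> score`, extra columns ignored;
#' * `"hippie"`: the six-column layout used by HIPPIE-style interaction
#'   dumps (`symbolA, entrezA, symbolB, entrezB, score, evidence`);
#'   identifiers are taken from the Entrez columns.
#'
#' Lines starting with `#` are treated as comments. Rows whose score does
#' not parse to a number in `[0, 1]`, or whose identifiers are empty, are
#' dropped with a warning; if no row survives, an error is raised.
#'
#' @param path Path to the TSV file.
#' @param dialect One of `"simple3col"` or `"hippie"`.
#' @return A tibble with columns `gene_a`, `gene_b`, `score`, one row per
#'   parseable interaction, input order preserved.
#' @seealso [build_network()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("g1\tg2\t0.9", "g2\tg3\t0.5"), tf)
#' read_interactions(tf)
read_interactions <- function(path, dialect = c("simple3col", "hippie")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- if (dialect == "simple3col") 3L else 5L
  if (ncol(raw) < need) {
    abort(sprintf("dialect '%s' needs at least %d columns, found %d",
                  dialect, need, ncol(raw)))
  }
  if (dialect == "simple3col") {
    out <- tibble::tibble(gene_a = raw[[1]], gene_b = raw[[2]], score_chr = raw[[3]])
  } else {
    out <- tibble::tibble(gene_a = raw[[2]], gene_b = raw[[4]], score_chr = raw[[5]])
  }
  out$score <- suppressWarnings(as.numeric(out$score_chr))
  bad <- is.na(out$score) | out$score < 0 | out$score > 1 |
    is.na(out$gene_a) | is.na(out$gene_b) | !nzchar(out$gene_a) | !nzchar(out$gene_b)
  if (any(bad)) {
    warn(sprintf("dropped %d row(s) with unparseable score or empty identifier",
                 sum(bad)))
    out <- out[!bad, ]
  }
  if (nrow(out) == 0) abort("no parseable interaction rows")
  dplyr::select(out, "gene_a", "gene_b", "score")
}

#' Read a scored candidate-gene list and apply a score cutoff
#'
#' Reads a two-column TSV (`gene <tab> score`) of candidate genes, as
#' produced by cancer-gene ranking resources, and keeps genes whose score is
#' at or above the cutoff (the study default keeps scores >= 1).
#'
#' @param path Path to the TSV file (`#` comments allowed, no header).
#' @param cutoff Minimum score to retain a gene.
#' @return Character vector of unique retained gene identifiers.
#' @export
read_scored_genes <- function(path, cutoff = 1.0) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("expected two columns: gene, score")
  score <- suppressWarnings(as.numeric(raw[[2]]))
  keep <- !is.na(score) & score >= cutoff & nzchar(raw[[1]])
  genes <- unique(raw[[1]][keep])
  if (length(genes) == 0) abort("no genes at or above the score cutoff")
  genes
}

#' Read a known disease-gene list
#'
#' One gene identifier per line; blank lines and `#` comments are skipped.
#'
#' @param path Path to the file.
#' @return Character vector of unique gene identifiers.
#' @export
read_known_genes <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0) abort("no gene identifiers found")
  unique(x)
}

#' Read gene-disease associations
#'
#' Accepts either a pair file (`gene <tab> disease_id`, one association per
#' row, internally aggregated to counts) or a pre-counted file
#' (`gene <tab> count`). The two layouts are distinguished by whether the
#' second column is entirely numeric.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `gene` and `count` (associated diseases per
#'   gene). Genes absent from the file count as zero downstream.
#' @seealso [disease_trend()]
#' @export
read_associations <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("expected two columns")
  second <- suppressWarnings(as.numeric(raw[[2]]))
  if (!anyNA(second)) {
    out <- tibble::tibble(gene = raw[[1]], count = second)
    out <- dplyr::summarise(dplyr::group_by(out, .data$gene),
                            count = sum(.data$count), .groups = "drop")
  } else {
    out <- tibble::tibble(gene = raw[[1]], disease = raw[[2]])
    out <- dplyr::summarise(dplyr::group_by(out, .data$gene),
                            count = dplyr::n_distinct(.data$disease),
                            .groups = "drop")
  }
  out
}

#' Read gene-set collections in GMT format
#'
#' Standard GMT: one set per line, `name <tab> description <tab> gene...`.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (set name -> member genes).
#' @seealso [geneset_overrepresentation()]
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) {
    warn(sprintf("dropped %d GMT line(s) with fewer than 3 fields", sum(bad)))
    parts <- parts[!bad]
  }
  if (length(parts) == 0) abort("no valid GMT records")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}
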