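# Internal constructor shared by the OBO reader and the synthetic
# generator. Validates acyclicity and precomputes the ancestor closure
# (self excluded) in topological order.
new_ontology_dag <- function(terms, parents) {
  terms <- tibble::as_tibble(terms)
  stopifnot(all(c("term", "name", "namespace") %in% names(terms)))
  if (anyDuplicated(terms$term)) abort("duplicate term identifiers")
  ids <- terms$term
  parents <- parents[ids]
  parents <- lapply(parents, function(p) intersect(p %||% character(), ids))
  names(parents) <- ids
  # Kahn topological sort over child -> parent edges; cycle check
  n_par <- vapply(parents, length, 1L)
  children <- vector("list", length(ids))
  names(children) <- ids
  for (id in ids) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }
  queue <- ids[n_par == 0]
  topo <- character(0)
  remaining <- n_par
  while (length(queue) > 0) {
    id <- queue[[1]]
    queue <- queue[-1]
    topo <- c(topo, id)
    for (ch in children[[id]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) != length(ids)) abort("ontology contains a cycle")
  ancestors <- vector("list", length(ids))
  names(ancestors) <- ids
  for (id in topo) {  # parents appear before children
    anc <- unique(unlist(lapply(parents[[id]],
                                function(p) c(p, ancestors[[p]]))))
    ancestors[[id]] <- anc %||% character(0)
  }
  ns <- setNames(terms$namespace, terms$term)
  bad <- vapply(ids, function(id) {
    any(ns[parents[[id]]] != ns[[id]])
  }, TRUE)
  if (any(bad)) abort("is_a relation crosses namespaces")
  structure(list(terms = terms, parents = parents, ancestors = ancestors,
                 roots = unname(ids[n_par == 0])),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  nspl <- table(x$terms$namespace)
  cat(sprintf("<ontology_dag> %d terms (%s)\n", nrow(x$terms),
              paste(sprintf("%s: %d", names(nspl), nspl), collapse = ", ")))
  invisible(x)
}

#' Read an ontology in OBO 1.2 format
#'
#' Minimal OBO reader covering the fields the analysis needs: `[Term]`
#' stanzas with `id`, `name`, `namespace` and `is_a` relations. Obsolete
#' terms are skipped; trailing `!` comments on `is_a` lines are stripped;
#' the long namespace names (`biological_process`, `molecular_function`,
#' `cellular_component`) are abbreviated to `BP`/`MF`/`CC`. The graph must
#' be acyclic and `is_a` edges may not cross namespaces.
#'
#' @param path Path to the OBO file.
#' @return An `ontology_dag` object: term table (`term`, `name`,
#'   `namespace`), parent lists, precomputed ancestor closures, and root
#'   terms.
#' @seealso [read_annotations()], [semantic_similarity()]
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  ns_map <- c(biological_process = "BP", molecular_function = "MF",
              cellular_component = "CC")
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$id) || isTRUE(cur$obsolete)) return(NULL)
    cur
  }
  for (ln in c(lines, "[flush]")) {
    ln <- trimws(ln)
    if (startsWith(ln, "[")) {
      done <- flush(cur)
      if (!is.null(done)) terms[[done$id]] <- done
      in_term <- identical(ln, "[Term]")
      cur <- if (in_term) list(parents = character(0)) else NULL
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
    else if (startsWith(ln, "namespace:")) {
      ns <- trimws(sub("^namespace:", "", ln))
      cur$namespace <- unname(ns_map[ns] %|NA|% ns)
    } else if (startsWith(ln, "is_a:")) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$parents <- c(cur$parents, tgt)
    } else if (startsWith(ln, "is_obsolete:")) {
      cur$obsolete <- grepl("true", ln, fixed = TRUE)
    }
  }
  if (length(terms) == 0) abort("no [Term] stanzas found")
  tb <- tibble::tibble(
    term = unname(vapply(terms, `[[`, "", "id")),
    name = unname(vapply(terms, function(t) t$name %||% t$id, "")),
    namespace = unname(vapply(terms, function(t) t$namespace %||% "BP", ""))
  )
  parents <- lapply(terms, `[[`, "parents")
  names(parents) <- tb$term
  new_ontology_dag(tb, parents)
}

`%|NA|%` <- function(x, y) if (is.na(x)) y else x

#' Read gene-to-term annotations and compute information content
#'
#' Reads a two-column TSV (`gene <tab> term`, no header); annotations to
#' terms absent from the DAG are skipped with a warning. Annotations are
#' propagated to all ancestor terms (the true-path closure). Information
#' content is computed per term as the negative natural log of its
#' annotation frequency relative to its namespace total, with the loaded
#' corpus itself as the reference: `IC = -ln(n_term / n_namespace)`, so
#' roots score 0 and rarer (more specific) terms score higher.
#'
#' @param path Path to the annotation TSV.
#' @param dag An `ontology_dag` (see [read_obo()]).
#' @return An `annotation_map`: lists `direct` and `propagated` (gene ->
#'   terms), `term_genes` (term -> genes, propagated), numeric `ic`
#'   (nats), and the `dag`.
#' @export
read_annotations <- function(path, dag) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("expected two columns: gene, term")
  build_annotation_map(tibble::tibble(gene = raw[[1]], term = raw[[2]]), dag)
}

# Core annotation builder shared with the synthetic generator.
build_annotation_map <- function(pairs, dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  known <- pairs$term %in% dag$terms$term
  if (any(!known)) {
    warn(sprintf("skipped %d annotation(s) to unknown terms", sum(!known)))
    pairs <- pairs[known, ]
  }
  if (nrow(pairs) == 0) abort("no usable annotations")
  pairs <- dplyr::distinct(pairs)
  direct <- split(pairs$term, pairs$gene)
  propagated <- lapply(direct, function(ts) {
    unique(c(ts, unlist(dag$ancestors[ts], use.names = FALSE)))
  })
  prop_pairs <- tibble::tibble(
    gene = rep(names(propagated), lengths(propagated)),
    term = unlist(propagated, use.names = FALSE)
  )
  term_genes <- split(prop_pairs$gene, prop_pairs$term)
  ns <- setNames(dag$terms$namespace, dag$terms$term)
  ns_total <- vapply(split(term_genes, ns[names(term_genes)]),
                     function(tg) length(unique(unlist(tg, use.names = FALSE))),
                     1L)
  counts <- lengths(term_genes)
  ic <- setNames(rep(NA_real_, nrow(dag$terms)), dag$terms$term)
  ic[names(counts)] <- -log(counts / ns_total[ns[names(counts)]])
  structure(list(direct = direct, propagated = propagated,
                 term_genes = term_genes, ic = ic, dag = dag),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("<annotation_map> %d genes, %d annotated terms\n",
              length(x$direct), length(x$term_genes)))
  invisible(x)
}

#' Semantic similarity of two ontology terms
#'
#' Information-content based similarity over the shared `is_a` ancestry:
#' Resnik similarity is the IC of the most informative common ancestor
#' (MICA, a term counting as its own ancestor); Lin similarity normalizes
#' it as `2 * IC(MICA) / (IC(t1) + IC(t2))`, defined as 0 when both term
#' ICs are 0. Terms must share a namespace.
#'
#' @param t1,t2 Term identifiers.
#' @param dag An `ontology_dag`.
#' @param ic Named numeric vector of information contents (e.g. the `ic`
#'   element of an [read_annotations()] result).
#' @param method `"lin"` (default) or `"resnik"`.
#' @return The similarity value (Lin in `[0, 1]`).
#' @export
semantic_similarity <- function(t1, t2, dag, ic, method = c("lin", "resnik")) {
  method <- match.arg(method)
  stopifnot(inherits(dag, "ontology_dag"))
  ns <- setNames(dag$terms$namespace, dag$terms$term)
  if (!t1 %in% names(ns) || !t2 %in% names(ns)) abort("unknown term identifier")
  if (ns[[t1]] != ns[[t2]]) abort("terms belong to different namespaces")
  common <- intersect(c(t1, dag$ancestors[[t1]]), c(t2, dag$ancestors[[t2]]))
  ic_common <- ic[common]
  ic_common <- ic_common[!is.na(ic_common)]
  mica <- if (length(ic_common) == 0) 0 else max(ic_common)
  if (method == "resnik") return(unname(mica))
  denom <- ic[[t1]] + ic[[t2]]
  if (is.na(denom)) return(NA_real_)
  if (denom == 0) return(0)
  unname(2 * mica / denom)
}
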