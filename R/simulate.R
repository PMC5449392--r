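#' Configuration for the synthetic study generator
#'
#' Bundles every parameter of the synthetic data generator with the
#' defaults that emulate the data regime of a hub-dominated cancer-gene
#' interaction study scaled to desk size: a 2000-gene scale-free network
#' (preferential attachment, 3 edges per new node), 150 known disease
#' genes sampled with weight proportional to degree squared (disease genes
#' concentrate in hubs), Beta(6, 3) edge-confidence scores (mode ~0.7, so
#' the 0.63 confidence cutoff retains a well-connected core), a 300-term
#' three-namespace ontology with 30 planted enriched terms annotating
#' 10-40 genes each and drawing 90% of their genes from the disease set,
#' and per-gene disease counts decaying log-linearly in the consensus-rank
#' percentile.
#'
#' @param n_genes Number of genes in the universe.
#' @param attachment_edges Edges attached per new node in the
#'   preferential-attachment network.
#' @param n_disease_genes Number of planted known disease genes.
#' @param hub_bias Disease genes are sampled with weight `degree^hub_bias`
#'   (0 = uniform).
#' @param score_alpha,score_beta Beta parameters of edge-confidence scores.
#' @param n_terms Total ontology terms across the three namespaces.
#' @param dag_depth Maximum term depth below a namespace root.
#' @param n_enriched_terms Number of planted enriched terms.
#' @param enrichment_strength Fraction of a planted term's annotations
#'   drawn from the disease set, in `[0, 1]`.
#' @param term_size_range Length-2 integer range of direct annotations per
#'   term.
#' @param disease_count_rate Baseline Poisson rate of diseases per gene.
#' @param rank_effect Log-linear decay of the expected disease count with
#'   consensus-rank percentile (0 = rank-independent null).
#' @param seed Integer seed; every generator output is a pure function of
#'   the configuration including the seed.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_genes = 2000,
                         attachment_edges = 3,
                         n_disease_genes = 150,
                         hub_bias = 2,
                         score_alpha = 6,
                         score_beta = 3,
                         n_terms = 300,
                         dag_depth = 4,
                         n_enriched_terms = 30,
                         enrichment_strength = 0.9,
                         term_size_range = c(10, 40),
                         disease_count_rate = 5,
                         rank_effect = 2,
                         seed = 1) {
  cfg <- list(n_genes = n_genes, attachment_edges = attachment_edges,
              n_disease_genes = n_disease_genes, hub_bias = hub_bias,
              score_alpha = score_alpha, score_beta = score_beta,
              n_terms = n_terms, dag_depth = dag_depth,
              n_enriched_terms = n_enriched_terms,
              enrichment_strength = enrichment_strength,
              term_size_range = as.integer(term_size_range),
              disease_count_rate = disease_count_rate,
              rank_effect = rank_effect, seed = as.integer(seed))
  counts <- c("n_genes", "attachment_edges", "n_disease_genes", "n_terms",
              "dag_depth", "n_enriched_terms")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] < 1) {
      abort(sprintf("`%s` must be a positive count", nm))
    }
  }
  if (cfg$attachment_edges >= cfg$n_genes) {
    abort("`attachment_edges` must be smaller than `n_genes`")
  }
  if (cfg$n_disease_genes >= cfg$n_genes) {
    abort("`n_disease_genes` must be smaller than `n_genes`")
  }
  if (cfg$hub_bias < 0) abort("`hub_bias` must be >= 0")
  if (cfg$score_alpha <= 0 || cfg$score_beta <= 0) {
    abort("Beta score parameters must be positive")
  }
  if (cfg$n_enriched_terms > cfg$n_terms) {
    abort("`n_enriched_terms` must not exceed `n_terms`")
  }
  assert_fraction(cfg$enrichment_strength, "enrichment_strength",
                  closed_zero = TRUE)
  if (length(cfg$term_size_range) != 2 || cfg$term_size_range[1] < 1 ||
      cfg$term_size_range[1] > cfg$term_size_range[2]) {
    abort("`term_size_range` must be an increasing positive pair")
  }
  if (cfg$term_size_range[2] > cfg$n_genes) {
    abort("term sizes cannot exceed the gene universe")
  }
  if (cfg$disease_count_rate < 0) abort("`disease_count_rate` must be >= 0")
  if (cfg$rank_effect < 0) abort("`rank_effect` must be >= 0")
  if (is.na(cfg$seed) || abs(cfg$seed) > 2^31 - 10) {
    abort("`seed` must be a 32-bit integer")
  }
  structure(cfg, class = "synth_config")
}

synth_gene_ids <- function(n) sprintf("G%05d", seq_len(n))

#' Simulate a scored scale-free interaction network
#'
#' Grows an undirected preferential-attachment graph (each new node
#' attaches `attachment_edges` edges, so the graph is connected by
#' construction and its degree distribution is scale-free with hubs) and
#' assigns each edge an independent Beta-distributed confidence score.
#'
#' @param cfg A [synth_config()].
#' @return List with `interactions` (tibble `gene_a`, `gene_b`, `score`)
#'   and `genes` (the full gene universe).
#' @export
simulate_network <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  g <- igraph::sample_pa(cfg$n_genes, power = 1, m = cfg$attachment_edges,
                         directed = FALSE)
  ids <- synth_gene_ids(cfg$n_genes)
  el <- igraph::as_edgelist(g, names = FALSE)
  interactions <- tibble::tibble(
    gene_a = ids[el[, 1]],
    gene_b = ids[el[, 2]],
    score = rbeta(nrow(el), cfg$score_alpha, cfg$score_beta)
  )
  list(interactions = interactions, genes = ids)
}

#' Plant known disease genes with hub bias
#'
#' Samples the known disease-gene set without replacement with probability
#' proportional to `degree^hub_bias`, emulating the empirical tendency of
#' disease genes to sit on network hubs; `hub_bias = 0` gives uniform
#' sampling.
#'
#' @param x A simulated network (the list from [simulate_network()]), an
#'   interactions tibble, or a `gene_network`.
#' @param cfg A [synth_config()].
#' @return Character vector of disease-gene identifiers (sorted).
#' @export
plant_disease_genes <- function(x, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (inherits(x, "gene_network")) {
    genes <- network_genes(x)
    deg <- as.numeric(igraph::degree(as_igraph(x)))
  } else {
    if (is.list(x) && !is.data.frame(x) && !is.null(x$interactions)) {
      ints <- x$interactions
      genes <- x$genes
    } else {
      ints <- tibble::as_tibble(x)
      genes <- sort(unique(c(ints$gene_a, ints$gene_b)))
    }
    tab <- table(factor(c(ints$gene_a, ints$gene_b), levels = genes))
    deg <- as.numeric(tab)
  }
  if (cfg$n_disease_genes >= length(genes)) {
    abort("`n_disease_genes` must be smaller than the gene universe")
  }
  set.seed(cfg$seed + 1L)
  sort(sample(genes, cfg$n_disease_genes, prob = deg^cfg$hub_bias))
}

#' Simulate an ontology with planted enriched terms
#'
#' Builds a random rooted DAG per namespace (BP/MF/CC split roughly
#' 70/15/15) of the configured depth: each non-root term draws one or two
#' parents from strictly shallower terms of its namespace. Each non-root
#' term then annotates a gene count drawn from `term_size_range`; planted
#' enriched terms draw `ceiling(enrichment_strength * size)` of their
#' genes from the disease set and the rest uniformly, while the other
#' terms annotate uniformly. Root terms carry no direct annotation (they
#' accumulate everything by propagation).
#'
#' @param genes Gene universe.
#' @param disease_genes Planted disease-gene set.
#' @param cfg A [synth_config()].
#' @return List with `dag` (an `ontology_dag`), `annotations` (tibble
#'   `gene`, `term`), and `enriched_terms` (the planted truth).
#' @export
simulate_ontology <- function(genes, disease_genes, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  assert_genes(genes)
  k_max <- ceiling(cfg$enrichment_strength * cfg$term_size_range[2])
  if (k_max > length(disease_genes)) {
    abort("disease set too small for the requested enrichment strength and term sizes")
  }
  set.seed(cfg$seed + 2L)
  n_ns <- size_round(cfg$n_terms * c(BP = 0.7, MF = 0.15, CC = 0.15))
  n_ns <- pmax(n_ns, 1L)
  n_ns[1] <- n_ns[1] + (cfg$n_terms - sum(n_ns))  # absorb rounding in BP
  ids <- sprintf("T:%06d", seq_len(sum(n_ns)))
  namespace <- rep(names(n_ns), n_ns)
  depth <- integer(length(ids))
  parents <- vector("list", length(ids))
  names(parents) <- ids
  offset <- 0L
  for (ns in names(n_ns)) {
    idx <- offset + seq_len(n_ns[[ns]])
    depth[idx[1]] <- 0L  # namespace root
    parents[[idx[1]]] <- character(0)
    for (i in idx[-1]) {
      depth[i] <- sample.int(cfg$dag_depth, 1)
      assigned <- idx[idx < i]  # processed so far, root included
      shallower <- assigned[depth[assigned] < depth[i]]
      n_par <- min(length(shallower), sample.int(2, 1))
      parents[[i]] <- ids[resample(shallower, n_par)]
    }
    offset <- offset + n_ns[[ns]]
  }
  terms <- tibble::tibble(term = ids,
                          name = sprintf("synthetic term %s", ids),
                          namespace = namespace)
  dag <- new_ontology_dag(terms, parents)
  non_root <- ids[depth > 0]
  if (length(non_root) < cfg$n_enriched_terms) {
    abort("too few non-root terms for the requested number of enriched terms")
  }
  enriched <- sort(resample(non_root, cfg$n_enriched_terms))
  sizes_pool <- seq(cfg$term_size_range[1], cfg$term_size_range[2])
  ann <- purrr::map_dfr(non_root, function(tid) {
    size <- resample(sizes_pool, 1)
    if (tid %in% enriched) {
      k <- ceiling(cfg$enrichment_strength * size)
      from_disease <- sample(disease_genes, k)
      rest <- sample(setdiff(genes, from_disease), size - k)
      members <- c(from_disease, rest)
    } else {
      members <- sample(genes, size)
    }
    tibble::tibble(gene = members, term = tid)
  })
  list(dag = dag, annotations = ann, enriched_terms = enriched)
}

#' Simulate per-gene disease-association counts
#'
#' Draws each gene's disease count from a Poisson distribution whose mean
#' decays log-linearly in the gene's consensus-rank percentile:
#' `lambda = disease_count_rate * exp(-rank_effect * rank / n)`. With
#' `rank_effect = 0` the counts are rank-independent (the null).
#'
#' @param consensus A `consensus_ranking` (or any tibble with `gene` and
#'   `consensus_rank`).
#' @param cfg A [synth_config()].
#' @return Tibble with columns `gene` and `count`.
#' @export
simulate_disease_counts <- function(consensus, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  tb <- tibble::as_tibble(consensus)
  if (!all(c("gene", "consensus_rank") %in% names(tb))) {
    abort("`consensus` needs columns gene and consensus_rank")
  }
  set.seed(cfg$seed + 3L)
  pct <- tb$consensus_rank / nrow(tb)
  lambda <- cfg$disease_count_rate * exp(-cfg$rank_effect * pct)
  tibble::tibble(gene = tb$gene, count = rpois(nrow(tb), lambda))
}

#' Write a complete synthetic study to disk
#'
#' Generates every input the analysis pipeline consumes and writes them as
#' plain-text files: `edges.tsv` (simple three-column interactions),
#' `genes.tsv` (scored candidate list; scores uniform in `[1, 4]` so the
#' study's `>= 1` candidate cutoff keeps the whole simulated universe),
#' `known.txt`, `ontology.obo`, `annotations.tsv`, `associations.tsv`,
#' and `truth.json` (planted enriched terms, disease genes, and the
#' configuration echo). The standalone `associations.tsv` uses a
#' degree-based ranking as its rank driver, since the consensus ranking
#' only exists once the pipeline has run; [run_pipeline()] regenerates
#' counts from the true consensus instead.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the generated objects and paths.
#' @export
simulate_study <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  net_sim <- simulate_network(cfg)
  disease <- plant_disease_genes(net_sim, cfg)
  onto <- simulate_ontology(net_sim$genes, disease, cfg)
  # degree-rank proxy for the standalone association file
  tab <- table(factor(c(net_sim$interactions$gene_a,
                        net_sim$interactions$gene_b),
                      levels = net_sim$genes))
  proxy <- tibble::tibble(gene = net_sim$genes,
                          consensus_rank = order(order(-as.numeric(tab),
                                                       net_sim$genes)))
  assoc <- simulate_disease_counts(proxy, cfg)
  set.seed(cfg$seed + 4L)
  gene_scores <- tibble::tibble(gene = net_sim$genes,
                                score = round(runif(length(net_sim$genes), 1, 4), 2))
  paths <- list(
    edges = file.path(dir, "edges.tsv"),
    genes = file.path(dir, "genes.tsv"),
    known = file.path(dir, "known.txt"),
    ontology = file.path(dir, "ontology.obo"),
    annotations = file.path(dir, "annotations.tsv"),
    associations = file.path(dir, "associations.tsv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_tsv(net_sim$interactions, paths$edges, col_names = FALSE)
  readr::write_tsv(gene_scores, paths$genes, col_names = FALSE)
  writeLines(disease, paths$known)
  write_obo(onto$dag, paths$ontology)
  readr::write_tsv(onto$annotations, paths$annotations, col_names = FALSE)
  readr::write_tsv(assoc, paths$associations, col_names = FALSE)
  jsonlite::write_json(
    list(enriched_terms = onto$enriched_terms, disease_genes = disease,
         config = unclass(cfg)),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(paths = paths, interactions = net_sim$interactions,
                 genes = net_sim$genes, disease_genes = disease,
                 dag = onto$dag, annotations = onto$annotations,
                 enriched_terms = onto$enriched_terms, associations = assoc))
}

#' Write an ontology DAG in OBO 1.2 format
#'
#' @param dag An `ontology_dag`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "ontology_dag"))
  ns_long <- c(BP = "biological_process", MF = "molecular_function",
               CC = "cellular_component")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    ns <- dag$terms$namespace[i]
    lines <- c("[Term]",
               paste0("id: ", dag$terms$term[i]),
               paste0("name: ", dag$terms$name[i]),
               paste0("namespace: ", unname(ns_long[ns] %|NA|% ns)),
               paste0("is_a: ", dag$parents[[dag$terms$term[i]]]),
               "")
    writeLines(lines, con)
  }
  invisible(path)
}
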