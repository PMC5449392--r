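#' Pipeline configuration
#'
#' Collects every stage parameter of the prioritization pipeline with the
#' study's published defaults: interaction-confidence cutoff 0.63,
#' candidate-gene score cutoff 1.0, precision cutoffs 2/5/7/10%, Set-A
#' fraction 5%, enrichment p < 0.001, gene-set over-representation
#' p < 0.01, term-size bounds 3..50, top-term fraction 20%, Lin-similarity
#' pruning threshold 0.7, measure-redundancy threshold 1.0 (exact), and
#' ten rank bins.
#'
#' @param input_dir Directory of study inputs (`edges.tsv`, `genes.tsv`,
#'   `known.txt`, `ontology.obo`, `annotations.tsv`, optionally
#'   `associations.tsv`); `NULL` (default) simulates a synthetic study.
#' @param synth A [synth_config()] used when `input_dir` is `NULL`; its
#'   seed defaults to `seed`.
#' @param dialect Edge-list dialect (see [read_interactions()]).
#' @param score_cutoff,gene_cutoff Confidence and candidate-score cutoffs.
#' @param measures Centrality measures (default: all eleven).
#' @param prune_threshold Rank-correlation threshold for measure collapse.
#' @param fractions Precision-table cutoff fractions.
#' @param top_fraction Consensus fraction defining Set A.
#' @param enrich_p,ora_p Raw p-value thresholds.
#' @param min_B,max_B Term-size bounds (first term-selection criterion).
#' @param top_term_fraction Top-term fraction (second and third
#'   term-selection criteria).
#' @param sim_threshold,sim_method Semantic-similarity pruning parameters
#'   (third term-selection criterion).
#' @param n_bins Rank bins for the disease-association trend.
#' @param policy,rounding List-size policy and precision rounding mode.
#' @param seed Integer seed funneling all randomness.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL,
                            synth = NULL,
                            dialect = "simple3col",
                            score_cutoff = 0.63,
                            gene_cutoff = 1.0,
                            measures = centrality_measures(),
                            prune_threshold = 1.0,
                            fractions = c(0.02, 0.05, 0.07, 0.10),
                            top_fraction = 0.05,
                            enrich_p = 0.001,
                            ora_p = 0.01,
                            min_B = 3,
                            max_B = 50,
                            top_term_fraction = 0.20,
                            sim_threshold = 0.7,
                            sim_method = "lin",
                            n_bins = 10,
                            policy = "round",
                            rounding = "half_up",
                            seed = 1L) {
  synth <- synth %||% synth_config(seed = seed)
  cfg <- list(input_dir = input_dir, synth = synth, dialect = dialect,
              score_cutoff = score_cutoff, gene_cutoff = gene_cutoff,
              measures = measures, prune_threshold = prune_threshold,
              fractions = fractions, top_fraction = top_fraction,
              enrich_p = enrich_p, ora_p = ora_p,
              min_B = min_B, max_B = max_B,
              top_term_fraction = top_term_fraction,
              sim_threshold = sim_threshold, sim_method = sim_method,
              n_bins = n_bins, policy = policy, rounding = rounding,
              seed = as.integer(seed))
  for (f in cfg$fractions) assert_fraction(f, "fractions")
  assert_fraction(cfg$top_fraction, "top_fraction")
  structure(cfg, class = "pipeline_config")
}

#' Run the full prioritization pipeline
#'
#' Executes every stage in order: obtain inputs (simulate a synthetic
#' study or read the files in `config$input_dir`), build the filtered
#' largest-component network, summarize its topology, compute the
#' centralities, rank and correlate them, collapse perfectly correlated
#' measures, build the rank-sum consensus, run the two-list enrichment
#' with the three term-selection criteria, expand the surviving terms to
#' Set C, assemble the prediction sets, tabulate precision across
#' centralities and cutoffs, and fit the rank-bin disease-association
#' trend. When `out_dir` is given, every stage artifact is written as
#' plain text (each file carries a `#` header naming the producing step
#' and the configuration hash) together with `summary.json` and
#' `run.log`; re-running with an identical configuration reproduces
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional artifact directory.
#' @return A named list of stage results (invisible when `out_dir` is
#'   given): `network`, `topology`, `centralities`, `ranks`, `rho`,
#'   `retained`, `consensus`, `enrichment` (all + per-criterion tables),
#'   `set_c`, `sets`, `precision_table`, `criteria_precision`, `bins`,
#'   `trend`, `truth` (synthetic runs only).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$input_dir)) {
    sim <- simulate_network(config$synth)
    known <- plant_disease_genes(sim, config$synth)
    onto <- simulate_ontology(sim$genes, known, config$synth)
    interactions <- sim$interactions
    universe <- sim$genes
    dag <- onto$dag
    ann_pairs <- onto$annotations
    assoc <- NULL
    truth <- list(enriched_terms = onto$enriched_terms, disease_genes = known)
  } else {
    p <- function(f) file.path(config$input_dir, f)
    interactions <- read_interactions(p("edges.tsv"), dialect = config$dialect)
    universe <- read_scored_genes(p("genes.tsv"), cutoff = config$gene_cutoff)
    known <- read_known_genes(p("known.txt"))
    dag <- read_obo(p("ontology.obo"))
    raw_ann <- readr::read_tsv(p("annotations.tsv"), col_names = FALSE,
                               comment = "#",
                               col_types = readr::cols(.default = readr::col_character()),
                               progress = FALSE)
    ann_pairs <- tibble::tibble(gene = raw_ann[[1]], term = raw_ann[[2]])
    assoc <- if (file.exists(p("associations.tsv"))) {
      read_associations(p("associations.tsv"))
    } else NULL
    truth <- NULL
  }

  net <- build_network(interactions, universe, config$score_cutoff)
  topology <- summarize_topology(net, seed = config$seed)
  cent <- compute_centralities(net, config$measures)
  ranks <- rank_table(cent)
  rho <- rank_correlation_matrix(ranks)
  retained <- prune_redundant_measures(rho, config$prune_threshold)
  cons <- consensus_ranking(ranks, retained)

  nodes <- network_genes(net)
  target <- intersect(known, nodes)
  ann <- build_annotation_map(ann_pairs, dag)
  enr_all <- enrich_two_list(target, nodes, ann, config$enrich_p)
  crit <- list(
    size_filter = tryCatch(
      filter_by_term_size(enr_all, config$min_B, config$max_B),
      error = function(e) NULL),
    top_fraction = tryCatch(
      select_top_terms(enr_all, config$top_term_fraction),
      error = function(e) NULL)
  )
  crit$pruned <- if (!is.null(crit$top_fraction)) {
    prune_redundant_terms(crit$top_fraction, dag, ann$ic,
                          config$sim_threshold, config$sim_method)
  } else NULL
  if (is.null(crit$pruned) || nrow(crit$pruned) == 0) {
    abort("no enriched terms survive the selection criteria")
  }
  set_c <- terms_to_genes(crit$pruned, ann, net)
  criteria_precision <- purrr::imap_dfr(crit, function(df, label) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    genes <- tryCatch(terms_to_genes(df, ann, net), error = function(e) NULL)
    if (is.null(genes)) return(NULL)
    dplyr::bind_cols(tibble::tibble(criterion = label, n_terms = nrow(df)),
                     precision(genes, known, mode = "truncate"))
  })

  set_a <- select_top_fraction(cons, config$top_fraction, config$policy)
  sets <- define_sets(set_a, known, set_c, net)
  prec_tab <- precision_table(ranks, cons, known,
                              fractions = config$fractions,
                              policy = config$policy, mode = config$rounding)
  assoc <- assoc %||% simulate_disease_counts(cons, config$synth)
  bins <- bin_by_rank(cons, config$n_bins)
  trend <- disease_trend(bins, assoc)

  res <- list(network = net, topology = topology, centralities = cent,
              ranks = ranks, rho = rho, retained = retained,
              consensus = cons,
              enrichment = c(list(all = enr_all), crit),
              set_c = set_c, sets = sets,
              precision_table = prec_tab,
              criteria_precision = criteria_precision,
              bins = bins, trend = trend, truth = truth,
              config = config)
  if (!is.null(out_dir)) {
    write_pipeline_artifacts(res, out_dir)
    return(invisible(res))
  }
  res
}

write_pipeline_artifacts <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- res$config
  hash <- rlang::hash(unclass(cfg))
  hdr <- function(step) sprintf("netprior %s | step: %s | config: %s",
                                as.character(utils::packageVersion("netprior")),
                                step, hash)
  tsv <- function(df, file, step) {
    path <- file.path(out_dir, file)
    con <- file(path, "w")
    writeLines(paste0("# ", hdr(step)), con)
    close(con)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  }
  write_network(res$network, file.path(out_dir, "network.tsv"),
                header = hdr("build-network"))
  jsonlite::write_json(c(list(`_produced_by` = hdr("topology")),
                         as.list(res$topology)),
                       file.path(out_dir, "topology.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cent_out <- res$centralities
  for (ms in setdiff(names(res$ranks$ordinal), "gene")) {
    cent_out[[paste0(ms, "_rank")]] <- res$ranks$ordinal[[ms]]
  }
  tsv(cent_out, "centrality.tsv", "centrality")
  rho_df <- tibble::as_tibble(res$rho, rownames = "measure")
  tsv(rho_df, "correlations.tsv", "correlations")
  tsv(res$consensus, "consensus.tsv", "consensus")
  enr <- res$enrichment$all
  enr$retained_size_filter <- enr$term %in% (res$enrichment$size_filter$term %||% character())
  enr$retained_top_fraction <- enr$term %in% (res$enrichment$top_fraction$term %||% character())
  enr$retained_pruned <- enr$term %in% res$enrichment$pruned$term
  tsv(enr, "enrichment.tsv", "enrich")
  for (s in names(res$sets)) {
    path <- file.path(out_dir, paste0(s, ".txt"))
    writeLines(c(paste0("# ", hdr("predict")), res$sets[[s]]), path)
  }
  tsv(res$precision_table, "precision_table.tsv", "precision-table")
  tsv(res$criteria_precision, "criteria_precision.tsv", "criteria-precision")
  jsonlite::write_json(
    list(`_produced_by` = hdr("validate-bins"),
         per_bin_means = res$trend$bins$mean_count,
         slope = res$trend$slope, intercept = res$trend$intercept,
         r_squared = res$trend$r_squared),
    file.path(out_dir, "bin_trend.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  summary <- list(
    produced_by = hdr("run-all"),
    seed = cfg$seed,
    n_genes = length(network_genes(res$network)),
    n_edges = nrow(network_edges(res$network)),
    topology = as.list(res$topology),
    retained_measures = res$retained,
    set_sizes = as.list(vapply(res$sets, length, 1L)),
    consensus_precision = as.list(setNames(
      res$precision_table$precision[res$precision_table$label == "consensus"],
      paste0("top_", res$precision_table$fraction[res$precision_table$label == "consensus"]))),
    n_enriched_terms = nrow(res$enrichment$all),
    n_terms_after_criteria = nrow(res$enrichment$pruned),
    bin_trend = list(slope = res$trend$slope, r_squared = res$trend$r_squared)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(
    sprintf("netprior %s", as.character(utils::packageVersion("netprior"))),
    sprintf("R %s.%s", R.version$major, R.version$minor),
    sprintf("config hash: %s", hash),
    sprintf("seed: %d", cfg$seed),
    sprintf("input: %s", cfg$input_dir %||% "synthetic"),
    sprintf("score_cutoff: %s | gene_cutoff: %s", cfg$score_cutoff, cfg$gene_cutoff),
    sprintf("measures: %s", paste(cfg$measures, collapse = ",")),
    sprintf("retained: %s", paste(res$retained, collapse = ",")),
    sprintf("fractions: %s | top_fraction: %s",
            paste(cfg$fractions, collapse = ","), cfg$top_fraction),
    sprintf("enrich_p: %s | min_B: %s | max_B: %s | top_term_fraction: %s | sim_threshold: %s",
            cfg$enrich_p, cfg$min_B, cfg$max_B, cfg$top_term_fraction,
            cfg$sim_threshold),
    sprintf("n_bins: %s", cfg$n_bins)
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
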