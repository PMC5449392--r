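# netprior

Network-based disease-gene prioritization in R: consensus centrality
ranking over a confidence-filtered protein–protein interaction (PPI)
network, combined with ontology enrichment, to predict candidate disease
genes by guilt-by-association.

## Who this is for

Computational biologists who have (a) a scored interaction network
(HIPPIE-style TSV), (b) a scored candidate-gene list, (c) a known
disease-gene list, and (d) a GO-style ontology with gene annotations —
and want a reproducible, tested implementation of the
centrality-consensus + enrichment prioritization recipe, including a
seeded synthetic study generator so the whole pipeline runs and is
testable without any database download.

## The method

1. **Network.** Keep interactions with confidence ≥ 0.63 between
   candidate genes (candidate score ≥ 1), drop self-loops, collapse
   parallel edges to their maximum score, take the largest connected
   component. Characterize topology (degree, diameter, distance, density,
   modularity, efficiency, clustering, and the exponent γ of
   P(K) ∝ K^−γ fitted by OLS on the log-log degree distribution).
2. **Consensus ranking.** Compute eleven centralities (degree, closeness,
   radiality, shortest-path betweenness, current-flow betweenness,
   current-flow closeness, centroid, PageRank, vulnerability, stress,
   eigenvector). Collapse perfectly Spearman-correlated measures
   (ρ = 1 − 6Σd²/(n(n²−1)); closeness/radiality always collapse, 11 → 10),
   then rank each gene by the **sum of its ranks** over the retained
   measures.
3. **Enrichment.** Two-list hypergeometric over-representation of the
   known disease genes against the network (raw p < 0.001), followed by
   three selection criteria: term size 3 ≤ B ≤ 50; top 20% by p-value;
   top 20% plus Lin-similarity redundancy pruning (threshold 0.7). The
   surviving terms expand to their annotated network genes (Set C).
4. **Prediction.** With Set A = top 5% of the consensus and Set B = known
   disease genes in the network, the candidates are
   **D = (A ∩ C) \\ B**. Precision (the % of a list that is known) is
   tabulated per centrality, pooled, and for the consensus at the
   2/5/7/10% cutoffs; a ten-bin regression of mean disease associations
   per gene on consensus-rank bin validates that the ranking carries
   disease signal.

## Worked example

```r
library(netprior)

cfg <- pipeline_config(seed = 11)   # default synthetic study, published thresholds
res <- run_pipeline(cfg)

res$network
#> <gene_network> 1938 genes, 3682 interactions (score >= 0.63)

res$retained   # the 11 -> 10 collapse drops radiality
#>  [1] "degree"  "closeness"  "betweenness"  "cf_betweenness"  "cf_closeness"
#>  [6] "centroid"  "pagerank"  "vulnerability"  "stress"  "eigenvector"

dplyr::filter(res$precision_table, label == "consensus")
#>   label     fraction  hits total precision
#> 1 consensus     0.02    28    39     71.79
#> 2 consensus     0.05    46    97     47.42
#> 3 consensus     0.07    53   136     38.97
#> 4 consensus     0.10    67   194     34.54

tidy(res$sets)
#>   A 97 | B 150 | C 362 | D 7 | E 46 | F 133 | G 39

glance(res$trend)
#>    slope intercept r_squared n_bins
#> 1 -0.396      4.30     0.936     10
```

Reading: the planted disease genes make up 7.7% of the network, but the
consensus top-2% list is 71.8% disease genes — the hub bias planted by
the generator is exactly what the consensus ranking exploits, and
precision decays as the cutoff loosens (71.8 → 34.5%). Seven genes
satisfy the candidate rule D = (A ∩ C) \\ B. The bin trend (slope −0.40,
R² 0.94) shows mean disease associations per gene falling with consensus
rank, the expected validation signature.

Real data run the same way: put `edges.tsv`, `genes.tsv`, `known.txt`,
`ontology.obo`, `annotations.tsv` (and optionally `associations.tsv`) in
a directory and pass `pipeline_config(input_dir = "dir")`. A thin
command-line dispatcher with per-stage subcommands (simulate,
build-network, topology, centrality, consensus, correlations, enrich,
ora, predict, precision-table, validate-bins, run-all) is installed at
`inst/cli/netprior.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/netprior.R", package="netprior"))')" run-all --seed 11 --out-dir study-out
```

## Package layout

- `R/` — readers (TSV/OBO/GMT), network construction and topology,
  centralities and consensus ranking, enrichment and semantic pruning,
  set-logic prediction and precision tables, rank-bin validation, the
  synthetic generator, and the `run_pipeline()` orchestrator.
- `src/` — Rcpp kernels for stress, centroid and vulnerability.
- `tests/testthat/` — oracle-based unit tests plus an acceptance suite.
- `vignettes/disease-gene-prioritization.Rmd` — the methods vignette:
  model, parameters, numerical choices, generator design, limitations.
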