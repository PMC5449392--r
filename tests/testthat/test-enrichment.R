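test_that("the hypergeometric tail equals exhaustive enumeration in the worked case", {
  fx <- hyper_fixture(N = 10, B = 4, n = 5, b = 3)
  res <- enrich_two_list(fx$target, fx$background, fx$ann, p_threshold = 0.999)
  row <- res[res$term == "H:T", ]
  expect_equal(row$p, 66 / 252, tolerance = 1e-12)   # enumeration: 66 of C(10,5)
  expect_equal(row$p, oracle_hyper_tail(3, 4, 10, 5), tolerance = 1e-12)
  expect_equal(row$enrichment, (3 / 5) / (4 / 10))
})

test_that("the tail probability matches enumeration across small configurations", {
  for (N in c(5, 7, 8)) {
    for (B in seq_len(N - 1)) {
      for (n in seq_len(N - 1)) {
        for (b in seq_len(min(n, B))) {
          if (n - b > N - B) next
          fx <- hyper_fixture(N, B, n, b)
          res <- enrich_two_list(fx$target, fx$background, fx$ann,
                                 p_threshold = 0.999999)
          want <- oracle_hyper_tail(b, B, N, n)
          got <- res$p[res$term == "H:T"]
          if (want >= 0.999999) {
            expect_length(got, 0)  # certain events never pass the threshold
          } else {
            expect_equal(got, want, tolerance = 1e-10,
                         label = sprintf("p(N=%d,B=%d,n=%d,b=%d)", N, B, n, b))
          }
        }
      }
    }
  }
})

test_that("certain events and absent terms never appear as enriched", {
  fx <- hyper_fixture(N = 8, B = 8, n = 4, b = 4)  # b = n, B = N: p = 1
  res <- enrich_two_list(fx$target, fx$background, fx$ann, p_threshold = 0.999)
  expect_equal(nrow(res), 0)
  fx0 <- hyper_fixture(N = 10, B = 3, n = 4, b = 1)
  # target disjoint from the term
  target <- setdiff(fx0$background, sprintf("x%03d", 1:3))[1:4]
  res0 <- enrich_two_list(target, fx0$background, fx0$ann, p_threshold = 0.999)
  expect_equal(nrow(res0), 0)
  expect_error(enrich_two_list(c("nope"), fx0$background, fx0$ann), "subset")
})

test_that("term-size filtering keeps the inclusive bounds", {
  res <- tibble::tibble(term = sprintf("t%d", 1:4), B = c(2, 3, 50, 51))
  expect_equal(filter_by_term_size(res)$B, c(3, 50))
  expect_equal(nrow(filter_by_term_size(res[0, ])), 0)
  expect_equal(filter_by_term_size(res, 1, Inf), res)
  expect_error(filter_by_term_size(res, 10, 5), "exceed")
})

test_that("top-term selection floors per namespace", {
  res <- tibble::tibble(term = sprintf("t%03d", 1:10),
                        namespace = "BP",
                        enrichment = 2,
                        p = seq(1e-6, 1e-3, length.out = 10))
  out <- select_top_terms(res, 0.2)
  expect_equal(out$term, c("t001", "t002"))
  expect_equal(select_top_terms(res, 1.0)$term, res$term)

  big <- tibble::tibble(
    term = sprintf("t%04d", 1:903),
    namespace = rep(c("BP", "MF", "CC"), c(785, 52, 66)),
    enrichment = 1,
    p = runif(903))
  out2 <- select_top_terms(big, 0.2)
  expect_equal(nrow(out2), 157 + 10 + 13)
  expect_error(select_top_terms(res, 0.01), "empty")
})

# corpus giving lin(T:A, T:C) = 2 ln2 / (ln2 + ln(8/3)) ~ 0.83 > 0.7:
# parent A covers 4 of 8 genes, child C covers 3, sibling B the other 4
overlap_annotations <- function(dag) {
  annotations_from_pairs(tibble::tibble(
    gene = c(sprintf("g%d", 1:4), sprintf("g%d", 1:3), sprintf("h%d", 1:4)),
    term = c(rep("T:A", 4), rep("T:C", 3), rep("T:B", 4))), dag)
}

test_that("redundancy pruning keeps the more significant of similar terms", {
  dag <- toy_ontology()
  ann <- overlap_annotations(dag)
  res <- tibble::tibble(term = c("T:C", "T:A"), namespace = "BP",
                        enrichment = c(2, 2), p = c(1e-5, 1e-4))
  out <- prune_redundant_terms(res, dag, ann$ic, sim_threshold = 0.7)
  expect_equal(out$term, "T:C")  # smaller p survives; parent discarded
  # idempotence and subset
  expect_equal(prune_redundant_terms(out, dag, ann$ic), out)

  # all pairwise similarities below an extreme threshold: identity
  expect_equal(nrow(prune_redundant_terms(res, dag, ann$ic, 0.99999)), 2)
  # dissimilar pair (C and B share only the zero-IC root): identity
  none <- tibble::tibble(term = c("T:C", "T:B"), namespace = "BP",
                         enrichment = 1, p = c(1e-5, 1e-4))
  expect_equal(nrow(prune_redundant_terms(none, dag, ann$ic, 0.5)), 2)
})

test_that("a parent-child pair with equal p keeps the more specific child", {
  dag <- toy_ontology()
  ann <- overlap_annotations(dag)
  res <- tibble::tibble(term = c("T:A", "T:C"), namespace = "BP",
                        enrichment = 1, p = c(1e-4, 1e-4))
  out <- prune_redundant_terms(res, dag, ann$ic, sim_threshold = 0.7)
  expect_equal(out$term, "T:C")
})

test_that("terms expand to the union of their genes inside the network", {
  dag <- toy_ontology()
  ann <- annotations_from_pairs(
    tibble::tibble(gene = c("g1", "g2", "g3"), term = c("T:A", "T:A", "T:B")),
    dag)
  ids <- c("g1", "g3", "g9")
  net <- build_network(tibble::tibble(gene_a = c("g1", "g3"),
                                      gene_b = c("g3", "g9"), score = 1),
                       ids, 0)
  one <- tibble::tibble(term = "T:A")
  expect_equal(terms_to_genes(one, ann, net), "g1")
  both <- tibble::tibble(term = c("T:A", "T:B"))
  expect_equal(terms_to_genes(both, ann, net), c("g1", "g3"))
  expect_error(terms_to_genes(tibble::tibble(term = character()), ann, net),
               "no network genes")
})

test_that("gene-set over-representation reports observed > expected below threshold", {
  genes <- sprintf("x%03d", 1:10)
  sets <- list(hit = genes[1:4], miss = c("z1", "z2"))
  query <- c(genes[1:3], genes[5:6])     # b = 3 of the 'hit' set
  res <- geneset_overrepresentation(query, sets, genes, p_threshold = 0.5)
  expect_equal(res$set, "hit")
  expect_equal(res$observed, 3)
  expect_equal(res$expected, 5 * 4 / 10)
  expect_equal(res$p, 66 / 252, tolerance = 1e-12)
  # a set equal to the query dominates every other set
  sets2 <- list(self = query, partial = genes[1:2])
  res2 <- geneset_overrepresentation(query, sets2, genes, p_threshold = 0.9999)
  expect_equal(res2$set[1], "self")
  expect_error(geneset_overrepresentation(c("nope"), sets, genes), "subset")
})
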