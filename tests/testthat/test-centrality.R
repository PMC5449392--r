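cycle_network <- function(n) {
  ids <- sprintf("g%02d", seq_len(n))
  edges <- tibble::tibble(gene_a = ids, gene_b = ids[c(2:n, 1)], score = 1)
  build_network(edges, ids, 0)
}

star_network <- function(leaves = 3) {
  ids <- c("hub", sprintf("leaf%d", seq_len(leaves)))
  edges <- tibble::tibble(gene_a = "hub", gene_b = ids[-1], score = 1)
  build_network(edges, ids, 0)
}

test_that("all measures are constant on a vertex-transitive cycle", {
  cent <- compute_centralities(cycle_network(5))
  for (ms in centrality_measures()) {
    expect_equal(diff(range(cent[[ms]])), 0, tolerance = 1e-9,
                 label = sprintf("spread of %s on C5", ms))
  }
})

test_that("the star centre carries the hand-computed scores", {
  cent <- compute_centralities(star_network(3))
  hub <- cent[cent$gene == "hub", ]
  leaf <- cent[cent$gene != "hub", ]
  expect_equal(hub$degree, 3)
  expect_equal(hub$betweenness, 3)  # C(3,2) leaf pairs
  expect_equal(hub$stress, 3)
  expect_equal(hub$centroid, 2)
  expect_equal(unique(leaf$centroid), -2)
})

test_that("vulnerability matches the hand efficiency computation on the 3-path", {
  ids <- c("a", "b", "c")
  net <- build_network(tibble::tibble(gene_a = c("a", "b"),
                                      gene_b = c("b", "c"), score = 1), ids, 0)
  cent <- compute_centralities(net, "vulnerability")
  vul <- setNames(cent$vulnerability, cent$gene)
  expect_equal(unname(vul["b"]), 1)           # removal disconnects a and c
  expect_equal(unname(vul["a"]), -0.2)        # (5/6 - 1)/(5/6)
  expect_equal(unname(vul["c"]), -0.2)
})

test_that("PageRank sums to one and the eigenvector satisfies its eigen equation", {
  withr::local_seed(31)
  for (i in 1:5) {
    A <- random_connected_adj(sample(5:8, 1))
    net <- adj_to_network(A)
    cent <- compute_centralities(net, c("pagerank", "eigenvector"))
    expect_equal(sum(cent$pagerank), 1, tolerance = 1e-9)
    perm <- adj_perm(A, net)
    v <- cent$eigenvector
    Ap <- A[perm, perm]
    lambda <- as.numeric(v %*% (Ap %*% v))  # Rayleigh quotient, ||v|| = 1
    expect_lt(max(abs(Ap %*% v - lambda * v)), 1e-8)
  }
})

test_that("every measure agrees with its brute-force oracle on random small graphs", {
  withr::local_seed(99)
  for (i in 1:25) {
    n <- sample(3:7, 1)
    A <- random_connected_adj(n)
    net <- adj_to_network(A)
    perm <- adj_perm(A, net)
    cent <- compute_centralities(net)
    D <- floyd_warshall(A)
    bs <- oracle_betweenness_stress(A)
    expect_equal(cent$degree, rowSums(A)[perm], ignore_attr = TRUE)
    expect_equal(cent$closeness, oracle_closeness(D)[perm], tolerance = 1e-12)
    expect_equal(cent$radiality, oracle_radiality(D)[perm], tolerance = 1e-12)
    expect_equal(cent$betweenness, bs$betweenness[perm], tolerance = 1e-9)
    expect_equal(cent$stress, bs$stress[perm], tolerance = 1e-9)
    expect_equal(cent$centroid, oracle_centroid(D)[perm])
    expect_equal(cent$cf_betweenness, oracle_cf_betweenness(A)[perm],
                 tolerance = 1e-9)
    expect_equal(cent$cf_closeness, oracle_cf_closeness(A)[perm],
                 tolerance = 1e-9)
    expect_equal(cent$pagerank, oracle_pagerank(A)[perm], tolerance = 1e-8)
    expect_equal(cent$vulnerability, oracle_vulnerability(A)[perm],
                 tolerance = 1e-10)
    expect_equal(cent$eigenvector, oracle_eigenvector(A)[perm],
                 tolerance = 1e-7)
  }
})

test_that("adding an edge never lowers an endpoint's degree or eigenvector score", {
  withr::local_seed(47)
  for (i in 1:10) {
    n <- sample(5:7, 1)
    A <- random_connected_adj(n, p = 0.4)
    missing <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
    if (nrow(missing) == 0) next
    pick <- missing[sample.int(nrow(missing), 1), ]
    A2 <- A
    A2[pick[1], pick[2]] <- A2[pick[2], pick[1]] <- 1
    for (M in list(A, A2)) {
      net <- adj_to_network(M)
      perm <- order(adj_perm(M, net))
      cent <- compute_centralities(net, c("degree", "eigenvector"))
      if (identical(M, A)) {
        before <- cent[perm, ]
      } else {
        after <- cent[perm, ]
      }
    }
    for (v in pick) {
      expect_gte(after$degree[v], before$degree[v])
      expect_gte(after$eigenvector[v], before$eigenvector[v] - 1e-9)
    }
  }
})

test_that("disconnected graphs are rejected with a measure-specific message", {
  ids <- c("a", "b", "c", "d")
  edges <- tibble::tibble(gene_a = c("a", "c"), gene_b = c("b", "d"), score = 1)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$gene_a, to = edges$gene_b), directed = FALSE)
  net <- netprior:::new_gene_network(g, edges, 0)
  expect_error(compute_centralities(net), "closeness")
  expect_error(compute_centralities(net, "unknown_measure"), "unknown")
})
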