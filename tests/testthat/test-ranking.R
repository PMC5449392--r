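test_that("fractional ranks average over ties and ordinal ranks break them by gene id", {
  sc <- tibble::tibble(gene = c("g1", "g2", "g3"), m = c(5, 5, 1))
  rk <- rank_table(sc)
  expect_equal(rk$fractional$m, c(1.5, 1.5, 3))
  expect_equal(rk$ordinal$m, c(1, 2, 3))

  sc2 <- tibble::tibble(gene = sprintf("g%d", 1:4), m = c(9, 7, 5, 3))
  rk2 <- rank_table(sc2)
  expect_equal(rk2$fractional$m, 1:4, ignore_attr = TRUE)
  expect_equal(rk2$ordinal$m, 1:4)

  sc3 <- tibble::tibble(gene = sprintf("g%d", 1:4), m = rep(2, 4))
  expect_equal(rank_table(sc3)$fractional$m, rep(2.5, 4))

  expect_error(rank_table(tibble::tibble(gene = "a", m = NaN)), "non-finite")
})

test_that("rank-sum invariants hold: fractional sums and ordinal permutations", {
  withr::local_seed(8)
  for (i in 1:10) {
    n <- sample(3:20, 1)
    sc <- tibble::tibble(gene = sprintf("g%03d", 1:n),
                         m = sample(5, n, replace = TRUE) + 0)
    rk <- rank_table(sc)
    expect_equal(sum(rk$fractional$m), n * (n + 1) / 2)
    expect_setequal(rk$ordinal$m, 1:n)
    # higher score => numerically smaller rank
    o <- order(-sc$m, sc$gene)
    expect_equal(rk$ordinal$m[o], 1:n)
  }
})

test_that("spearman_rho reproduces the closed form and the tie-aware correlation", {
  expect_equal(spearman_rho(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 2, 1)), -1)  # sum d^2 = 8
  withr::local_seed(13)
  for (i in 1:10) {
    x <- rank(sample(5, 8, replace = TRUE), ties.method = "average")
    y <- rank(sample(5, 8, replace = TRUE), ties.method = "average")
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_equal(spearman_rho(c(1.5, 1.5, 3), c(1, 2, 3)),
               cor(c(1.5, 1.5, 3), c(1, 2, 3)), tolerance = 1e-12)
  expect_error(spearman_rho(c(2, 2, 2), c(1, 2, 3)), "constant")
})

test_that("tie-free rankings give rho(x, x) = 1 and rho(x, rev x) = -1", {
  withr::local_seed(17)
  for (n in c(2, 5, 9, 20)) {
    x <- sample(n)
    expect_equal(spearman_rho(x, x), 1)
    expect_equal(spearman_rho(x, (n + 1) - x), -1)
  }
})

test_that("perfectly correlated measures collapse, keeping the canonical first", {
  sc <- tibble::tibble(gene = sprintf("g%d", 1:5),
                       degree = c(5, 4, 3, 2, 1),
                       closeness = c(50, 40, 30, 20, 10),   # same ranking
                       radiality = c(5.5, 4.4, 3.3, 2.2, 1.1),  # same again
                       stress = c(1, 3, 5, 2, 4))
  rho <- rank_correlation_matrix(rank_table(sc))
  kept <- prune_redundant_measures(rho)
  expect_equal(kept, c("degree", "stress"))  # triple collapses to its first

  rho_id <- diag(1, 2)
  dimnames(rho_id) <- list(c("a", "b"), c("a", "b"))
  expect_equal(prune_redundant_measures(rho_id), c("a", "b"))
})

test_that("radiality and closeness produce identical ordinal rankings on any connected graph", {
  withr::local_seed(53)
  checked <- 0
  while (checked < 10) {
    A <- random_connected_adj(sample(4:8, 1))
    net <- adj_to_network(A)
    cent <- compute_centralities(net, c("closeness", "radiality"))
    rk <- rank_table(cent)
    expect_equal(rk$ordinal$closeness, rk$ordinal$radiality)
    if (length(unique(cent$closeness)) == 1) next  # correlation undefined
    rho <- rank_correlation_matrix(rk)
    expect_equal(rho["closeness", "radiality"], 1, tolerance = 1e-12)
    expect_equal(prune_redundant_measures(rho), "closeness")
    checked <- checked + 1
  }
})

test_that("consensus ranking sums ordinal ranks and breaks ties by gene id", {
  sc <- tibble::tibble(gene = c("g1", "g2", "g3"),
                       m1 = c(3, 2, 1), m2 = c(2, 3, 1))
  rk <- rank_table(sc)
  cons <- consensus_ranking(rk)
  # ordinal ranks: m1 g1:1 g2:2 g3:3; m2 g2:1 g1:2 g3:3
  expect_equal(cons$gene, c("g1", "g2", "g3"))
  expect_equal(cons$rank_sum, c(3, 3, 6))
  expect_equal(cons$consensus_rank, 1:3)

  single <- consensus_ranking(rk, "m1")
  expect_equal(single$gene[single$consensus_rank],
               rk$ordinal$gene[order(rk$ordinal$m1)])
})

test_that("consensus is invariant under measure-order permutation and dominance", {
  withr::local_seed(61)
  sc <- tibble::tibble(gene = sprintf("g%02d", 1:12),
                       a = runif(12), b = runif(12), c = runif(12))
  sc$a[1] <- 10; sc$b[1] <- 10; sc$c[1] <- 10  # g01 ranked 1 everywhere
  rk <- rank_table(sc)
  c1 <- consensus_ranking(rk, c("a", "b", "c"))
  c2 <- consensus_ranking(rk, c("c", "a", "b"))
  expect_equal(c1$rank_sum, c2$rank_sum)
  expect_equal(c1$gene, c2$gene)
  expect_equal(c1$gene[c1$consensus_rank == 1], "g01")
})

test_that("top-fraction selection sizes follow the policy", {
  ranking <- setNames(1:100, sprintf("g%03d", 1:100))
  expect_length(select_top_fraction(ranking, 0.05), 5)
  expect_length(select_top_fraction(ranking, 1.0), 100)
  expect_equal(select_top_fraction(ranking, 0.03), sprintf("g%03d", 1:3))
  small <- setNames(1:9, sprintf("g%d", 1:9))
  expect_length(select_top_fraction(small, 0.06), 1)   # round(0.54) = 1
  expect_error(select_top_fraction(small, 0.06, policy = "floor"), "empty")
  expect_error(select_top_fraction(small, 0.05), "empty")  # round(0.45) = 0
})
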