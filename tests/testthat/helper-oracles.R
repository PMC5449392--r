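# Brute-force oracles for the centrality suite. Everything here works from
# first principles (adjacency matrices, exhaustive path enumeration, dense
# linear algebra) so it is independent of the package's BFS/Laplacian code
# paths.

# random connected simple graph on n nodes as a 0/1 adjacency matrix
random_connected_adj <- function(n, p = 0.5) {
  repeat {
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- as.numeric(runif(n * (n - 1) / 2) < p)
    A <- A + t(A)
    if (all(floyd_warshall(A) < Inf)) return(A)
  }
}

adj_to_network <- function(A, ids = NULL) {
  n <- nrow(A)
  if (is.null(ids)) ids <- sprintf("g%02d", seq_len(n))
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  edges <- tibble::tibble(gene_a = ids[idx[, 1]], gene_b = ids[idx[, 2]],
                          score = 1)
  build_network(edges, universe = ids, score_cutoff = 0)
}

# network whose vertex order matches the adjacency row order (build_network
# may reorder; recover the permutation)
adj_perm <- function(A, net, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("g%02d", seq_len(nrow(A)))
  match(network_genes(net), ids)
}

floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  for (k in 1:n)
    for (i in 1:n)
      for (j in 1:n)
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# all shortest paths between s and t by exhaustive DFS over simple paths
all_shortest_paths_enum <- function(A, s, t, D = floyd_warshall(A)) {
  target_len <- D[s, t]
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      if (length(path) - 1 == target_len) paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    if (length(path) - 1 >= target_len) return(invisible())
    for (w in which(A[v, ] > 0)) {
      if (!(w %in% path)) walk(c(path, w))
    }
  }
  walk(s)
  paths
}

# shortest-path betweenness and stress over unordered pairs, by enumeration
oracle_betweenness_stress <- function(A) {
  n <- nrow(A)
  D <- floyd_warshall(A)
  btw <- numeric(n)
  str <- numeric(n)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_shortest_paths_enum(A, s, t, D)
      sigma <- length(paths)
      if (sigma == 0) next
      inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      through <- tabulate(inner, nbins = n)
      btw <- btw + through / sigma
      str <- str + through
    }
  }
  list(betweenness = btw, stress = str)
}

oracle_closeness <- function(D) (nrow(D) - 1) / rowSums(D)

oracle_radiality <- function(D) {
  n <- nrow(D)
  diam <- max(D)
  vapply(1:n, function(v) sum(diam + 1 - D[v, -v]) / (n - 1), 1)
}

oracle_centroid <- function(D) {
  n <- nrow(D)
  vapply(1:n, function(v) {
    min(vapply(setdiff(1:n, v), function(u) {
      w <- setdiff(1:n, c(u, v))
      sum(D[w, v] < D[w, u]) - sum(D[w, u] < D[w, v])
    }, 1))
  }, 1)
}

oracle_eigenvector <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  v <- v / sqrt(sum(v^2))
  if (sum(v) < 0) v <- -v
  abs(v)
}

oracle_pagerank <- function(A, d = 0.85) {
  n <- nrow(A)
  M <- t(A / rowSums(A))
  solve(diag(n) - d * M, rep((1 - d) / n, n))
}

# unit-current potentials for source s, sink t (ground the sink)
current_potentials <- function(A, s, t) {
  n <- nrow(A)
  L <- diag(rowSums(A)) - A
  phi <- numeric(n)
  free <- setdiff(1:n, t)
  rhs <- numeric(n)
  rhs[s] <- 1
  phi[free] <- solve(L[free, free], rhs[free])
  phi
}

oracle_cf_betweenness <- function(A) {
  n <- nrow(A)
  raw <- numeric(n)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      phi <- current_potentials(A, s, t)
      for (v in 1:n) {
        if (v == s || v == t) {
          raw[v] <- raw[v] + 1
        } else {
          raw[v] <- raw[v] + sum(abs(phi[v] - phi[A[v, ] > 0])) / 2
        }
      }
    }
  }
  raw / (n * (n - 1) / 2)
}

oracle_cf_closeness <- function(A) {
  n <- nrow(A)
  vapply(1:n, function(v) {
    rsum <- sum(vapply(setdiff(1:n, v), function(t) {
      phi <- current_potentials(A, v, t)
      phi[v] - phi[t]
    }, 1))
    (n - 1) / rsum
  }, 1)
}

global_efficiency_of <- function(D) {
  iD <- 1 / D
  diag(iD) <- 0
  iD[is.infinite(D)] <- 0
  sum(iD) / (nrow(D) * (nrow(D) - 1))
}

oracle_vulnerability <- function(A) {
  n <- nrow(A)
  E <- global_efficiency_of(floyd_warshall(A))
  vapply(1:n, function(v) {
    Ev <- global_efficiency_of(floyd_warshall(A[-v, -v, drop = FALSE]))
    (E - Ev) / E
  }, 1)
}

# exact hypergeometric upper tail by exhaustive enumeration of draws
oracle_hyper_tail <- function(b, B, N, n) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= B)  # successes are items 1..B
  mean(hits >= b)
}

# tiny ontology written through the OBO round trip
toy_ontology <- function() {
  obo <- c(
    "format-version: 1.2", "",
    "[Term]", "id: T:R", "name: root", "namespace: biological_process", "",
    "[Term]", "id: T:A", "name: a", "namespace: biological_process",
    "is_a: T:R ! root", "",
    "[Term]", "id: T:B", "name: b", "namespace: biological_process",
    "is_a: T:R ! root", "",
    "[Term]", "id: T:C", "name: c", "namespace: biological_process",
    "is_a: T:A ! a", "",
    "[Term]", "id: T:M", "name: m-root", "namespace: molecular_function", ""
  )
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(obo, path)
  read_obo(path)
}

annotations_from_pairs <- function(pairs, dag) {
  netprior:::build_annotation_map(pairs, dag)
}

# single-term ontology plus gene sets realizing given (N, B, n, b) counts
hyper_fixture <- function(N, B, n, b) {
  obo <- c("[Term]", "id: H:R", "name: r", "namespace: biological_process", "",
           "[Term]", "id: H:T", "name: t", "namespace: biological_process",
           "is_a: H:R", "")
  tf <- withr::local_tempfile(fileext = ".obo", .local_envir = parent.frame())
  writeLines(obo, tf)
  dag <- read_obo(tf)
  genes <- sprintf("x%03d", seq_len(N))
  term_members <- genes[seq_len(B)]
  target <- c(genes[seq_len(b)], genes[(B + 1):N][seq_len(n - b)])
  ann <- annotations_from_pairs(
    tibble::tibble(gene = term_members, term = "H:T"), dag)
  list(target = target, background = genes, ann = ann)
}

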