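# Independent brute-force references used to check the graph-metric and PNN
# implementations. These deliberately avoid igraph and the package's own code:
# distances come from Floyd-Warshall on the raw adjacency matrix, neighbour
# edge counts from explicit pair loops.

floyd_warshall <- function(A) {
  R <- nrow(A)
  D <- matrix(Inf, R, R)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(R)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

oracle_metrics <- function(A) {
  A <- (as.matrix(A) != 0) * 1L
  R <- nrow(A)
  deg <- rowSums(A)
  D <- floyd_warshall(A)
  Ds <- D
  Ds[is.infinite(Ds)] <- R
  clus <- leff_sub <- leff_glob <- numeric(R)
  for (i in seq_len(R)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    e <- 0
    for (a in 1:(k - 1)) for (b in (a + 1):k) e <- e + A[nb[a], nb[b]]
    clus[i] <- 2 * e / (k * (k - 1))
    Dsub <- floyd_warshall(A[nb, nb, drop = FALSE])
    s <- 1 / Dsub; s[!is.finite(s)] <- 0; diag(s) <- 0
    leff_sub[i] <- sum(s) / (k * (k - 1))
    g <- 1 / D[nb, nb, drop = FALSE]; g[!is.finite(g)] <- 0; diag(g) <- 0
    leff_glob[i] <- sum(g) / (k * (k - 1))
  }
  list(degree = deg, clustering = clus, shortest_path = Ds,
       local_eff_subgraph = leff_sub, local_eff_global = leff_glob)
}

rand_adjacency <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(runif(n * (n - 1) / 2) < p)
  A + t(A)
}

expect_metrics_match_oracle <- function(A) {
  M <- graph_metrics(A)
  O <- oracle_metrics(A)
  expect_equal(M$degree, as.integer(O$degree))
  expect_equal(M$clustering, O$clustering, tolerance = 1e-12)
  expect_equal(unname(M$shortest_path), unname(O$shortest_path))
  expect_equal(M$local_efficiency, O$local_eff_subgraph, tolerance = 1e-12)
  Mg <- graph_metrics(A, local_distances = "global")
  expect_equal(Mg$local_efficiency, O$local_eff_global, tolerance = 1e-12)
}

# Direct Gaussian kernel-sum PNN reference (no log-space tricks).
oracle_pnn_predict <- function(train_x, train_y, query, sigma) {
  lev <- levels(train_y)
  scores <- vapply(lev, function(cl) {
    P <- train_x[train_y == cl, , drop = FALSE]
    mean(exp(-rowSums((P - matrix(query, nrow(P), length(query),
                                  byrow = TRUE))^2) / sigma^2))
  }, 0)
  lev[which.max(scores)]
}

# Small planted cohort shared by several tests.
toy_cohort_table <- function(seed, n_per_group = 20, R = 10, n_tp = 150,
                             delta = 0.6) {
  spec <- cohort_spec(n_per_group, n_regions = R, n_timepoints = n_tp,
                      planted_pairs = list(c(1, 2), c(3, 4)),
                      delta_rho = delta, base_rho = 0.1, seed = seed)
  extract_cohort_features(generate_cohort(spec), 0.25)
}
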