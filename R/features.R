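#' Pearson functional-connectivity matrix of an ROI time-series matrix
#'
#' @param ts T-by-R numeric matrix, one column per region (T >= 3, R >= 2).
#' @return R-by-R symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop_ctx("need at least 3 time points, got %d", nrow(ts))
  if (ncol(ts) < 2) stop_ctx("need at least 2 regions, got %d", ncol(ts))
  if (anyNA(ts)) stop_ctx("time series contains missing values")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop_ctx("region(s) %s have constant time series; correlation undefined",
             paste(bad, collapse = ", "))
  }
  C <- cor(ts)
  diag(C) <- 1
  C
}

#' Threshold a connectivity matrix into a binary brain graph
#'
#' An (undirected, unweighted) edge links regions i and j iff
#' `|r_ij| > threshold` — strictly, so boundary correlations are excluded —
#' and the diagonal is removed.
#'
#' @param C Correlation matrix from [correlation_matrix()].
#' @param threshold Edge threshold in `[0, 1)` (default 0.25).
#' @return An object of class `brain_graph` (binary adjacency + threshold).
#' @export
binarize <- function(C, threshold = 0.25) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold >= 1)
    stop_ctx("threshold must be a single value in [0, 1)")
  A <- (abs(C) > threshold) * 1L
  diag(A) <- 0L
  A <- ((A + t(A)) > 0) * 1L   # guard symmetry against numeric asymmetry
  structure(list(adjacency = A, threshold = threshold), class = "brain_graph")
}

#' Nodal and pairwise graph metrics of a binary brain graph
#'
#' Computes, for every region: degree N_i; clustering coefficient
#' C_i = 2e / (N_i (N_i - 1)) with e the number of edges among the neighbours
#' of i; all-pairs shortest-path hop counts d_ij; and local efficiency
#' E(i) = (1 / (N_i (N_i - 1))) * sum over ordered neighbour pairs (j, l) of
#' 1 / d_jl, with d_jl measured inside the subgraph induced by the
#' neighbourhood V_i (Latora–Marchiori form). Nodes with fewer than two
#' neighbours get C_i = E(i) = 0. Disconnected pairs have no finite hop
#' distance; their d_ij is recorded as the sentinel R (one more than the
#' largest possible hop count) and they contribute 0 to local efficiency.
#'
#' @param G A [binarize()] result (or a binary adjacency matrix).
#' @param local_distances `"subgraph"` (default) measures local-efficiency
#'   distances in the neighbour-induced subgraph; `"global"` uses distances
#'   from the full graph.
#' @return A list of class `graph_metrics` with `degree`, `clustering`,
#'   `shortest_path`, `local_efficiency`, and `n_regions`.
#' @export
graph_metrics <- function(G, local_distances = c("subgraph", "global")) {
  local_distances <- match.arg(local_distances)
  A <- if (inherits(G, "brain_graph")) G$adjacency else (as.matrix(G) != 0) * 1L
  R <- nrow(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  deg <- as.integer(rowSums(A))

  D <- igraph::distances(g)          # unweighted hop counts, Inf if disconnected
  Dfeat <- D
  Dfeat[is.infinite(Dfeat)] <- R     # sentinel: one more than max possible hops

  clus <- numeric(R)
  leff <- numeric(R)
  for (i in seq_len(R)) {
    if (deg[i] < 2) next
    nb <- which(A[i, ] == 1)
    e <- sum(A[nb, nb]) / 2
    clus[i] <- 2 * e / (deg[i] * (deg[i] - 1))
    Dnb <- if (local_distances == "subgraph") {
      sg <- igraph::induced_subgraph(g, nb)
      igraph::distances(sg)
    } else {
      D[nb, nb, drop = FALSE]
    }
    inv <- 1 / Dnb
    inv[!is.finite(inv)] <- 0        # disconnected neighbour pairs contribute 0
    diag(inv) <- 0
    leff[i] <- sum(inv) / (deg[i] * (deg[i] - 1))
  }
  structure(list(degree = deg, clustering = clus, shortest_path = Dfeat,
                 local_efficiency = leff, n_regions = R),
            class = "graph_metrics")
}

#' Layout map of the connectome feature vector
#'
#' The feature vector concatenates, in order: R degrees, R clustering
#' coefficients, the R(R-1)/2 upper-triangle shortest-path lengths in
#' row-major order (pair (1,2), (1,3), ..., (2,3), ...), and R local
#' efficiencies — 4275 features for the 90-region AAL parcellation. The map
#' is a bijection between feature index and (indicator, region or pair).
#'
#' @param n_regions Number of regions R.
#' @return Data frame with columns `index`, `indicator`, `region1`, `region2`
#'   (`region2` is `NA` for nodal features).
#' @export
feature_layout <- function(n_regions) {
  R <- as.integer(n_regions)
  pairs <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]  # row-major
  layout <- rbind(
    data.frame(indicator = "degree", region1 = seq_len(R), region2 = NA_integer_),
    data.frame(indicator = "clustering", region1 = seq_len(R), region2 = NA_integer_),
    data.frame(indicator = "shortest_path", region1 = as.integer(pairs[, 1]),
               region2 = as.integer(pairs[, 2])),
    data.frame(indicator = "local_efficiency", region1 = seq_len(R),
               region2 = NA_integer_))
  layout <- cbind(index = seq_len(nrow(layout)), layout)
  rownames(layout) <- NULL
  layout
}

#' Flatten graph metrics into the canonical feature vector
#'
#' @param M A [graph_metrics()] result.
#' @return Numeric vector of length `3R + R(R-1)/2` following the
#'   [feature_layout()] order.
#' @export
assemble_features <- function(M) {
  stopifnot(inherits(M, "graph_metrics"))
  R <- M$n_regions
  ut <- t(M$shortest_path)[lower.tri(M$shortest_path)]  # row-major upper tri
  c(M$degree, M$clustering, ut, M$local_efficiency)
}

#' Extract the full connectome feature table for a cohort
#'
#' Runs [correlation_matrix()], [binarize()], [graph_metrics()] and
#' [assemble_features()] for every subject, preserving manifest order.
#'
#' @param subjects List of subject records (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param threshold Edge threshold passed to [binarize()].
#' @param local_distances Passed to [graph_metrics()].
#' @return A [feature_table()] with the layout map attached.
#' @export
extract_cohort_features <- function(subjects, threshold = 0.25,
                                    local_distances = "subgraph") {
  if (length(subjects) == 0) {
    return(feature_table(matrix(numeric(0), 0, 0), factor(character(0)),
                         layout = NULL, subject_ids = character(0)))
  }
  Rs <- vapply(subjects, function(s) ncol(s$timeseries), 0L)
  if (length(unique(Rs)) != 1)
    stop_ctx("subjects have differing region counts: %s",
             paste(unique(Rs), collapse = ", "))
  R <- Rs[1]
  layout <- feature_layout(R)
  rows <- lapply(subjects, function(s) {
    tryCatch({
      M <- graph_metrics(binarize(correlation_matrix(s$timeseries), threshold),
                         local_distances = local_distances)
      assemble_features(M)
    }, error = function(e) {
      stop_ctx("subject %s: %s", s$subject_id, conditionMessage(e))
    })
  })
  x <- do.call(rbind, rows)
  colnames(x) <- sprintf("%s_%s", substr(layout$indicator, 1, 4),
                         ifelse(is.na(layout$region2),
                                sprintf("%03d", layout$region1),
                                sprintf("%03d_%03d", layout$region1,
                                        layout$region2)))
  labs <- vapply(subjects, function(s) as.character(s$label), "")
  lev <- if (all(labs %in% c("control", "case"))) c("control", "case")
         else unique(labs)
  feature_table(x, factor(labs, levels = lev), layout,
                vapply(subjects, function(s) s$subject_id, ""))
}
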