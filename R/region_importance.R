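#' Map a feature index back to its brain region(s)
#'
#' Nodal features (degree, clustering, local efficiency) map to one region;
#' shortest-path features map to their unordered region pair.
#'
#' @param index Feature index (1-based).
#' @param layout Layout map from [feature_layout()].
#' @return Integer vector of 1 or 2 region indices.
#' @export
feature_to_regions <- function(index, layout) {
  if (length(index) != 1 || is.na(index) || index < 1 || index > nrow(layout))
    stop_ctx("feature index %s out of range 1..%d",
             as.character(index)[1], nrow(layout))
  row <- layout[index, ]
  if (is.na(row$region2)) row$region1 else c(row$region1, row$region2)
}

#' Region importance weights from selected features
#'
#' Each selected nodal feature adds 1 to its region's weight; each selected
#' pair (shortest-path) feature adds 1 to both endpoint regions. Regions
#' touched by no selected feature keep weight 0, so
#' `sum(weights) == n_nodal_selected + 2 * n_pair_selected`.
#'
#' @param selected Integer vector of selected feature indices.
#' @param layout Layout map from [feature_layout()].
#' @param labels Optional region label table (see [read_region_labels()]).
#' @return Data frame (`region`, `abbrev`, `name`, `weight`) sorted by
#'   decreasing weight, ties by region index.
#' @export
region_weights <- function(selected, layout, labels = NULL) {
  R <- max(layout$region1, layout$region2, na.rm = TRUE)
  selected <- as.integer(selected)
  if (length(selected) && (any(selected < 1) || any(selected > nrow(layout))))
    stop_ctx("selected indices must lie in 1..%d", nrow(layout))
  w <- integer(R)
  for (i in selected) {
    for (r in feature_to_regions(i, layout)) w[r] <- w[r] + 1L
  }
  if (is.null(labels)) {
    labels <- data.frame(index = seq_len(R),
                         abbrev = sprintf("R%03d", seq_len(R)),
                         name = sprintf("region %d", seq_len(R)))
  }
  out <- data.frame(region = seq_len(R),
                    abbrev = labels$abbrev[seq_len(R)],
                    name = labels$name[seq_len(R)],
                    weight = w, stringsAsFactors = FALSE)
  out <- out[order(-out$weight, out$region), ]
  rownames(out) <- NULL
  out
}

#' Filter a region weight table at a minimum weight
#'
#' The cut is inclusive (`weight >= min_weight`), matching how reported
#' region tables list the boundary weight itself.
#'
#' @param table A [region_weights()] table.
#' @param min_weight Non-negative integer cut.
#' @return The filtered table, descending by weight.
#' @export
rank_regions <- function(table, min_weight = 0) {
  if (min_weight < 0) stop_ctx("min_weight must be >= 0")
  out <- table[table$weight >= min_weight, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a region label table (AAL-90 by default)
#'
#' @param path CSV with columns `index`, `abbrev`, `name`; defaults to the
#'   AAL-90 table shipped with the package (1-based AAL numbering, odd = left
#'   hemisphere).
#' @return Data frame of region labels.
#' @export
read_region_labels <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "aal90_labels.csv", package = "rnnclust")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Pearson chi-square test on a 2x2 sex table
#'
#' No continuity correction (1 df), as used for case/control sex balance.
#'
#' @param tab 2x2 matrix of non-negative counts with positive margins.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
sex_chisq <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop_ctx("need a 2x2 table")
  if (any(tab < 0)) stop_ctx("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_ctx("a margin of the table is zero")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Pooled two-sample t test from summary statistics
#'
#' For group age comparisons reported as mean +/- SD: pooled-variance t with
#' `n1 + n2 - 2` degrees of freedom, two-sided.
#'
#' @param mean1,sd1,n1 First group summary (sd > 0, n >= 2).
#' @param mean2,sd2,n2 Second group summary.
#' @return List with `t`, `df` and `p_value`.
#' @export
age_ttest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) stop_ctx("standard deviations must be positive")
  if (n1 < 2 || n2 < 2) stop_ctx("each group needs n >= 2")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Summarise a cohort's demographics
#'
#' @param labels Factor of class labels.
#' @param sex Factor/character of sex per subject (optional).
#' @param age Numeric age per subject (optional).
#' @return List of class `cohort_summary` with per-group n, sex counts and
#'   age mean/sd.
#' @export
cohort_summary <- function(labels, sex = NULL, age = NULL) {
  labels <- as.factor(labels)
  out <- list(n = as.list(table(labels)))
  if (!is.null(sex)) out$sex <- table(labels, sex)
  if (!is.null(age)) {
    out$age <- lapply(split(age, labels), function(a)
      list(mean = mean(a), sd = stats::sd(a)))
  }
  structure(out, class = "cohort_summary")
}
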