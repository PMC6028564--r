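#' Configuration of a random neural network cluster
#'
#' The ensemble trains `k` base classifiers, each on its own random subsample
#' of `n_sub` training subjects and `m_feat` features (both without
#' replacement), and combines their predictions by majority vote. Defaults
#' follow the reference protocol: 1000 members, 70 subjects and 120 features
#' per member, an 8:2 train/test split and a 0.6 per-member accuracy cut for
#' calling a member significant.
#'
#' @param k Number of ensemble members.
#' @param n_sub Subjects sampled (without replacement) per member.
#' @param m_feat Features sampled (without replacement) per member.
#' @param base_kind Base classifier: `"bp"`, `"pnn"`, `"competitive"`,
#'   `"lvq"` or `"elman"`.
#' @param split_ratio Training fraction of the cohort.
#' @param sig_threshold Per-member accuracy cut (strict `>`) for the
#'   significant-member selection.
#' @param seed Integer base seed; member seeds are derived from it with
#'   [derive_seed()].
#' @param nn A [train_config()] for the base classifiers (its `seed` is
#'   overridden per member).
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(k = 1000, n_sub = 70, m_feat = 120,
                           base_kind = c("elman", "bp", "pnn", "competitive",
                                         "lvq"),
                           split_ratio = 0.8, sig_threshold = 0.6,
                           seed = 1L, nn = train_config()) {
  if (!is_count(k)) stop_ctx("k must be a positive integer")
  if (!is_count(n_sub)) stop_ctx("n_sub must be a positive integer")
  if (!is_count(m_feat)) stop_ctx("m_feat must be a positive integer")
  if (split_ratio <= 0 || split_ratio >= 1)
    stop_ctx("split_ratio must be in (0, 1)")
  if (sig_threshold < 0 || sig_threshold > 1)
    stop_ctx("sig_threshold must be in [0, 1]")
  structure(list(k = as.integer(k), n_sub = as.integer(n_sub),
                 m_feat = as.integer(m_feat),
                 base_kind = match.arg(base_kind),
                 split_ratio = split_ratio, sig_threshold = sig_threshold,
                 seed = as.integer(seed), nn = nn),
            class = "cluster_config")
}

#' Stratified train/test split of a feature table
#'
#' Per class, `floor(ratio * n_class)` subjects go to training (seeded
#' sampling without replacement), the remainder to test; sides are disjoint
#' and exhaustive. A 92-subject cohort at ratio 0.8 yields 73 training and
#' 19 test subjects.
#'
#' @param ft A [feature_table()] with labels.
#' @param ratio Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` feature tables.
#' @export
split_train_test <- function(ft, ratio = 0.8, seed = 1L) {
  stopifnot(inherits(ft, "feature_table"))
  if (ratio <= 0 || ratio >= 1) stop_ctx("ratio must be in (0, 1)")
  if (any(table(ft$labels) < 2))
    stop_ctx("need at least 2 subjects per class to split")
  idx_train <- with_seed(seed, {
    unlist(lapply(levels(ft$labels), function(cl) {
      i <- which(ft$labels == cl)
      n_tr <- floor(ratio * length(i))
      sort(sample(i, n_tr))
    }))
  })
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_along(ft$labels), idx_train)
  tr <- subset_table(ft, rows = idx_train)
  te <- subset_table(ft, rows = idx_test)
  if (nlevels(droplevels(tr$labels)) < nlevels(ft$labels) ||
      nlevels(droplevels(te$labels)) < nlevels(ft$labels))
    stop_ctx("a class is absent from one side of the split at ratio %g", ratio)
  list(train = tr, test = te)
}

#' Build a random neural network cluster
#'
#' Trains `cfg$k` independent base classifiers, each on a seeded random
#' subsample of `n_sub` training subjects and `m_feat` features (both without
#' replacement). Members whose training fails are flagged, excluded from
#' voting, and counted in a warning.
#'
#' @param train Training [feature_table()].
#' @param cfg A [cluster_config()].
#' @return An object of class `nn_cluster`.
#' @export
build_cluster <- function(train, cfg) {
  stopifnot(inherits(train, "feature_table"), inherits(cfg, "cluster_config"))
  N <- nrow(train$x); M <- ncol(train$x)
  if (cfg$n_sub > N) stop_ctx("n_sub (%d) exceeds training size (%d)",
                              cfg$n_sub, N)
  if (cfg$m_feat > M) stop_ctx("m_feat (%d) exceeds feature count (%d)",
                               cfg$m_feat, M)
  members <- vector("list", cfg$k)
  n_failed <- 0L
  for (i in seq_len(cfg$k)) {
    mseed <- derive_seed(cfg$seed, i)
    samp <- with_seed(mseed, {
      list(subj = sort(sample(N, cfg$n_sub)),
           feat = sort(sample(M, cfg$m_feat)))
    })
    nn_cfg <- cfg$nn
    nn_cfg$seed <- derive_seed(mseed, 1L)
    model <- tryCatch(
      fit_base(cfg$base_kind, train$x[samp$subj, samp$feat, drop = FALSE],
               droplevels(train$labels[samp$subj]), nn_cfg),
      error = function(e) e)
    ok <- !inherits(model, "error")
    if (!ok) n_failed <- n_failed + 1L
    members[[i]] <- list(subjects = samp$subj, features = samp$feat,
                         model = if (ok) model else NULL, seed = mseed,
                         ok = ok,
                         failure = if (ok) NULL else conditionMessage(model))
  }
  if (n_failed > 0)
    warning(sprintf("%d of %d members failed to train and are excluded",
                    n_failed, cfg$k), call. = FALSE)
  structure(list(members = members, config = cfg,
                 n_features = M, levels = levels(train$labels),
                 layout = train$layout, n_failed = n_failed),
            class = "nn_cluster")
}

#' Majority vote over member predictions for one subject
#'
#' @param votes Vector of predicted labels.
#' @param levels Label levels; ties break toward the class listed first and
#'   the result carries attribute `tie = TRUE`.
#' @return The winning label (factor of length 1).
#' @export
majority_vote <- function(votes, levels = NULL) {
  votes <- as.character(votes)
  if (length(votes) == 0) stop_ctx("majority_vote needs at least one vote")
  if (is.null(levels)) levels <- unique(votes)
  counts <- vapply(levels, function(l) sum(votes == l), 0L)
  top <- which(counts == max(counts))
  out <- factor(levels[top[1]], levels = levels)
  attr(out, "tie") <- length(top) > 1
  out
}

member_votes <- function(cluster, X) {
  ok <- which(vapply(cluster$members, function(m) m$ok, TRUE))
  if (length(ok) == 0) stop_ctx("no trained members available")
  votes <- matrix(NA_character_, length(ok), nrow(X))
  for (j in seq_along(ok)) {
    m <- cluster$members[[ok[j]]]
    votes[j, ] <- as.character(predict(m$model,
                                       X[, m$features, drop = FALSE]))
  }
  votes
}

#' Predict labels with the ensemble (majority vote)
#'
#' @param object An [build_cluster()] result.
#' @param newdata Feature matrix or [feature_table()] aligned with training
#'   layout.
#' @param ... Unused.
#' @return Factor of predicted labels; attribute `ties` flags subjects whose
#'   vote was tied.
#' @export
predict.nn_cluster <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table")) newdata$x else as.matrix(newdata)
  if (ncol(X) != object$n_features)
    stop_ctx("cluster expects %d features, got %d", object$n_features, ncol(X))
  votes <- member_votes(object, X)
  res <- apply(votes, 2, majority_vote, levels = object$levels,
               simplify = FALSE)
  out <- factor(vapply(res, as.character, ""), levels = object$levels)
  attr(out, "ties") <- vapply(res, attr, TRUE, "tie")
  out
}

#' Ensemble accuracy on a labelled test table
#'
#' Fraction of test subjects whose majority-vote label matches the truth.
#'
#' @param cluster An `nn_cluster`.
#' @param test Test [feature_table()].
#' @return Fraction in `[0, 1]`.
#' @export
ensemble_accuracy <- function(cluster, test) {
  p <- predict(cluster, test)
  mean(as.character(p) == as.character(test$labels))
}

#' Per-member test accuracies
#'
#' @inheritParams ensemble_accuracy
#' @return Numeric vector of length `k`; `NA` for failed members.
#' @export
member_accuracies <- function(cluster, test) {
  vapply(cluster$members, function(m) {
    if (!m$ok) return(NA_real_)
    accuracy(m$model, test$x[, m$features, drop = FALSE], test$labels)
  }, 0)
}

#' Select the significant members of a cluster
#'
#' Members whose individual test accuracy is strictly greater than the
#' threshold; the set may be empty.
#'
#' @inheritParams ensemble_accuracy
#' @param threshold Accuracy cut (default the config's `sig_threshold`).
#' @return List with `indices` and their `accuracies`.
#' @export
select_significant <- function(cluster, test, threshold = NULL) {
  if (is.null(threshold)) threshold <- cluster$config$sig_threshold
  acc <- member_accuracies(cluster, test)
  idx <- which(!is.na(acc) & acc > threshold)
  list(indices = idx, accuracies = acc[idx])
}

#' Feature sampling frequencies among significant members
#'
#' Counts, for every feature, how many of the given members sampled it. The
#' counts obey the conservation identity
#' `sum(counts) == length(members) * m_feat`.
#'
#' @param cluster An `nn_cluster`.
#' @param member_indices Indices of the (significant) members to count over.
#' @return Integer vector of per-feature counts.
#' @export
feature_frequencies <- function(cluster, member_indices) {
  counts <- integer(cluster$n_features)
  for (i in member_indices) {
    f <- cluster$members[[i]]$features
    counts[f] <- counts[f] + 1L
  }
  counts
}

#' Top-m features by sampling frequency
#'
#' @param counts Integer counts from [feature_frequencies()].
#' @param m Number of features to keep.
#' @return Integer vector of `m` feature indices, highest counts first; ties
#'   at the cut break by ascending feature index.
#' @export
top_features <- function(counts, m) {
  if (m > length(counts)) stop_ctx("m (%d) exceeds feature count (%d)",
                                   m, length(counts))
  order(-counts, seq_along(counts))[seq_len(m)]
}

#' Choose the optimal number of significant features
#'
#' Builds a cluster on the training set, ranks features by their frequency
#' among significant members, then for every candidate count rebuilds the
#' cluster restricted to the top-ranked features `reps` times (distinct
#' derived seeds) and scores it on the test set. The chosen count has the
#' highest mean accuracy; ties break toward lower standard deviation, then
#' the smaller count (the stability rule).
#'
#' @param train,test Feature tables from [split_train_test()].
#' @param cfg A [cluster_config()].
#' @param candidates Integer vector of feature counts to try.
#' @param reps Repetitions per candidate (>= 1).
#' @return List with `best` (the chosen count) and `profile` (a data frame
#'   of candidate, mean_accuracy, sd_accuracy).
#' @export
optimal_feature_count <- function(train, test, cfg, candidates, reps = 3) {
  if (length(candidates) == 0) stop_ctx("candidates must be non-empty")
  if (!is_count(reps)) stop_ctx("reps must be a positive integer")
  if (any(candidates > ncol(train$x)))
    stop_ctx("candidates exceed the feature count (%d)", ncol(train$x))
  base <- build_cluster(train, cfg)
  sig <- select_significant(base, test)
  counts <- feature_frequencies(base, sig$indices)
  prof <- lapply(seq_along(candidates), function(ci) {
    m_star <- candidates[ci]
    keep <- top_features(counts, m_star)
    tr <- subset_table(train, cols = keep)
    te <- subset_table(test, cols = keep)
    acc <- vapply(seq_len(reps), function(r) {
      cfg_r <- cfg
      cfg_r$seed <- derive_seed(cfg$seed, 1000L * ci + r)
      cfg_r$m_feat <- min(cfg$m_feat, m_star)
      ensemble_accuracy(build_cluster(tr, cfg_r), te)
    }, 0)
    c(mean = mean(acc), sd = stats::sd(acc))
  })
  profile <- data.frame(candidate = as.integer(candidates),
                        mean_accuracy = vapply(prof, `[[`, 0, "mean"),
                        sd_accuracy = vapply(prof, `[[`, 0, "sd"))
  profile$sd_accuracy[is.na(profile$sd_accuracy)] <- 0
  ord <- order(-profile$mean_accuracy, profile$sd_accuracy, profile$candidate)
  list(best = profile$candidate[ord[1]], profile = profile,
       frequencies = counts, significant = sig)
}
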