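mk_table <- function(seed = 1, n_per = 20, p = 40, effect = 2.5) {
  generate_feature_table(n_per, p, planted_features = seq_len(min(5, p)),
                         effect_size = effect, seed = seed)
}

fast_cfg <- function(seed, k = 10, n_sub = 20, m_feat = 15,
                     base = "bp", ...) {
  cluster_config(k = k, n_sub = n_sub, m_feat = m_feat, base_kind = base,
                 seed = seed,
                 nn = train_config(epochs = 100, seed = seed, ...))
}

test_that("the train/test split is stratified, disjoint and exhaustive", {
  # 92 subjects, 50/42: 8:2 gives 73 train / 19 test
  x <- matrix(rnorm(92 * 4), 92, 4)
  labs <- factor(rep(c("case", "control"), c(50, 42)),
                 levels = c("control", "case"))
  ft <- feature_table(x, labs)
  sp <- split_train_test(ft, 0.8, seed = 3)
  expect_equal(nrow(sp$train$x), 73)
  expect_equal(nrow(sp$test$x), 19)
  expect_equal(as.vector(table(sp$train$labels)), c(floor(0.8 * 42),
                                                    floor(0.8 * 50)))
  expect_equal(sort(c(sp$train$subject_ids, sp$test$subject_ids)),
               sort(ft$subject_ids))
  # N = 10 at 0.8 -> 8/2; same seed reproduces the split exactly
  ft10 <- mk_table(2, n_per = 5, p = 3)
  s1 <- split_train_test(ft10, 0.8, seed = 9)
  s2 <- split_train_test(ft10, 0.8, seed = 9)
  expect_equal(nrow(s1$train$x), 8)
  expect_equal(nrow(s1$test$x), 2)
  expect_identical(s1$train$subject_ids, s2$train$subject_ids)
  # a ratio that empties one side of a class errors
  ft_im <- feature_table(matrix(rnorm(40), 10, 4),
                         factor(rep(c("a", "b"), c(2, 8))))
  expect_error(split_train_test(ft_im, 0.3, seed = 1), "absent")
})

test_that("a single-member cluster is equivalent to its base classifier", {
  ft <- mk_table(5)
  sp <- split_train_test(ft, 0.8, seed = 5)
  cl <- build_cluster(sp$train, fast_cfg(5, k = 1))
  mb <- cl$members[[1]]
  solo <- predict(mb$model, sp$test$x[, mb$features, drop = FALSE])
  expect_equal(as.character(predict(cl, sp$test)), as.character(solo))
  expect_equal(ensemble_accuracy(cl, sp$test),
               accuracy(mb$model, sp$test$x[, mb$features, drop = FALSE],
                        sp$test$labels))
})

test_that("member subsampling honours the without-replacement contract and the seed", {
  ft <- mk_table(6)
  sp <- split_train_test(ft, 0.8, seed = 6)
  cfg <- fast_cfg(6, k = 10)
  cl <- build_cluster(sp$train, cfg)
  for (m in cl$members) {
    expect_length(unique(m$features), cfg$m_feat)
    expect_length(unique(m$subjects), cfg$n_sub)
    expect_true(all(m$features >= 1 & m$features <= ncol(sp$train$x)))
    expect_true(all(m$subjects >= 1 & m$subjects <= nrow(sp$train$x)))
  }
  cl2 <- build_cluster(sp$train, cfg)
  for (i in 1:10) {
    expect_identical(cl$members[[i]]$features, cl2$members[[i]]$features)
    expect_identical(cl$members[[i]]$subjects, cl2$members[[i]]$subjects)
  }
  expect_error(build_cluster(sp$train, fast_cfg(1, n_sub = 1000)), "n_sub")
  expect_error(build_cluster(sp$train, fast_cfg(1, m_feat = 1000)), "m_feat")
})

test_that("majority voting follows the declared count and tie rules", {
  expect_equal(as.character(majority_vote(c("A", "A", "B"),
                                          levels = c("A", "B"))), "A")
  expect_equal(as.character(majority_vote(rep("B", 5), levels = c("A", "B"))),
               "B")
  tied <- majority_vote(c("A", "B", "B", "A"), levels = c("A", "B"))
  expect_equal(as.character(tied), "A")    # toward the first listed class
  expect_true(attr(tied, "tie"))
  not_tied <- majority_vote(c("A", "A", "B"), levels = c("A", "B"))
  expect_false(attr(not_tied, "tie"))
  # invariant to member ordering
  set.seed(8)
  for (i in 1:10) {
    v <- sample(c("A", "B"), 11, replace = TRUE)
    expect_equal(as.character(majority_vote(v, c("A", "B"))),
                 as.character(majority_vote(sample(v), c("A", "B"))))
  }
  expect_error(majority_vote(character(0)), "at least one")
})

test_that("ensemble accuracy aggregates member votes on planted data", {
  ft <- mk_table(7, n_per = 30)
  sp <- split_train_test(ft, 0.8, seed = 7)
  cl <- build_cluster(sp$train, fast_cfg(7, k = 30))
  ens <- ensemble_accuracy(cl, sp$test)
  mem <- member_accuracies(cl, sp$test)
  expect_gte(ens, 0.5)
  expect_gte(ens, mean(mem) - 0.1)  # voting should not fall below members
  expect_length(mem, 30)
  expect_true(all(mem >= 0 & mem <= 1))
})

test_that("significant-member selection uses a strict accuracy cut", {
  ft <- mk_table(9)
  sp <- split_train_test(ft, 0.8, seed = 9)
  cl <- build_cluster(sp$train, fast_cfg(9, k = 5))
  acc <- member_accuracies(cl, sp$test)
  # threshold 0: every member is significant (accuracies are positive here)
  expect_equal(select_significant(cl, sp$test, threshold = 0)$indices,
               which(acc > 0))
  # threshold equal to a member's accuracy excludes that member (strict >)
  thr <- acc[1]
  sel <- select_significant(cl, sp$test, threshold = thr)
  expect_false(1 %in% sel$indices)
  expect_equal(sel$indices, which(acc > thr))
  # threshold 1 leaves nothing
  expect_length(select_significant(cl, sp$test, threshold = 1)$indices, 0)
})

test_that("feature frequencies obey the conservation identity", {
  ft <- mk_table(10)
  sp <- split_train_test(ft, 0.8, seed = 10)
  cfg <- fast_cfg(10, k = 12)
  cl <- build_cluster(sp$train, cfg)
  counts_all <- feature_frequencies(cl, seq_len(cfg$k))
  expect_equal(sum(counts_all), cfg$k * cfg$m_feat)
  counts_none <- feature_frequencies(cl, integer(0))
  expect_true(all(counts_none == 0))
  sub <- c(2, 5, 9)
  expect_equal(sum(feature_frequencies(cl, sub)), length(sub) * cfg$m_feat)
  # shared feature counted once per member that sampled it
  f7 <- vapply(cl$members, function(m) 7 %in% m$features, TRUE)
  expect_equal(counts_all[7], sum(f7))
})

test_that("top_features ranks by count with ascending-index tie-break", {
  expect_equal(top_features(c(3, 1, 2), 2), c(1L, 3L))
  expect_equal(top_features(rep(4, 5), 2), c(1L, 2L))
  expect_equal(top_features(c(0, 5, 5, 1), 3), c(2L, 3L, 4L))
  expect_error(top_features(c(1, 2), 5), "exceeds")
})

test_that("optimal_feature_count profiles candidates and applies the stability rule", {
  ft <- mk_table(12, n_per = 25, p = 40)
  sp <- split_train_test(ft, 0.8, seed = 12)
  cfg <- fast_cfg(12, k = 15, m_feat = 10)
  expect_error(optimal_feature_count(sp$train, sp$test, cfg, integer(0)),
               "non-empty")
  expect_error(optimal_feature_count(sp$train, sp$test, cfg, 5, reps = 0),
               "reps")
  expect_error(optimal_feature_count(sp$train, sp$test, cfg, 10000),
               "exceed")
  # single candidate: returned with its profile
  one <- optimal_feature_count(sp$train, sp$test, cfg, 8, reps = 2)
  expect_equal(one$best, 8L)
  expect_equal(nrow(one$profile), 1)
  # candidates {below, at} the planted count: the chosen one is no worse
  res <- optimal_feature_count(sp$train, sp$test, cfg, c(3, 5), reps = 3)
  expect_true(res$best %in% c(3L, 5L))
  best_row <- res$profile[res$profile$candidate == res$best, ]
  expect_gte(best_row$mean_accuracy, max(res$profile$mean_accuracy) - 1e-12)
})

test_that("failed members are excluded from voting with a warning", {
  # competitive training errors when prototypes exceed the member sample
  ft <- mk_table(14, n_per = 10, p = 20)
  sp <- split_train_test(ft, 0.8, seed = 14)
  cfg <- cluster_config(k = 3, n_sub = 5, m_feat = 10,
                        base_kind = "competitive", seed = 14,
                        nn = train_config(hidden_units = 8, epochs = 20,
                                          seed = 14))
  expect_warning(cl <- build_cluster(sp$train, cfg), "failed")
  expect_equal(cl$n_failed, 3L)
  expect_error(predict(cl, sp$test), "no trained members")
})
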