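sep_data <- function(seed, n_per = 30, p = 6, effect = 3) {
  ft <- generate_feature_table(n_per, p, planted_features = 1:3,
                               effect_size = effect, seed = seed)
  split_train_test(ft, 0.8, seed = seed)
}

test_that("every base classifier is deterministic and beats chance when separable", {
  kinds <- c("bp", "pnn", "competitive", "lvq", "elman")
  wins <- setNames(integer(5), kinds)
  for (s in 1:10) {
    sp <- sep_data(400 + s)
    for (kind in kinds) {
      cfg <- train_config(seed = s)
      m1 <- fit_base(kind, sp$train$x, sp$train$labels, cfg)
      acc <- accuracy(m1, sp$test$x, sp$test$labels)
      if (acc > 0.7) wins[kind] <- wins[kind] + 1L
      if (s == 1) {  # determinism: identical seed => identical model
        m2 <- fit_base(kind, sp$train$x, sp$train$labels, cfg)
        expect_identical(predict(m1, sp$test$x), predict(m2, sp$test$x))
        expect_equal(unclass(m1), unclass(m2))
      }
    }
  }
  for (kind in kinds) expect_gte(wins[[kind]], 9)
})

test_that("BP learns linearly separable clusters and can solve XOR", {
  set.seed(2)
  X <- matrix(c(rnorm(20, -5), rnorm(20, 5)), ncol = 1)
  y <- factor(rep(c("a", "b"), each = 20))
  m <- fit_bp(X, y, train_config(hidden_units = 4, epochs = 200, seed = 1))
  expect_equal(accuracy(m, X, y), 1.0)
  # XOR: nonlinear, needs the hidden layer
  Xx <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  yx <- factor(c("a", "b", "b", "a"))
  accs <- vapply(1:5, function(s)
    accuracy(fit_bp(Xx, yx, train_config(hidden_units = 6, epochs = 3000,
                                         learning_rate = 0.5, seed = s,
                                         standardize = FALSE)), Xx, yx), 0)
  expect_gte(max(accs), 1.0)
  expect_error(fit_bp(X, factor(rep("a", 40))), "single class")
})

test_that("BP and Elman training loss is non-increasing at small learning rate", {
  sp <- sep_data(11)
  for (kind in c("bp", "elman")) {
    m <- fit_base(kind, sp$train$x, sp$train$labels,
                  train_config(learning_rate = 1e-3, epochs = 60, seed = 2))
    expect_true(all(diff(m$loss) <= 1e-6))
  }
})

test_that("PNN prediction equals the brute-force kernel-sum oracle", {
  set.seed(13)
  X <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 2), ncol = 2))
  y <- factor(rep(c("a", "b"), each = 20))
  m <- fit_pnn(X, y, train_config(sigma = 1, standardize = FALSE))
  Q <- matrix(rnorm(100, 1), ncol = 2)
  pred <- predict(m, Q)
  oracle <- vapply(seq_len(nrow(Q)), function(i)
    oracle_pnn_predict(X, y, Q[i, ], sigma = 1), "")
  expect_equal(as.character(pred), oracle)
  # stored training point with small sigma returns its own class
  msmall <- fit_pnn(X, y, train_config(sigma = 0.05, standardize = FALSE))
  expect_equal(as.character(predict(msmall, X[3, , drop = FALSE])), "a")
  expect_equal(as.character(predict(msmall, X[25, , drop = FALSE])), "b")
  # exact score tie (symmetric patterns, equidistant query) -> first level
  Xsym <- rbind(c(1, 0), c(-1, 0))
  msym <- fit_pnn(Xsym, factor(c("a", "b")),
                  train_config(sigma = 5, standardize = FALSE))
  expect_equal(as.character(predict(msym, rbind(c(0, 0), c(0, 3)))),
               c("a", "a"))
  expect_error(train_config(sigma = 0), "positive")
})

test_that("competitive prototypes follow the inner-star rule to cluster centres", {
  set.seed(4)
  X <- rbind(matrix(rnorm(60, -5, 0.5), ncol = 2),
             matrix(rnorm(60, 5, 0.5), ncol = 2))
  y <- factor(rep(c("a", "b"), each = 30))
  cfg <- train_config(hidden_units = 2, learning_rate = 0.1, epochs = 100,
                      seed = 3, standardize = FALSE)
  m <- fit_competitive(X, y, cfg)
  centres <- rbind(colMeans(X[1:30, ]), colMeans(X[31:60, ]))
  for (p in 1:2) {
    d <- sqrt(rowSums((centres - matrix(m$prototypes[p, ], 2, 2,
                                        byrow = TRUE))^2))
    expect_lt(min(d), 0.5)
  }
  expect_gt(accuracy(m, X, y), 0.9)
  # eta = 0 leaves prototypes at their initialization
  cfg0 <- train_config(hidden_units = 2, learning_rate = 0, epochs = 50,
                       seed = 3, standardize = FALSE)
  m0 <- fit_competitive(X, y, cfg0)
  init <- with(list(), {
    set.seed(3, kind = "Mersenne-Twister", normal.kind = "Inversion")
    matrix(runif(4, -0.5, 0.5), 2, 2)
  })
  expect_equal(unname(m0$prototypes), unname(init))
  expect_error(fit_competitive(X[c(1, 2, 31), ], y[c(1, 2, 31)],
                               train_config(hidden_units = 5)), "prototypes")
})

test_that("LVQ1 classifies separable clusters; eta = 0 with mean init is nearest-class-mean", {
  set.seed(6)
  X <- rbind(matrix(rnorm(60, -4, 0.7), ncol = 2),
             matrix(rnorm(60, 4, 0.7), ncol = 2))
  y <- factor(rep(c("a", "b"), each = 30))
  m <- fit_lvq(X, y, train_config(hidden_units = 4, learning_rate = 0.05,
                                  epochs = 200, seed = 1))
  Xt <- rbind(matrix(rnorm(30, -4, 0.7), ncol = 2),
              matrix(rnorm(30, 4, 0.7), ncol = 2))
  yt <- factor(rep(c("a", "b"), each = 15))
  expect_equal(accuracy(m, Xt, yt), 1.0)
  # eta = 0, prototypes at the class means: nearest-mean classifier
  m0 <- fit_lvq(X, y, train_config(hidden_units = 2, learning_rate = 0,
                                   epochs = 10, seed = 1, init = "mean",
                                   standardize = FALSE))
  mu <- rbind(colMeans(X[1:30, ]), colMeans(X[31:60, ]))
  pred0 <- predict(m0, Xt)
  nearest <- c("a", "b")[max.col(-as.matrix(dist(rbind(mu, Xt)))[-(1:2), 1:2])]
  expect_equal(as.character(pred0), nearest)
  expect_error(fit_lvq(X, factor(rep("a", 60))), "single class")
})

test_that("Elman with zero context decay reduces to a feed-forward network", {
  sp <- sep_data(19)
  m <- fit_elman(sp$train$x, sp$train$labels,
                 train_config(context_decay = 0, seed = 4, epochs = 100))
  # manual feed-forward pass with the trained weights must reproduce predict()
  Xs <- sweep(sweep(sp$test$x, 2, m$std$center), 2, m$std$scale, "/")
  H <- 1 / (1 + exp(-(Xs %*% t(m$Wxh) +
                        matrix(m$bh, nrow(Xs), length(m$bh), byrow = TRUE))))
  out <- H %*% t(m$Why) + matrix(m$by, nrow(Xs), length(m$by), byrow = TRUE)
  manual <- m$levels[max.col(out, ties.method = "first")]
  expect_equal(as.character(predict(m, sp$test$x)), manual)
  # separable data: perfect training accuracy
  m2 <- fit_elman(sp$train$x, sp$train$labels, train_config(seed = 4))
  expect_equal(accuracy(m2, sp$train$x, sp$train$labels), 1.0)
})

test_that("accuracy is the fraction of correct predictions and checks dimensions", {
  sp <- sep_data(23)
  m <- fit_pnn(sp$train$x, sp$train$labels, train_config(sigma = 1))
  pred <- predict(m, sp$test$x)
  expect_equal(accuracy(m, sp$test$x, sp$test$labels),
               mean(as.character(pred) == as.character(sp$test$labels)))
  expect_equal(accuracy(m, sp$test$x, pred), 1.0)
  flipped <- factor(ifelse(pred == "case", "control", "case"),
                    levels = levels(pred))
  expect_equal(accuracy(m, sp$test$x, flipped), 0.0)
  expect_error(predict(m, sp$test$x[, 1:3]), "features")
})

test_that("models serialize to JSON and reload exactly", {
  sp <- sep_data(29)
  for (kind in c("bp", "elman", "lvq")) {
    m <- fit_base(kind, sp$train$x, sp$train$labels, train_config(seed = 5))
    m2 <- deserialize_nn(serialize_nn(m))
    expect_identical(predict(m, sp$test$x), predict(m2, sp$test$x))
  }
  path <- withr::local_tempfile(fileext = ".json")
  m <- fit_bp(sp$train$x, sp$train$labels, train_config(seed = 5))
  serialize_nn(m, path)
  expect_identical(predict(deserialize_nn(path), sp$test$x),
                   predict(m, sp$test$x))
})
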