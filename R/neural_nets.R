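#' Training configuration for the neural-network base classifiers
#'
#' One configuration object serves all five network types; fields that a
#' given type does not use are ignored by it.
#'
#' @param hidden_units Hidden-layer size (BP/Elman) or number of prototypes
#'   (competitive/LVQ).
#' @param learning_rate Gradient / prototype step size eta.
#' @param epochs Passes over the training set.
#' @param seed Integer seed for weight initialisation (mandatory).
#' @param sigma Gaussian kernel smoothing factor (PNN only).
#' @param context_decay Context feedback weight alpha in `[0, 1]` (Elman only).
#' @param chunks Number of presentation steps for the Elman network (see
#'   [fit_elman()]; in `"chunk"` mode also the number of chunks the feature
#'   vector is split into).
#' @param presentation How the Elman network sees a static feature vector:
#'   `"repeat"` (default) presents the whole vector at every step so the
#'   context layer settles over `chunks` steps; `"chunk"` splits it into
#'   `chunks` contiguous zero-padded chunks fed stepwise.
#' @param standardize Standardise features (training-set mean/SD) before
#'   training; recommended for the sigmoid networks.
#' @param init Prototype initialisation for competitive/LVQ: `"uniform"`
#'   (uniform(-0.5, 0.5), the default for all weights) or `"mean"` (class or
#'   data means, no jitter).
#' @return A list of class `train_config`.
#' @export
train_config <- function(hidden_units = 10, learning_rate = 0.01,
                         epochs = 500, seed = 1L, sigma = 0.1,
                         context_decay = 1.0, chunks = 3,
                         presentation = c("repeat", "chunk"),
                         standardize = TRUE, init = c("uniform", "mean")) {
  if (!is_count(hidden_units)) stop_ctx("hidden_units must be a positive integer")
  if (learning_rate < 0) stop_ctx("learning_rate must be >= 0")
  if (!is_count(epochs)) stop_ctx("epochs must be a positive integer")
  if (sigma <= 0) stop_ctx("sigma must be positive")
  if (context_decay < 0 || context_decay > 1)
    stop_ctx("context_decay must be in [0, 1]")
  structure(list(hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed), sigma = sigma,
                 context_decay = context_decay, chunks = as.integer(chunks),
                 presentation = match.arg(presentation),
                 standardize = isTRUE(standardize), init = match.arg(init)),
            class = "train_config")
}

check_xy <- function(X, y, min_per_class = 1) {
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) stop_ctx("features must be finite")
  y <- as.factor(y)
  if (length(y) != nrow(X)) stop_ctx("length(y) != nrow(X)")
  y <- droplevels(y)
  if (nlevels(y) < 2) stop_ctx("training labels contain a single class")
  tab <- table(y)
  if (any(tab < min_per_class))
    stop_ctx("every class needs >= %d training sample(s)", min_per_class)
  list(X = X, y = y)
}

std_fit <- function(X, on) {
  if (!on) return(list(center = rep(0, ncol(X)), scale = rep(1, ncol(X))))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

std_apply <- function(X, std) sweep(sweep(X, 2, std$center), 2, std$scale, "/")

one_hot <- function(y) {
  Y <- matrix(0, length(y), nlevels(y))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

new_nn <- function(kind, fields, cfg, levels, std) {
  structure(c(fields,
              list(kind = kind, config = cfg, levels = levels, std = std)),
            class = c(paste0("nn_", kind), "nn_model"))
}

runif_mat <- function(r, c) matrix(runif(r * c, -0.5, 0.5), r, c)

#' Fit a backpropagation network
#'
#' One sigmoid hidden layer, linear outputs (one per class, 1-of-K targets),
#' trained by online gradient descent on the squared-error loss
#' `E = sum_j (c_j - t_j)^2 / 2`; weights start uniform(-0.5, 0.5) from the
#' seeded RNG.
#'
#' @param X Samples-by-features numeric matrix.
#' @param y Class labels (>= 2 classes present).
#' @param cfg A [train_config()].
#' @return A model of class `nn_bp` with a per-epoch training-loss trace.
#' @export
fit_bp <- function(X, y, cfg = train_config()) {
  d <- check_xy(X, y)
  std <- std_fit(d$X, cfg$standardize)
  Xs <- std_apply(d$X, std)
  K <- nlevels(d$y); m <- ncol(Xs); h <- cfg$hidden_units
  fit <- with_seed(cfg$seed, {
    W1 <- runif_mat(m, h); b1 <- runif(h, -0.5, 0.5)
    W2 <- runif_mat(h, K); b2 <- runif(K, -0.5, 0.5)
    train_bp_cpp(Xs, one_hot(d$y), W1, b1, W2, b2,
                 cfg$learning_rate, cfg$epochs)
  })
  new_nn("bp", fit, cfg, levels(d$y), std)
}

#' @export
predict.nn_bp <- function(object, newdata, ...) {
  X <- std_apply(check_dim(object, newdata, length(object$std$center)),
                 object$std)
  A1 <- 1 / (1 + exp(-(X %*% object$W1 + matrix(object$b1, nrow(X),
                                                length(object$b1), byrow = TRUE))))
  S <- A1 %*% object$W2 + matrix(object$b2, nrow(X), length(object$b2),
                                 byrow = TRUE)
  factor(object$levels[max.col(S, ties.method = "first")],
         levels = object$levels)
}

check_dim <- function(model, newdata, m) {
  X <- as.matrix(newdata)
  if (ncol(X) != m)
    stop_ctx("model expects %d features, got %d", m, ncol(X))
  X
}

#' Fit a probabilistic neural network
#'
#' Stores the (standardised) training patterns; prediction assigns the class
#' with the highest mean Gaussian kernel score
#' `nu_i = (1/L_i) sum_j exp(-||s - s_ij||^2 / sigma^2)`, evaluated in log
#' space for numerical stability (the shared normalising constant cancels in
#' the argmax). Ties go to the lowest class index.
#'
#' @inheritParams fit_bp
#' @return A model of class `nn_pnn`.
#' @export
fit_pnn <- function(X, y, cfg = train_config()) {
  if (cfg$sigma <= 0) stop_ctx("sigma must be positive")
  d <- check_xy(X, y)
  std <- std_fit(d$X, cfg$standardize)
  new_nn("pnn", list(patterns = std_apply(d$X, std), y = d$y), cfg,
         levels(d$y), std)
}

#' @export
predict.nn_pnn <- function(object, newdata, ...) {
  X <- std_apply(check_dim(object, newdata, ncol(object$patterns)), object$std)
  P <- object$patterns
  s2 <- object$config$sigma^2
  # squared distances query x pattern
  D2 <- outer(rowSums(X^2), rowSums(P^2), "+") - 2 * tcrossprod(X, P)
  D2[D2 < 0] <- 0
  logk <- -D2 / s2
  scores <- vapply(object$levels, function(cl) {
    cols <- which(object$y == cl)
    lk <- logk[, cols, drop = FALSE]
    mx <- apply(lk, 1, max)
    mx + log(rowMeans(exp(lk - mx)))          # log mean kernel per class
  }, numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X))
  factor(object$levels[max.col(scores, ties.method = "first")],
         levels = object$levels)
}

#' Fit a competitive (winner-take-all) network
#'
#' Unsupervised prototype learning with the inner-star rule
#' `dw = eta (p - w)` applied to the winning (closest) prototype only. After
#' training each prototype is labelled with the majority class of the
#' training samples it wins; prototypes that win no samples inherit the
#' overall majority class.
#'
#' @inheritParams fit_bp
#' @return A model of class `nn_competitive`.
#' @export
fit_competitive <- function(X, y, cfg = train_config()) {
  d <- check_xy(X, y)
  if (cfg$hidden_units > nrow(d$X))
    stop_ctx("more prototypes (%d) than samples (%d)",
             cfg$hidden_units, nrow(d$X))
  std <- std_fit(d$X, cfg$standardize)
  Xs <- std_apply(d$X, std)
  P0 <- with_seed(cfg$seed, {
    if (cfg$init == "mean")
      matrix(colMeans(Xs), cfg$hidden_units, ncol(Xs), byrow = TRUE) +
        runif_mat(cfg$hidden_units, ncol(Xs)) * 1e-3
    else runif_mat(cfg$hidden_units, ncol(Xs))
  })
  P <- train_competitive_cpp(Xs, P0, cfg$learning_rate, cfg$epochs)
  win <- nearest_prototype(Xs, P)
  overall <- names(which.max(table(d$y)))
  pclass <- vapply(seq_len(nrow(P)), function(p) {
    won <- d$y[win == p]
    if (length(won) == 0) overall else names(which.max(table(won)))
  }, "")
  new_nn("competitive", list(prototypes = P, proto_class = pclass), cfg,
         levels(d$y), std)
}

nearest_prototype <- function(X, P) {
  D2 <- outer(rowSums(X^2), rowSums(P^2), "+") - 2 * tcrossprod(X, P)
  max.col(-D2, ties.method = "first")
}

#' @export
predict.nn_competitive <- function(object, newdata, ...) {
  X <- std_apply(check_dim(object, newdata, ncol(object$prototypes)),
                 object$std)
  factor(object$proto_class[nearest_prototype(X, object$prototypes)],
         levels = object$levels)
}

#' Fit a learning vector quantization (LVQ1) network
#'
#' Prototypes carry fixed class labels (hidden_units prototypes split evenly
#' over the classes, at least one each); the winning prototype moves toward
#' the sample when the labels match and away otherwise, step `eta`.
#'
#' @inheritParams fit_bp
#' @return A model of class `nn_lvq`.
#' @export
fit_lvq <- function(X, y, cfg = train_config()) {
  d <- check_xy(X, y)
  std <- std_fit(d$X, cfg$standardize)
  Xs <- std_apply(d$X, std)
  K <- nlevels(d$y)
  per <- max(1L, cfg$hidden_units %/% K)
  pclass <- rep(seq_len(K), each = per)
  P0 <- with_seed(cfg$seed, {
    if (cfg$init == "mean") {
      t(vapply(pclass, function(k)
        colMeans(Xs[as.integer(d$y) == k, , drop = FALSE]),
        numeric(ncol(Xs))))
    } else runif_mat(length(pclass), ncol(Xs))
  })
  P <- train_lvq_cpp(Xs, as.integer(d$y) - 1L, P0, as.integer(pclass) - 1L,
                     cfg$learning_rate, cfg$epochs)
  new_nn("lvq", list(prototypes = P, proto_class = levels(d$y)[pclass]),
         cfg, levels(d$y), std)
}

#' @export
predict.nn_lvq <- function(object, newdata, ...) {
  X <- std_apply(check_dim(object, newdata, ncol(object$prototypes)),
                 object$std)
  factor(object$proto_class[nearest_prototype(X, object$prototypes)],
         levels = object$levels)
}

#' Fit an Elman recurrent network
#'
#' The context layer feeds `alpha`-scaled copies of the previous hidden
#' state back into the hidden layer,
#' `h(f) = sigmoid(Wxh e(f) + Whh alpha q(f-1))`, with a linear read-out of
#' the final-step hidden state. A static feature vector becomes a short
#' sequence in one of two ways: `presentation = "repeat"` (default) presents
#' the full vector at every one of `chunks` steps, so the recurrent state
#' settles over repeated exposures; `"chunk"` splits the vector into
#' `chunks` contiguous zero-padded chunks fed stepwise (one shared input
#' weight matrix across steps). With `context_decay = 0` the network reduces
#' exactly to a feed-forward sigmoid network. Trained by online gradient
#' descent with full backpropagation through time on the squared error of
#' the final-step output.
#'
#' @inheritParams fit_bp
#' @return A model of class `nn_elman` with a per-epoch training-loss trace.
#' @export
fit_elman <- function(X, y, cfg = train_config()) {
  d <- check_xy(X, y)
  std <- std_fit(d$X, cfg$standardize)
  Xs <- std_apply(d$X, std)
  K <- nlevels(d$y); m <- ncol(Xs); h <- cfg$hidden_units
  if (cfg$presentation == "repeat") {
    S <- max(1L, cfg$chunks)
    L <- m
    Xin <- do.call(cbind, rep(list(Xs), S))
  } else {
    S <- max(1L, min(cfg$chunks, m))
    L <- as.integer(ceiling(m / S))
    Xin <- if (L * S > m) cbind(Xs, matrix(0, nrow(Xs), L * S - m)) else Xs
  }
  fit <- with_seed(cfg$seed, {
    Wxh <- runif_mat(h, L); Whh <- runif_mat(h, h); Why <- runif_mat(K, h)
    bh <- runif(h, -0.5, 0.5); by <- runif(K, -0.5, 0.5)
    train_elman_cpp(Xin, one_hot(d$y), L, S, cfg$context_decay,
                    Wxh, Whh, Why, bh, by, cfg$learning_rate, cfg$epochs)
  })
  new_nn("elman", c(fit, list(chunk_len = L, n_steps = S, n_features = m)),
         cfg, levels(d$y), std)
}

elman_forward <- function(object, X) {
  S <- object$n_steps; L <- object$chunk_len
  a <- object$config$context_decay
  Q <- matrix(0, nrow(X), nrow(object$Wxh))
  for (f in seq_len(S)) {
    E <- if (object$config$presentation == "repeat") X else {
      if (ncol(X) < L * S) X <- cbind(X, matrix(0, nrow(X), L * S - ncol(X)))
      X[, ((f - 1) * L + 1):(f * L), drop = FALSE]
    }
    Z <- E %*% t(object$Wxh) + (a * Q) %*% t(object$Whh) +
      matrix(object$bh, nrow(X), length(object$bh), byrow = TRUE)
    Q <- 1 / (1 + exp(-Z))
  }
  Q %*% t(object$Why) + matrix(object$by, nrow(X), length(object$by),
                               byrow = TRUE)
}

#' @export
predict.nn_elman <- function(object, newdata, ...) {
  X <- std_apply(check_dim(object, newdata, object$n_features), object$std)
  S <- elman_forward(object, X)
  factor(object$levels[max.col(S, ties.method = "first")],
         levels = object$levels)
}

#' Classification accuracy of a fitted base classifier
#'
#' @param model Any fitted `nn_*` model.
#' @param X Feature matrix.
#' @param y True labels.
#' @return Fraction of correct predictions in `[0, 1]`.
#' @export
accuracy <- function(model, X, y) {
  p <- predict(model, X)
  mean(as.character(p) == as.character(y))
}

#' Serialize / restore a fitted model as JSON
#'
#' Writes the full architecture, weights, configuration and seed so a model
#' can be audited and reloaded exactly.
#'
#' @param model A fitted `nn_*` model.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `serialize_nn`: JSON string (or `path`, invisibly);
#'   `deserialize_nn`: the restored model.
#' @export
serialize_nn <- function(model, path = NULL) {
  js <- jsonlite::serializeJSON(model, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname serialize_nn
#' @param json JSON string or file path produced by [serialize_nn()].
#' @export
deserialize_nn <- function(json) {
  if (length(json) == 1 && file.exists(json))
    json <- paste(readLines(json), collapse = "\n")
  jsonlite::unserializeJSON(json)
}

#' Fit any of the five base classifiers by name
#'
#' @param kind One of `"bp"`, `"pnn"`, `"competitive"`, `"lvq"`, `"elman"`.
#' @inheritParams fit_bp
#' @return The fitted model.
#' @export
fit_base <- function(kind, X, y, cfg = train_config()) {
  switch(match.arg(kind, c("bp", "pnn", "competitive", "lvq", "elman")),
         bp = fit_bp(X, y, cfg), pnn = fit_pnn(X, y, cfg),
         competitive = fit_competitive(X, y, cfg),
         lvq = fit_lvq(X, y, cfg), elman = fit_elman(X, y, cfg))
}
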