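CLASSIFIER_KINDS <- c("lda", "svm", "adaboost_tree", "ann", "rnn", "cnn")

#' Classifier configuration
#'
#' Builds one of the six benchmarked configurations with its default
#' hyperparameters. Defaults per kind:
#' \describe{
#'   \item{lda}{linear discriminant, empirical priors.}
#'   \item{svm}{linear-kernel SVM, 1000 MB cache, iteration budget 1000.}
#'   \item{adaboost_tree}{AdaBoost (SAMME) over decision trees, 100
#'     learners, learning rate 0.01.}
#'   \item{ann}{1 hidden layer of 10 logistic-sigmoid nodes, softmax
#'     output, MAE objective with L2 penalty, 100 epochs, learning rate
#'     0.01.}
#'   \item{rnn}{recurrent net with layer delays 1:2, 10 tanh nodes, linear
#'     output, MAE objective, 100 epochs, learning rate 0.01; the feature
#'     row is presented as a length-8 sequence of per-component channel
#'     slices.}
#'   \item{cnn}{2 conv/batchnorm/leaky-ReLU/dropout blocks, 96 filters,
#'     requested kernel 11x11 clamped per dimension to the largest odd
#'     extent fitting the channels-x-components map, dropout 0.25,
#'     2 fully connected layers, softmax output, Adam with piecewise
#'     schedule (drop period 125, factor 0.2), batch 64, 100 epochs.}
#' }
#'
#' @param kind one of `lda`, `svm`, `adaboost_tree`, `ann`, `rnn`, `cnn`.
#' @param seed integer seed for any stochastic element (initialisation,
#'   minibatch order, dropout).
#' @param ... overrides for the kind's hyperparameters.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(kind = CLASSIFIER_KINDS, seed = 1, ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    lda = list(prior = "empirical"),
    svm = list(kernel = "linear", cachesize = 1000, max_iter = 1000),
    adaboost_tree = list(n_learners = 100, learning_rate = 0.01,
                         max_depth = 3),
    ann = list(hidden = 10, epochs = 100, learning_rate = 0.01, l2 = 1e-4),
    rnn = list(delays = 1:2, hidden = 10, epochs = 100,
               learning_rate = 0.01, l2 = 1e-4),
    cnn = list(conv_blocks = 2, filters = 96, kernel = c(11, 11),
               dropout = 0.25, fc_width = 32, epochs = 100, batch = 64,
               learning_rate = 1e-3, lr_drop_period = 125,
               lr_drop_factor = 0.2))
  hp <- utils::modifyList(defaults, list(...))
  structure(list(kind = kind, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

# Linear discriminant with empirical priors and Ledoit-Wolf shrinkage of
# the pooled within-class covariance toward a scaled identity. The
# shrinkage intensity is estimated from the data (no tuning parameter), and
# vanishes as n grows, so in the well-conditioned regime this coincides
# with classical LDA; in the p ~ n regime typical of 160-column feature
# matrices on a few hundred trials it keeps the discriminant stable.
lda_train <- function(X, y) {
  levels <- sort(unique(y))
  n <- nrow(X); p <- ncol(X)
  mus <- lapply(levels, function(cl) colMeans(X[y == cl, , drop = FALSE]))
  Z <- X
  for (i in seq_along(levels))
    Z[y == levels[i], ] <- sweep(X[y == levels[i], , drop = FALSE], 2,
                                 mus[[i]])
  S <- crossprod(Z) / n
  m <- sum(diag(S)) / p
  d2 <- sum((S - diag(m, p))^2) / p
  b2bar <- sum(vapply(seq_len(n), function(i) {
    zi <- Z[i, ]
    sum((tcrossprod(zi) - S)^2)
  }, numeric(1))) / (n^2 * p)
  b2 <- min(b2bar, d2)
  rho <- if (d2 > 0) b2 / d2 else 1
  Sigma <- rho * diag(m, p) + (1 - rho) * S
  R <- chol(Sigma)
  priors <- vapply(levels, function(cl) mean(y == cl), numeric(1))
  list(levels = levels, mus = mus, R = R, priors = priors)
}

lda_predict <- function(model, X) {
  scores <- vapply(seq_along(model$levels), function(i) {
    w <- backsolve(model$R,
                   backsolve(model$R, model$mus[[i]], transpose = TRUE))
    as.numeric(X %*% w) - 0.5 * sum(model$mus[[i]] * w) +
      log(model$priors[i])
  }, numeric(nrow(X)))
  if (nrow(X) == 1) scores <- matrix(scores, 1)
  model$levels[max.col(scores, ties.method = "first")]
}

# AdaBoost (SAMME) over rpart trees; multi-class capable
adaboost_train <- function(X, y, n_learners, learning_rate, max_depth,
                           seed) {
  levels <- sort(unique(y))
  K <- length(levels)
  n <- nrow(X)
  df <- data.frame(y = factor(y, levels = levels), X)
  w <- rep(1 / n, n)
  learners <- list(); alphas <- numeric(0)
  with_seed(seed, function() {
    for (m in seq_len(n_learners)) {
      fit <- rpart::rpart(y ~ ., data = df, weights = w,
                          method = "class",
                          control = rpart::rpart.control(
                            maxdepth = max_depth, cp = 0, xval = 0,
                            minsplit = 4))
      pred <- as.character(predict(fit, df, type = "class"))
      miss <- pred != y
      err <- sum(w[miss])
      if (err >= 1 - 1 / K) break       # worse than chance: stop boosting
      err <- max(err, 1e-10)
      a <- learning_rate * (log((1 - err) / err) + log(K - 1))
      learners[[length(learners) + 1]] <<- fit
      alphas[length(alphas) + 1] <<- a
      if (sum(miss) == 0) break
      w <<- w * exp(a * miss)
      w <<- w / sum(w)
    }
  })
  list(learners = learners, alphas = alphas, levels = levels)
}

adaboost_predict <- function(model, X) {
  df <- data.frame(X)
  votes <- matrix(0, nrow(df), length(model$levels),
                  dimnames = list(NULL, model$levels))
  for (m in seq_along(model$learners)) {
    pred <- as.character(predict(model$learners[[m]], df, type = "class"))
    votes[cbind(seq_len(nrow(df)), match(pred, model$levels))] <-
      votes[cbind(seq_len(nrow(df)), match(pred, model$levels))] +
      model$alphas[m]
  }
  model$levels[max.col(votes, ties.method = "first")]
}

# reshape a trials x (channels * components) matrix into the n x T x D
# sequence consumed by the rnn (T = components as time, D = channels)
rows_to_sequence <- function(X, n_components = 8) {
  n <- nrow(X)
  n_ch <- ncol(X) %/% n_components
  stopifnot(n_ch * n_components == ncol(X))
  arr <- array(0, c(n, n_components, n_ch))
  for (t in seq_len(n_components))
    arr[, t, ] <- X[, (seq_len(n_ch) - 1) * n_components + t, drop = FALSE]
  arr
}

# reshape rows into channels x components maps for the cnn
rows_to_map <- function(X, n_components = 8) {
  n <- nrow(X)
  n_ch <- ncol(X) %/% n_components
  stopifnot(n_ch * n_components == ncol(X))
  arr <- array(0, c(n, n_ch, n_components))
  for (ch in seq_len(n_ch))
    arr[, ch, ] <- X[, (ch - 1) * n_components + seq_len(n_components),
                     drop = FALSE]
  arr
}

#' Train on one fold and predict the held-out rows
#'
#' Rows are assumed already standardized (z-scored on training statistics);
#' [run_issue()] does this per fold. Deterministic given `config$seed`.
#'
#' @param config a [classifier_config()].
#' @param train_x,train_y training rows (matrix) and labels.
#' @param test_x held-out rows.
#' @param n_components components per channel (default 8), used by the
#'   rnn/cnn reshaping.
#' @return character vector of predicted labels, one per test row.
#' @export
fit_predict <- function(config, train_x, train_y, test_x,
                        n_components = 8) {
  stopifnot(inherits(config, "classifier_config"))
  if (length(unique(train_y)) < 2)
    stop(structure(class = c("emdad_fold_skip", "error", "condition"),
                   list(message = "degenerate training fold: single class",
                        call = sys.call(-1))))
  hp <- config$hyperparameters
  switch(config$kind,
    lda = {
      model <- lda_train(train_x, train_y)
      lda_predict(model, test_x)
    },
    svm = {
      fit <- with_seed(config$seed, function()
        e1071::svm(train_x, factor(train_y), kernel = "linear",
                   cachesize = hp$cachesize, scale = FALSE))
      as.character(predict(fit, test_x))
    },
    adaboost_tree = {
      model <- adaboost_train(train_x, train_y, hp$n_learners,
                              hp$learning_rate, hp$max_depth, config$seed)
      adaboost_predict(model, test_x)
    },
    ann = {
      model <- mlp_train(train_x, train_y, hidden = hp$hidden,
                         epochs = hp$epochs, lr = hp$learning_rate,
                         l2 = hp$l2, seed = config$seed)
      mlp_predict(model, test_x)
    },
    rnn = {
      model <- rnn_train(rows_to_sequence(train_x, n_components), train_y,
                         hidden = hp$hidden, epochs = hp$epochs,
                         lr = hp$learning_rate, l2 = hp$l2,
                         seed = config$seed)
      rnn_predict(model, rows_to_sequence(test_x, n_components))
    },
    cnn = {
      model <- cnn_train(rows_to_map(train_x, n_components), train_y,
                         filters = hp$filters, kernel = hp$kernel,
                         dropout = hp$dropout, fc_width = hp$fc_width,
                         epochs = hp$epochs, batch = hp$batch,
                         lr = hp$learning_rate,
                         lr_drop_period = hp$lr_drop_period,
                         lr_drop_factor = hp$lr_drop_factor,
                         seed = config$seed)
      cnn_predict(model, rows_to_map(test_x, n_components))
    })
}
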