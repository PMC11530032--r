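# Tree-ensemble learners built on the compiled CART kernel: least-squares
# gradient boosting (pseudotime regression) and a bagged randomized-tree
# classifier (bin similarity).

fit_tree <- function(X, y, rows, feats, max_depth, min_node) {
  cpp_tree_fit(X, y, as.integer(rows - 1L), as.integer(feats - 1L),
               as.integer(max_depth), as.integer(min_node))
}

predict_tree <- function(tree, X) cpp_tree_predict(tree, X)

#' Gradient-boosted regression trees
#'
#' Least-squares gradient boosting: shallow CART trees fit to residuals with
#' shrinkage \code{learning_rate} and per-tree row subsampling.
#'
#' @param X numeric feature matrix (rows = observations).
#' @param y numeric response.
#' @param n_trees number of boosting rounds.
#' @param learning_rate shrinkage per round.
#' @param max_depth tree depth.
#' @param subsample row fraction per round.
#' @param min_node minimum observations per leaf.
#' @param seed seed for subsampling.
#' @return a \code{gbt} model (list of trees + init).
#' @export
fit_gbt <- function(X, y, n_trees = 200, learning_rate = 0.1,
                    max_depth = 4, subsample = 0.8, min_node = 10,
                    seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  init <- mean(y)
  pred <- rep(init, n)
  trees <- vector("list", n_trees)
  feats <- seq_len(ncol(X))
  with_seed(seed, {
    for (m in seq_len(n_trees)) {
      rows <- if (subsample < 1) sample.int(n, max(2, round(subsample * n)))
              else seq_len(n)
      tr <- fit_tree(X, y - pred, rows, feats, max_depth, min_node)
      trees[[m]] <- tr
      pred <- pred + learning_rate * predict_tree(tr, X)
    }
  })
  structure(list(trees = trees, init = init,
                 learning_rate = learning_rate, n_features = ncol(X)),
            class = "gbt")
}

#' Predict from a gradient-boosted tree model
#' @param object a \code{gbt} model.
#' @param newdata numeric matrix with the training feature layout.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.gbt <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_features)
    stop("predict.gbt: feature count mismatch")
  pred <- rep(object$init, nrow(X))
  for (tr in object$trees)
    pred <- pred + object$learning_rate * predict_tree(tr, X)
  pred
}

#' Randomized-tree binary classifier
#'
#' Bagged CART trees on bootstrap rows with a random feature subset per
#' tree (random-forest style); class scores are averaged leaf means of the
#' 0/1 response, classified at 0.5.
#'
#' @param X numeric feature matrix.
#' @param y01 0/1 response vector.
#' @param n_trees ensemble size.
#' @param mtry features per tree (default ceiling(sqrt(p))).
#' @param max_depth tree depth.
#' @param min_node minimum observations per leaf.
#' @param seed seed for bootstraps and feature draws.
#' @return an \code{rtrees} model.
#' @export
fit_rtrees <- function(X, y01, n_trees = 50, mtry = NULL, max_depth = 6,
                       min_node = 5, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, ceiling(sqrt(p)))
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(m) {
    rows <- sample.int(n, n, replace = TRUE)
    feats <- sample.int(p, mtry)
    fit_tree(X, y01, rows, feats, max_depth, min_node)
  }))
  structure(list(trees = trees, n_features = p), class = "rtrees")
}

#' Predict class probabilities from a randomized-tree classifier
#' @param object an \code{rtrees} model.
#' @param newdata numeric matrix.
#' @param ... unused.
#' @return numeric vector of P(class 1).
#' @export
predict.rtrees <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  score <- rep(0, nrow(X))
  for (tr in object$trees) score <- score + predict_tree(tr, X)
  score / length(object$trees)
}
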