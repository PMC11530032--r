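# Pseudotemporal gene attributes, common-pseudotime transfer, and
# classifier-based trajectory-bin similarity / merging.

#' Pseudotemporal attributes of one gene in one trajectory
#'
#' The three dotplot attributes: \code{correlation} (Pearson r between
#' per-cell expression and pseudotime), \code{peak} (the equal-width
#' pseudotime bin, 1..n_bins, with the maximal mean expression; lowest index
#' on ties), and \code{expression} (the mean of the occupied bin means).
#'
#' @param expr numeric expression vector over cells (log-normalized).
#' @param pt pseudotime vector in \[0,1\], same length.
#' @param n_bins number of bins (default 10).
#' @return list with \code{correlation}, \code{peak}, \code{expression},
#'   \code{flag} (\code{"zero_variance"} when expression is constant, in
#'   which case correlation is 0).
#' @export
gene_attributes <- function(expr, pt, n_bins = 10) {
  if (length(expr) != length(pt))
    stop("gene_attributes: expr and pt lengths differ")
  if (length(pt) < n_bins)
    stop("gene_attributes: need >= n_bins cells with pseudotime")
  bins <- assign_intervals(pt, n_bins)
  bm <- tapply(expr, factor(bins, levels = seq_len(n_bins)), mean)
  occupied <- !is.na(bm)
  peak <- which(occupied)[which.max(bm[occupied])]
  flag <- "ok"
  if (stats::sd(expr) == 0) {
    correlation <- 0
    flag <- "zero_variance"
  } else {
    correlation <- stats::cor(expr, pt)
  }
  list(correlation = correlation, peak = as.integer(peak),
       expression = mean(bm[occupied]), flag = flag)
}

#' Pseudotemporal attributes for many genes
#'
#' Vectorized \code{\link{gene_attributes}} over the columns of an
#' expression matrix.
#'
#' @param expr matrix (cells x genes) of log-normalized expression.
#' @param pt pseudotime vector.
#' @param n_bins number of bins.
#' @return data.frame \code{gene_id}, \code{correlation}, \code{peak},
#'   \code{expression}, \code{flag}.
#' @export
gene_attributes_matrix <- function(expr, pt, n_bins = 10) {
  ids <- colnames(expr)
  if (is.null(ids)) ids <- sprintf("g%d", seq_len(ncol(expr)))
  rows <- lapply(seq_len(ncol(expr)), function(j)
    gene_attributes(as.numeric(expr[, j]), pt, n_bins))
  data.frame(gene_id = ids,
             correlation = vapply(rows, `[[`, numeric(1), "correlation"),
             peak = vapply(rows, `[[`, integer(1), "peak"),
             expression = vapply(rows, `[[`, numeric(1), "expression"),
             flag = vapply(rows, `[[`, character(1), "flag"),
             stringsAsFactors = FALSE)
}

#' Partition a trajectory into equal-width pseudotime bins
#'
#' Same boundary convention as \code{\link{assign_intervals}}.
#'
#' @param pt pseudotime vector in \[0,1\].
#' @param n_bins number of bins (default 10).
#' @return integer bin ids 1..n_bins.
#' @export
partition_bins <- function(pt, n_bins = 10) assign_intervals(pt, n_bins)

#' Fit a common-pseudotime regressor
#'
#' Gradient-boosted regression trees mapping log-normalized expression of a
#' shared feature set to pseudotime, so pseudotime learned on a reference
#' trajectory can be transferred to query datasets on a common scale.
#'
#' @param reference a \code{cell_table} with pseudotime (>= 200 cells).
#' @param features character vector of feature gene ids, or NULL to select
#'   \code{n_features} HVGs from the reference.
#' @param n_features HVG count when \code{features} is NULL.
#' @param seed seed for boosting subsampling.
#' @param ... passed to \code{\link{fit_gbt}} (n_trees, max_depth, ...).
#' @return a \code{pt_model}: list with \code{model}, \code{features}.
#' @export
fit_common_pseudotime <- function(reference, features = NULL,
                                  n_features = 100, seed = 1L, ...) {
  pt <- reference$obs$pseudotime
  if (is.null(pt) || anyNA(pt))
    stop("fit_common_pseudotime: reference lacks pseudotime")
  if (n_cells(reference) < 200)
    stop("fit_common_pseudotime: need >= 200 reference cells")
  expr <- normalize_log_cpm(reference)
  if (is.null(features)) {
    features <- reference$var$gene_id[select_hvg(expr, n_top = n_features)]
  }
  fidx <- match(features, reference$var$gene_id)
  if (anyNA(fidx))
    stop("fit_common_pseudotime: feature(s) missing from reference")
  X <- as.matrix(expr[, fidx, drop = FALSE])
  model <- fit_gbt(X, pt, seed = seed, ...)
  structure(list(model = model, features = features), class = "pt_model")
}

#' Transfer common pseudotime to a query
#'
#' Predicts per-cell pseudotime from the trained regressor. Query features
#' are matched by gene id; missing features are imputed as zero (count
#' reported). Feature overlap below 50\% warns, below 10\% errors.
#' Predictions are clipped to \[0,1\] and then monotonely min-max rescaled
#' within each query sample.
#'
#' @param model a \code{pt_model} from \code{\link{fit_common_pseudotime}}.
#' @param query a \code{cell_table}.
#' @return numeric per-cell pseudotime in \[0,1\].
#' @export
predict_common_pseudotime <- function(model, query) {
  stopifnot(inherits(model, "pt_model"))
  fidx <- match(model$features, query$var$gene_id)
  overlap <- mean(!is.na(fidx))
  if (overlap < 0.1)
    stop("predict_common_pseudotime: feature overlap ",
         round(100 * overlap), "% < 10%")
  if (overlap < 0.5)
    warning("predict_common_pseudotime: feature overlap ",
            round(100 * overlap), "% < 50%")
  expr <- normalize_log_cpm(query)
  X <- matrix(0, n_cells(query), length(model$features))
  present <- !is.na(fidx)
  if (sum(!present) > 0)
    message("predict_common_pseudotime: ", sum(!present),
            " feature(s) missing from query, imputed as zero")
  X[, present] <- as.matrix(expr[, fidx[present], drop = FALSE])
  pred <- pmin(1, pmax(0, predict(model$model, X)))
  for (s in unique(as.character(query$obs$sample))) {
    i <- query$obs$sample == s
    rng <- range(pred[i])
    if (diff(rng) > 0) pred[i] <- (pred[i] - rng[1]) / diff(rng)
  }
  pred
}

#' Classifier-based similarity between two trajectory bins
#'
#' Downsamples both bins to equal size, then estimates the out-of-fold
#' misclassification rate of a randomized-tree classifier distinguishing
#' them in 5-fold cross-validation on a low-dimensional representation.
#' Indistinguishable bins misclassify at chance (0.5); similarity is the
#' chance-normalized rate \code{m / 0.5}, clipped to \[0,1\].
#'
#' @param representation numeric matrix (cells x dims), e.g. PCA scores.
#' @param cells_a,cells_b row indices of the two bins (each >= 20 cells).
#' @param seed seed for downsampling, folds and trees.
#' @param n_folds CV folds.
#' @param n_trees trees per fold.
#' @return list with \code{misclassification} in \[0, 0.5\],
#'   \code{similarity} in \[0,1\], \code{n_per_bin}.
#' @export
bin_similarity <- function(representation, cells_a, cells_b, seed = 1L,
                           n_folds = 5, n_trees = 50) {
  if (length(cells_a) < 20 || length(cells_b) < 20)
    stop("bin_similarity: both bins need >= 20 cells")
  # canonical bin order makes the construction symmetric in (a, b)
  if (min(cells_b) < min(cells_a)) {
    tmp <- cells_a; cells_a <- cells_b; cells_b <- tmp
  }
  n <- min(length(cells_a), length(cells_b))
  with_seed(seed, {
    a <- sample(cells_a, n)
    b <- sample(cells_b, n)
    X <- as.matrix(representation[c(a, b), , drop = FALSE])
    y <- rep(c(0, 1), each = n)
    fold <- sample(rep_len(seq_len(n_folds), 2 * n))
    wrong <- 0L
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      mod <- fit_rtrees(X[tr, , drop = FALSE], y[tr], n_trees = n_trees,
                        seed = seed + f)
      pred <- as.integer(predict(mod, X[!tr, , drop = FALSE]) > 0.5)
      wrong <- wrong + sum(pred != y[!tr])
    }
    m <- min(0.5, wrong / (2 * n))
    list(misclassification = m, similarity = min(1, m / 0.5),
         n_per_bin = n)
  })
}

#' Merge trajectory bins by similarity
#'
#' Union-find merge of bin pairs with similarity at or above
#' \code{threshold}; merged component ids are the sorted member ids joined
#' with \code{"+"} (deterministic).
#'
#' @param similarities data.frame with columns \code{bin_a}, \code{bin_b},
#'   \code{similarity}.
#' @param threshold merge threshold (default 0.75).
#' @return data.frame \code{bin}, \code{component} -- a valid partition of
#'   all bins mentioned.
#' @export
merge_bins <- function(similarities, threshold = 0.75) {
  bins <- sort(unique(c(as.character(similarities$bin_a),
                        as.character(similarities$bin_b))))
  parent <- stats::setNames(seq_along(bins), bins)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  take <- similarities$similarity >= threshold
  for (r in which(take)) {
    ra <- find(match(as.character(similarities$bin_a[r]), bins))
    rb <- find(match(as.character(similarities$bin_b[r]), bins))
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_along(bins), function(i) find(i), numeric(1))
  comp <- vapply(seq_along(bins), function(i)
    paste(sort(bins[root == root[i]]), collapse = "+"), character(1))
  data.frame(bin = bins, component = comp, stringsAsFactors = FALSE)
}
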