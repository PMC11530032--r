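#' Principal components of an expression matrix
#'
#' Column-centered SVD-based PCA; the embedding used for KNN graphs and bin
#' similarity.
#'
#' @param expr real matrix (cells x features), dense or sparse.
#' @param n_pcs number of components (capped at the matrix rank bound).
#' @return numeric matrix (cells x n_pcs) of PC scores.
#' @export
pca_embed <- function(expr, n_pcs = 30) {
  x <- as.matrix(expr)
  x <- sweep(x, 2, colMeans(x))
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  sv <- svd(x, nu = n_pcs, nv = 0)
  pcs <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs, n_pcs)
  rownames(pcs) <- rownames(expr)
  pcs
}

#' Build an exact KNN graph
#'
#' PCA on log-normalized expression followed by exact Euclidean k-nearest
#' neighbors (no approximate index; deterministic).
#'
#' @param expr real matrix (cells x genes), typically log-normalized HVG
#'   expression; alternatively pass precomputed PCs with
#'   \code{n_pcs = NULL}.
#' @param k number of neighbors per cell.
#' @param n_pcs number of principal components, or \code{NULL} to use
#'   \code{expr} as the embedding directly.
#' @return a \code{knn_graph}: list with \code{nn} (n x k neighbor indices,
#'   nearest first), \code{nn_dist} (n x k distances), \code{pcs}
#'   (embedding), \code{k}.
#' @export
build_knn <- function(expr, k = 15, n_pcs = 30) {
  n <- nrow(expr)
  if (k >= n) stop("build_knn: k = ", k, " >= number of cells (", n, ")")
  pcs <- if (is.null(n_pcs)) as.matrix(expr) else pca_embed(expr, n_pcs)
  nn <- matrix(0L, n, k)
  nd <- matrix(0, n, k)
  sq <- rowSums(pcs^2)
  block <- max(1L, floor(2e7 / n))
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(n, start + block - 1L)
    d2 <- -2 * tcrossprod(pcs[idx, , drop = FALSE], pcs)
    d2 <- d2 + sq[idx]                         # row term, recycled
    d2 <- d2 + rep(sq, each = length(idx))     # column term
    d2[cbind(seq_along(idx), idx)] <- Inf   # exclude self
    for (j in seq_along(idx)) {
      o <- order(d2[j, ])[seq_len(k)]
      nn[idx[j], ] <- o
      nd[idx[j], ] <- sqrt(pmax(0, d2[j, o]))
    }
  }
  structure(list(nn = nn, nn_dist = nd, pcs = pcs, k = k),
            class = "knn_graph")
}

#' Sample index cells and build neighborhoods
#'
#' Samples \code{ceiling(proportion * n)} candidate index cells; with
#' \code{refined = TRUE} each candidate is replaced by the member of its
#' neighbor set minimizing the mean distance to the candidate's neighbors
#' (a local medoid), which concentrates index cells in dense regions and
#' deduplicates heavily overlapping candidates. A neighborhood is the index
#' cell plus its k nearest neighbors; its spatial-FDR weight is the distance
#' from the index cell to its kth neighbor (a density-inverse proxy).
#'
#' @param graph a \code{knn_graph}.
#' @param proportion fraction of cells to sample as candidates, in (0, 1].
#' @param refined replace candidates by local medoids (default TRUE).
#' @param seed integer seed for candidate sampling.
#' @return a \code{nhood_set}: list with \code{index_cells} (integer ids),
#'   \code{membership} (sparse N x cells binary matrix), \code{weights},
#'   \code{k}.
#' @export
sample_neighborhoods <- function(graph, proportion = 0.1, refined = TRUE,
                                 seed = 1L) {
  stopifnot(inherits(graph, "knn_graph"))
  if (proportion <= 0 || proportion > 1)
    stop("sample_neighborhoods: proportion must be in (0, 1]")
  n <- nrow(graph$nn)
  n_cand <- ceiling(proportion * n)
  cand <- if (n_cand >= n) seq_len(n) else
    with_seed(seed, sample.int(n, n_cand))
  if (refined) {
    cand <- vapply(cand, function(i) {
      nbrs <- c(i, graph$nn[i, ])            # candidate + its k NN
      sub <- graph$pcs[nbrs, , drop = FALSE]
      d2 <- outer(rowSums(sub^2), rowSums(sub^2), "+") - 2 * sub %*% t(sub)
      score <- rowMeans(d2)
      min(nbrs[score <= min(score) + 1e-12])  # tie: lowest cell id wins
    }, integer(1))
  }
  index_cells <- sort(unique(cand))          # dedupe; deterministic order
  m <- length(index_cells)
  j <- cbind(index_cells, graph$nn[index_cells, , drop = FALSE])
  membership <- Matrix::sparseMatrix(
    i = rep(seq_len(m), times = graph$k + 1L),
    j = as.vector(j), x = 1, dims = c(m, n))
  weights <- graph$nn_dist[index_cells, graph$k]
  weights[weights <= 0] <- min(c(weights[weights > 0], 1)) * 1e-3 + 1e-12
  structure(list(index_cells = index_cells, membership = membership,
                 weights = weights, k = graph$k),
            class = "nhood_set")
}

#' Count cells per neighborhood per sample
#'
#' @param nhoods a \code{nhood_set}.
#' @param ct the \code{cell_table} the graph was built on (same cell order).
#' @return integer matrix (neighborhoods x samples); column order is
#'   \code{\link{sample_order}(ct)}.
#' @export
count_cells <- function(nhoods, ct) {
  so <- sample_order(ct)
  s <- factor(as.character(ct$obs$sample), levels = so)
  ind <- Matrix::sparseMatrix(i = seq_len(n_cells(ct)),
                              j = as.integer(s), x = 1,
                              dims = c(n_cells(ct), length(so)))
  out <- as.matrix(nhoods$membership %*% ind)
  colnames(out) <- so
  storage.mode(out) <- "integer"
  out
}

#' Neighborhood pseudotime
#'
#' Projects each neighborhood onto the pseudotime axis as the median of its
#' member cells' pseudotimes (robust to stragglers).
#'
#' @param nhoods a \code{nhood_set}.
#' @param ct \code{cell_table} with a complete \code{pseudotime} column.
#' @return numeric vector in \[0,1\], one entry per neighborhood.
#' @export
nhood_pseudotime <- function(nhoods, ct) {
  pt <- ct$obs$pseudotime
  if (is.null(pt) || anyNA(pt))
    stop("nhood_pseudotime: cell_table has missing pseudotime")
  apply(nhoods$membership, 1, function(row) stats::median(pt[row > 0]))
}
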