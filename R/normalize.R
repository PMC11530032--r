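#' Log-CPM normalization
#'
#' Per-cell library-size normalization followed by a log transform:
#' \code{entry = ln(1 + scale * count / cell_total)} (the LogNormalize
#' convention with a default scale factor of 10,000).
#'
#' @param ct a \code{cell_table}, or a counts matrix (cells x genes).
#' @param scale scale factor.
#' @return sparse \code{dgCMatrix} of the same shape as the counts.
#' @export
normalize_log_cpm <- function(ct, scale = 1e4) {
  counts <- if (inherits(ct, "cell_table")) ct$counts else
    methods::as(methods::as(methods::as(ct, "dMatrix"), "generalMatrix"),
                "CsparseMatrix")
  tot <- Matrix::rowSums(counts)
  if (any(tot == 0))
    stop("normalize_log_cpm: ", sum(tot == 0), " cell(s) with zero total ",
         "counts; run qc_filter first")
  out <- Matrix::Diagonal(x = scale / tot) %*% counts
  out@x <- log1p(out@x)
  out <- methods::as(out, "CsparseMatrix")
  dimnames(out) <- dimnames(counts)
  out
}

#' Select highly variable genes
#'
#' Ranks genes by a variance-stabilized dispersion statistic computed on
#' log-normalized expression: dispersion = variance / mean, z-scored within
#' 20 equal-frequency mean bins (the classical dispersion-based HVG scheme).
#' Deterministic; ties broken by gene id lexicographic order.
#'
#' @param expr real matrix (cells x genes), typically
#'   \code{\link{normalize_log_cpm}} output. Column names are the gene ids
#'   used for tie-breaking (column index if absent).
#' @param n_top number of genes to return.
#' @param n_bins number of mean bins for dispersion standardization.
#' @return integer vector of column indices of the selected genes, ordered
#'   from most to least variable.
#' @export
select_hvg <- function(expr, n_top = 2000, n_bins = 20) {
  ng <- ncol(expr)
  if (ng <= n_top) {
    if (ng < n_top)
      warning("select_hvg: only ", ng, " genes available (< n_top = ",
              n_top, "); returning all")
    return(seq_len(ng))
  }
  mu <- Matrix::colMeans(expr)
  ex2 <- Matrix::colMeans(expr^2)
  v <- (ex2 - mu^2) * nrow(expr) / max(1, nrow(expr) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  # standardize dispersion within equal-frequency mean bins
  n_bins <- min(n_bins, max(1, floor(ng / 5)))
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mu, breaks = br, include.lowest = TRUE)
  zdisp <- disp
  for (b in levels(bin)) {
    i <- which(bin == b)
    m <- mean(disp[i]); s <- stats::sd(disp[i])
    zdisp[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - m) / s
  }
  gid <- colnames(expr)
  if (is.null(gid)) gid <- sprintf("g%09d", seq_len(ng))
  ord <- order(-zdisp, gid)
  ord[seq_len(n_top)]
}
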