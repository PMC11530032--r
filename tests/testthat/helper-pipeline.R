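# Shared fixtures and pipeline shorthands, all built in code at test time.

# Toy-scale config used across suites: 2 groups x 4 samples x 500 cells x
# 300 genes; moderately expressed baselines so neighborhood pseudobulks
# carry usable counts.
toy_config <- function(seed, ...) {
  sim_config(seed = seed, baseline_log_mean = c(log(1.5), 0.6), ...)
}

# Expression -> HVG -> KNN -> neighborhoods, the common front end.
make_nhoods <- function(ct, k = 30, n_hvg = 200, proportion = 0.1,
                        seed = 1L) {
  expr <- normalize_log_cpm(ct)
  hvg <- select_hvg(expr, n_top = min(n_hvg, ncol(expr)))
  graph <- build_knn(expr[, hvg, drop = FALSE], k = k, n_pcs = 30)
  sample_neighborhoods(graph, proportion = proportion, seed = seed)
}

# Split a multi-sample table into per-sample trajectories.
split_trajectories <- function(ct) {
  so <- sample_order(ct)
  out <- lapply(so, function(s) subset_cells(ct, ct$obs$sample == s))
  names(out) <- so
  out
}

# Independent oracle: binomial CDF by direct term summation with exact
# integer binomial coefficients (totals <= ~500 keep choose() exact).
binom_cdf_oracle <- function(n_accept, n_total, lambda) {
  i <- 0:n_accept
  sum(choose(n_total, i) * lambda^i * (1 - lambda)^(n_total - i))
}

# Independent oracle: weighted BH by the definitional double loop.
spatial_fdr_oracle <- function(p, w) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]; ws <- w[o]
  fdr <- numeric(n)
  for (j in seq_len(n)) {
    best <- Inf
    for (l in j:n) {
      val <- ps[l] * sum(w) / sum(ws[1:l])
      if (val < best) best <- val
    }
    fdr[j] <- min(1, best)
  }
  out <- numeric(n)
  out[o] <- fdr
  out
}

# Independent oracle: the three pseudotemporal gene attributes by explicit
# loops over bins and cells.
gene_attributes_oracle <- function(expr, pt, n_bins = 10) {
  bins <- integer(length(pt))
  for (i in seq_along(pt)) {
    b <- floor(pt[i] * n_bins) + 1
    if (b > n_bins) b <- n_bins
    bins[i] <- b
  }
  bm <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    vals <- expr[bins == b]
    if (length(vals) > 0) bm[b] <- sum(vals) / length(vals)
  }
  occ <- which(!is.na(bm))
  peak <- occ[1]
  for (b in occ) if (bm[b] > bm[peak]) peak <- b
  corr <- if (stats::sd(expr) == 0) 0 else stats::cor(expr, pt)
  list(correlation = corr, peak = peak, expression = mean(bm[occ]))
}
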