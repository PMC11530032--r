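test_that("gene_attributes matches closed-form and flagged cases", {
  n <- 200
  pt <- seq(0, 1, length.out = n)
  a <- gene_attributes(pt, pt)            # expression == pseudotime
  expect_equal(a$correlation, 1)
  expect_equal(a$peak, 10L)
  b <- gene_attributes(rep(3.5, n), pt)   # constant expression
  expect_equal(b$correlation, 0)
  expect_equal(b$expression, 3.5)
  expect_equal(b$flag, "zero_variance")
  # low-noise Gaussian bump at t0 = 0.55 peaks in bin 6 = ceil(0.55 * 10)
  set.seed(33)
  bump <- exp(-(pt - 0.55)^2 / 0.02) + rnorm(n, 0, 0.01)
  expect_equal(gene_attributes(bump, pt)$peak, 6L)
  expect_error(gene_attributes(1:5 / 5, 1:5 / 5, n_bins = 10), "n_bins")
})

test_that("gene_attributes equals the explicit-loop oracle", {
  set.seed(77)
  for (case in 1:25) {
    n <- sample(30:120, 1)
    pt <- runif(n)
    expr <- rnorm(n, 2, 1)
    got <- gene_attributes(expr, pt)
    want <- gene_attributes_oracle(expr, pt)
    expect_identical(got$peak, as.integer(want$peak))
    expect_equal(got$correlation, want$correlation, tolerance = 1e-12)
    expect_equal(got$expression, want$expression, tolerance = 1e-12)
  }
})

test_that("partition_bins shares the interval boundary convention", {
  expect_equal(partition_bins(0), 1L)
  expect_equal(partition_bins(0.95), 10L)
  expect_equal(partition_bins(1), 10L)
  set.seed(4)
  pt <- runif(5000)
  occ <- tabulate(partition_bins(pt), 10)
  expect_true(all(abs(occ - 500) < 4 * sqrt(500)))
})

test_that("common pseudotime memorizes the reference and degrades safely", {
  cfg <- toy_config(71, n_samples_per_group = 2, n_cells_per_sample = 200)
  ct <- simulate_trajectories(cfg)
  m <- fit_common_pseudotime(ct, n_features = 50, seed = 3,
                             n_trees = 300, max_depth = 4)
  pred <- predict_common_pseudotime(m, ct)
  expect_gte(cor(pred, ct$obs$pseudotime, method = "spearman"), 0.99)
  expect_true(all(pred >= 0 & pred <= 1))

  # all-zero query cell: prediction stays in [0,1], no NaN
  q <- ct
  counts <- as.matrix(q$counts)
  counts[1, ] <- 0
  counts[1, 1] <- 1       # keep the library nonzero for normalization
  q$counts <- Matrix::Matrix(counts, sparse = TRUE)
  predq <- predict_common_pseudotime(m, q)
  expect_false(anyNA(predq))
  expect_true(all(predq >= 0 & predq <= 1))

  # shuffled gene labels exercise the overlap warning / error paths
  q2 <- ct
  q2$var$gene_id <- paste0("x_", q2$var$gene_id)
  colnames(q2$counts) <- q2$var$gene_id
  expect_error(predict_common_pseudotime(m, q2), "overlap")
  q3 <- ct
  keep <- m$features[1:15]            # 30% overlap
  q3$var$gene_id[!q3$var$gene_id %in% keep] <-
    paste0("y_", q3$var$gene_id[!q3$var$gene_id %in% keep])
  colnames(q3$counts) <- q3$var$gene_id
  expect_warning(predict_common_pseudotime(m, q3), "overlap")

  # preconditions
  tiny <- subset_cells(ct, 1:100)
  expect_error(fit_common_pseudotime(tiny), "200")
})

test_that("bin_similarity separates distributions and is symmetric", {
  set.seed(9)
  rep_mat <- rbind(matrix(rnorm(120 * 8), 120, 8),
                   matrix(rnorm(60 * 8, 5), 60, 8))
  # bootstrap resample of the same distribution: near-chance classifier
  sims <- vapply(1:5, function(s)
    bin_similarity(rep_mat, 1:60, 61:120, seed = s)$similarity, numeric(1))
  expect_gte(mean(sims), 0.8)
  # well-separated Gaussians: near-perfect classifier
  sims2 <- vapply(1:5, function(s)
    bin_similarity(rep_mat, 1:60, 121:180, seed = s)$similarity,
    numeric(1))
  expect_lte(mean(sims2), 0.2)
  # symmetric under the same seed protocol
  s_ab <- bin_similarity(rep_mat, 1:60, 121:180, seed = 2)
  s_ba <- bin_similarity(rep_mat, 121:180, 1:60, seed = 2)
  expect_equal(s_ab$similarity, s_ba$similarity)
  expect_error(bin_similarity(rep_mat, 1:10, 61:120), ">= 20")
})

test_that("merge_bins is a valid union-find partition", {
  allsim <- expand.grid(bin_a = c("t1.b1", "t1.b2"),
                        bin_b = c("t2.b1", "t2.b2"))
  allsim$similarity <- 1
  m1 <- merge_bins(allsim)
  expect_equal(length(unique(m1$component)), 1)
  allsim$similarity <- 0
  m0 <- merge_bins(allsim)
  expect_equal(m0$component, m0$bin)
  # chained merges stay transitive (partition property)
  chain <- data.frame(bin_a = c("a", "b"), bin_b = c("b", "c"),
                      similarity = c(0.8, 0.9))
  mc <- merge_bins(chain, threshold = 0.75)
  expect_equal(unique(mc$component), "a+b+c")
})

test_that("converging trajectories merge only in late bins", {
  # two trajectory groups that express distinct early/mid programs on a
  # shared flat baseline and converge onto a common late program: bins
  # before the convergence point stay separable, late bins merge
  hits <- 0
  for (s in 1:3) {
    shared_late <- gene_program(51:75, t0 = 0.85, width = 0.1,
                                amplitude = 2.5)
    cfg1 <- sim_config(
      n_samples_per_group = 1, groups = "A", n_cells_per_sample = 600,
      n_genes = 150, seed = 500 + s,
      baseline_log_mean = c(log(2), 0),
      programs = list(gene_program(1:25, t0 = 0.15, width = 0.12,
                                   amplitude = 2.5),
                      gene_program(76:100, t0 = 0.45, width = 0.12,
                                   amplitude = 2.5),
                      shared_late))
    cfg2 <- cfg1
    cfg2$seed <- 700 + s
    cfg2$programs <- list(gene_program(26:50, t0 = 0.15, width = 0.12,
                                       amplitude = 2.5),
                          gene_program(101:125, t0 = 0.45, width = 0.12,
                                       amplitude = 2.5),
                          shared_late)
    ct1 <- simulate_trajectories(cfg1)
    ct2 <- simulate_trajectories(cfg2)
    expr <- normalize_log_cpm(rbind(ct1$counts, ct2$counts))
    rep_mat <- pca_embed(expr, 30)
    src <- rep(c(1, 2), each = 600)
    bins <- partition_bins(c(ct1$obs$pseudotime, ct2$obs$pseudotime))
    sims <- do.call(rbind, lapply(1:10, function(b) {
      ia <- which(src == 1 & bins == b)
      ib <- which(src == 2 & bins == b)
      if (length(ia) < 20 || length(ib) < 20) return(NULL)
      s2 <- bin_similarity(rep_mat, ia, ib, seed = s)
      data.frame(bin_a = sprintf("t1.b%02d", b),
                 bin_b = sprintf("t2.b%02d", b), bin = b,
                 similarity = s2$similarity)
    }))
    merged <- merge_bins(sims[, c("bin_a", "bin_b", "similarity")])
    n_comp <- length(unique(merged$component))
    merged_bins <- sims$bin[sims$similarity >= 0.75]
    # some late bin merges; nothing merges before the convergence point
    ok <- length(merged_bins) > 0 && all(merged_bins >= 7) &&
      n_comp < nrow(merged)
    if (ok) hits <- hits + 1
  }
  expect_gte(hits, 2)
})
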