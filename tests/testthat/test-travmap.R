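test_that("build_traj_matrix scales rows and matches a CPM recount", {
  cfg <- sim_config(n_samples_per_group = 1, groups = "A",
                    n_cells_per_sample = 300, n_genes = 80, seed = 41)
  ct <- simulate_trajectories(cfg)
  tm <- build_traj_matrix(ct, n_intervals = 20, n_hvg = 60,
                          trajectory_id = "t1")
  expect_true(all(tm$matrix >= 0))
  expect_true(all(apply(tm$matrix, 1, max) <= 1 + 1e-12))
  # brute-force per-interval CPM for a few genes
  iv <- assign_intervals(ct$obs$pseudotime, 20)
  for (g in tm$gene_ids[1:5]) {
    gi <- match(g, ct$var$gene_id)
    cpm <- vapply(tm$interval_ids, function(b) {
      cells <- which(iv == b)
      sum(ct$counts[cells, gi]) / sum(ct$counts[cells, ]) * 1e6
    }, numeric(1))
    want <- cpm / max(cpm)
    expect_equal(unname(tm$matrix[match(g, tm$gene_ids), ]), want,
                 tolerance = 1e-9)
  }
  # constant gene scales to ones; late gene concentrates late
  m <- matrix(c(rep(5, 10), c(rep(0, 8), 3, 9)), 2, 10, byrow = TRUE)
  rmax <- apply(m, 1, max)
  sc <- m / rmax
  expect_equal(sc[1, ], rep(1, 10))
  expect_true(sum(sc[2, 9:10]) / sum(sc[2, ]) == 1)
  # too few occupied intervals rejected
  ct2 <- subset_cells(ct, ct$obs$pseudotime < 0.15)
  expect_error(build_traj_matrix(ct2, n_intervals = 10, n_hvg = 20),
               "rejected")
})

test_that("nmf_decompose factors exactly-low-rank and planted structures", {
  set.seed(6)
  # exact rank-1: error below 1e-8
  V <- outer(runif(30) + 0.1, runif(12) + 0.1)
  f <- nmf_decompose(V, K = 1, seed = 3, max_iter = 3000, tol = 1e-13)
  expect_lt(f$recon_error, 1e-8)
  expect_true(all(diff(f$objective) <= 1e-9))   # monotone non-increasing
  expect_equal(sum(f$W^2), 1, tolerance = 1e-8) # unit-normalized column

  # planted 3 disjoint gene-block x time-bump programs
  t <- seq(0, 1, length.out = 25)
  bumps <- cbind(exp(-(t - 0.15)^2 / 0.005), exp(-(t - 0.5)^2 / 0.005),
                 exp(-(t - 0.85)^2 / 0.005))
  W0 <- matrix(0, 60, 3)
  W0[1:20, 1] <- runif(20) + 0.5
  W0[21:40, 2] <- runif(20) + 0.5
  W0[41:60, 3] <- runif(20) + 0.5
  V3 <- W0 %*% t(bumps) + matrix(abs(rnorm(60 * 25, 0, 0.01)), 60, 25)
  f3 <- nmf_decompose(V3, K = 3, seed = 5, max_iter = 1000)
  cors <- abs(cor(f3$W, W0))
  # greedy optimal matching: each recovered factor pairs with one block
  matched <- numeric(3)
  used <- integer(0)
  for (k in 1:3) {
    j <- which.max(ifelse(seq_len(3) %in% used, -1, cors[k, ]))
    matched[k] <- cors[k, j]
    used <- c(used, j)
  }
  expect_true(all(matched > 0.9))
  expect_error(nmf_decompose(V, K = 20), "K")
})

test_that("choose_rank recovers the planted rank", {
  set.seed(8)
  V1 <- outer(runif(40) + 0.2, runif(15) + 0.2)
  expect_equal(choose_rank(V1, c(1, 3, 6), seed = 1), 1)   # noise-free rank 1
  expect_equal(choose_rank(V1, 4), 4)                      # single candidate
  hits <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    V2 <- outer(runif(40) + 0.2, runif(15) + 0.2) +
      outer(runif(40) + 0.2, runif(15) + 0.2) +
      matrix(abs(rnorm(600, 0, 0.05)), 40, 15)
    if (choose_rank(V2, c(1, 2, 6), mask_frac = 0.2, n_masks = 5,
                    seed = s) == 2) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("trav cluster-count arithmetic is exact", {
  expect_equal(trav_cluster_count(121, 15), 226L)
  expect_equal(trav_cluster_count(8, 15), 15L)
  expect_equal(trav_cluster_count(1, 5), 1L)     # < 8 factors floor
})

test_that("pool_and_cluster partitions factors and trav_activity is bounded", {
  cfg <- toy_config(43, n_cells_per_sample = 250)
  ct <- simulate_trajectories(cfg)
  tv <- fit_travmap(split_trajectories(ct), K = 5, n_intervals = 20,
                    n_hvg = 150, seed = 17)
  ts <- tv$travset
  expect_equal(ts$C, trav_cluster_count(8, 5))
  # every pooled factor in exactly one TRAV
  expect_equal(length(ts$membership), 8 * 5)
  expect_equal(sum(vapply(ts$travs, function(t) nrow(t$members),
                          integer(1))), 8 * 5)
  act <- tv$activity
  expect_true(all(act >= -1 - 1e-9 & act <= 1 + 1e-9))
  # a trajectory owning a member factor scores high for that TRAV
  for (t in seq_len(ts$C)) {
    owners <- unique(ts$travs[[t]]$members$trajectory)
    expect_gte(max(act[t, owners]), max(act[t, ]) - 1e-9)
  }
})

test_that("conserved_travs boundary behavior is exact", {
  act <- matrix(0, 3, 15,
                dimnames = list(c("TRAV1", "TRAV2", "TRAV3"), NULL))
  act[1, 1:6] <- 0.5       # 40% of trajectories: conserved
  act[2, 1:5] <- 0.5       # exactly 1/3: NOT conserved (strict >)
  act[3, 1:6] <- 0.4       # exactly at threshold: NOT high (strict >)
  expect_equal(conserved_travs(act), "TRAV1")
})

test_that("covariate_travs finds planted effects and stays calibrated", {
  set.seed(23)
  act <- matrix(rnorm(10 * 12, 0.3, 0.08), 10, 12,
                dimnames = list(sprintf("TRAV%d", 1:10), NULL))
  cov <- rep(c("young", "old"), each = 6)
  proj <- rep(c("p1", "p2", "p3"), 4)
  act[4, cov == "old"] <- act[4, cov == "old"] + 0.35
  res <- covariate_travs(act, cov, proj)
  expect_equal(res$trav[which.min(res$p)], "TRAV4")
  expect_lt(res$fdr[res$trav == "TRAV4"], 0.05)
  # identical activity across levels: effect ~ 0, p ~ 1
  act2 <- act
  act2[1, ] <- rep(c(0.2, 0.4, 0.3, 0.2, 0.4, 0.3), 2)
  res2 <- covariate_travs(act2, cov, proj)
  expect_lt(abs(res2$effect[1]), 0.15)
  expect_gt(res2$p[1], 0.2)
})

test_that("trav_temporal_profile locates the module stage", {
  cfg <- toy_config(44, n_cells_per_sample = 250)
  ct <- simulate_trajectories(cfg)
  trajs <- split_trajectories(ct)
  tv <- fit_travmap(trajs, K = 5, n_intervals = 20, n_hvg = 150, seed = 11)
  prof <- trav_temporal_profile(tv$travset, tv$activity, trajs)
  expect_equal(nrow(prof), tv$travset$C)
  expect_true(all(prof$peak %in% 1:10))
  expect_true(all(abs(prof$correlation) <= 1))
  # the TRAV matching the late program (t0 = 0.9) peaks late
  mt <- attr(ct, "module_truth")
  late_genes <- mt$gene_id[mt$t0 == 0.90]
  ov <- vapply(tv$travset$travs, function(t)
    length(intersect(t$module, late_genes)), integer(1))
  expect_gte(prof$peak[which.max(ov)], 8)
})

test_that("embed_trajectories is deterministic and separates families", {
  skip_if_not_installed("cluster")
  set.seed(15)
  # two trajectory families with distinct activity blocks
  actA <- cbind(matrix(rnorm(6 * 4, 0.8, 0.05), 6),
                matrix(rnorm(6 * 4, 0.0, 0.05), 6))
  actB <- cbind(matrix(rnorm(6 * 4, 0.0, 0.05), 6),
                matrix(rnorm(6 * 4, 0.8, 0.05), 6))
  act <- rbind(actA, actB)
  expr <- matrix(rnorm(12 * 5), 12, 5)
  co1 <- embed_trajectories(list(activity = act, expression = expr))
  co2 <- embed_trajectories(list(activity = act, expression = expr))
  expect_identical(co1, co2)
  fam <- rep(c(1, 2), each = 6)
  sil <- cluster::silhouette(fam, dist(co1))
  expect_gt(mean(sil[, 3]), 0.3)
  # identical trajectories land together
  act3 <- rbind(act, act[1, ])
  co3 <- embed_trajectories(list(activity = act3))
  expect_lt(sqrt(sum((co3[13, ] - co3[1, ])^2)), 1e-6)
})
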