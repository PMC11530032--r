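# TrajDiff: neighborhood-level differential testing with spatial FDR,
# projection onto pseudotime intervals, and the binomial interval test
# against a permutation-estimated null acceptance rate.

#' Weighted (spatial) false-discovery rate
#'
#' Weighted Benjamini-Hochberg over neighborhoods: order p ascending and set
#' \code{fdr_j = min over l >= j of p_l * sum(w) / sum_{m <= l} w_m},
#' clipped to 1, returned in input order. Weights compensate for uneven
#' graph density (a neighborhood in a dense region counts for less). With
#' unit weights this is exactly classical BH.
#'
#' @param p p-value vector.
#' @param weights positive weight per hypothesis.
#' @return vector of spatial FDR values in input order.
#' @export
spatial_fdr <- function(p, weights) {
  if (length(p) != length(weights))
    stop("spatial_fdr: length(p) != length(weights)")
  if (any(weights <= 0)) stop("spatial_fdr: weights must be > 0")
  o <- order(p)
  cw <- cumsum(weights[o])
  adj <- p[o] * sum(weights) / cw
  fdr <- pmin(1, rev(cummin(rev(adj))))
  out <- numeric(length(p))
  out[o] <- fdr
  out
}

#' Assign pseudotimes to equal-width intervals
#'
#' Half-open bins \code{[(i-1)/n, i/n)} with the last bin closed at 1;
#' ids 1..n. Shared by interval projection and trajectory-bin partitioning.
#'
#' @param pt pseudotime vector in \[0,1\].
#' @param n_intervals number of intervals (default 100).
#' @return integer interval ids.
#' @export
assign_intervals <- function(pt, n_intervals = 100) {
  if (any(pt < 0 | pt > 1)) stop("assign_intervals: pseudotime outside [0,1]")
  pmin(n_intervals, floor(pt * n_intervals) + 1L)
}

#' Label neighborhoods Accept / Rejection
#'
#' Rejection iff spatial FDR is strictly below \code{alpha}.
#'
#' @param fdr spatial FDR vector.
#' @param alpha threshold (default 0.05).
#' @return character vector of \code{"Accept"} / \code{"Rejection"}.
#' @export
label_accept_reject <- function(fdr, alpha = 0.05) {
  ifelse(fdr < alpha, "Rejection", "Accept")
}

#' Estimate the null acceptance rate lambda per interval
#'
#' From shuffled-label runs: lambda is the mean over shuffles of the interval
#' acceptance fraction N_accept / (N_accept + N_rejection). If the mean is 0
#' it is replaced by the precision of the calculation,
#' \code{1 / ((N_accept + N_rejection) * n_shuffles)}; symmetrically, a mean
#' of 1 is capped at one minus that precision so the downstream binomial test
#' is always well defined. Intervals empty in all shuffles get \code{NA}.
#'
#' @param null_runs list (one element per shuffle) of two-column matrices,
#'   rows = intervals, columns = (N_accept, N_rejection).
#' @param n_shuffles number of shuffles (defaults to
#'   \code{length(null_runs)}).
#' @return numeric vector of lambda per interval (NA where undefined).
#' @export
estimate_lambda <- function(null_runs, n_shuffles = length(null_runs)) {
  if (n_shuffles < 1) stop("estimate_lambda: n_shuffles must be >= 1")
  acc <- sapply(null_runs, function(m) m[, 1])
  tot <- sapply(null_runs, function(m) m[, 1] + m[, 2])
  acc <- rbind(acc); tot <- rbind(tot)
  frac <- ifelse(tot > 0, acc / pmax(tot, 1), NA)
  lam <- rowMeans(frac, na.rm = TRUE)
  n_tot <- rowMeans(tot)
  prec <- 1 / (pmax(n_tot, 1e-300) * n_shuffles)
  lam[!is.nan(lam) & lam == 0] <- prec[!is.nan(lam) & lam == 0]
  lam <- pmin(lam, 1 - prec)
  lam[is.nan(lam) | rowSums(tot) == 0] <- NA
  unname(lam)
}

#' Binomial interval test
#'
#' Tests whether an interval holds unusually many Rejection neighborhoods:
#' \code{p = sum_{i=0}^{N_accept} C(N, i) lambda^i (1-lambda)^{N-i}} with
#' \code{N = N_accept + N_rejection}, i.e. the binomial CDF at N_accept with
#' success probability lambda (the null acceptance rate). Small p means
#' fewer acceptances than the null predicts.
#'
#' @param N_accept,N_rejection non-negative counts, not both zero
#'   (vectorized).
#' @param lambda null acceptance probability in (0, 1).
#' @return p-value(s) in (0, 1\].
#' @export
binomial_interval_test <- function(N_accept, N_rejection, lambda) {
  if (any(N_accept < 0 | N_rejection < 0))
    stop("binomial_interval_test: negative counts")
  if (any(N_accept + N_rejection == 0))
    stop("binomial_interval_test: N_accept and N_rejection both zero")
  if (any(lambda <= 0 | lambda >= 1))
    stop("binomial_interval_test: lambda must be in (0,1); apply ",
         "estimate_lambda's precision fallback first")
  stats::pbinom(N_accept, N_accept + N_rejection, lambda)
}

#' Overall trajectory-association test
#'
#' The binomial interval test applied to the global Accept/Rejection counts
#' over all neighborhoods, with a globally estimated lambda.
#'
#' @param labels character vector of \code{"Accept"}/\code{"Rejection"}.
#' @param lambda global null acceptance rate in (0, 1).
#' @return p_overall in (0, 1\].
#' @export
overall_test <- function(labels, lambda) {
  binomial_interval_test(sum(labels == "Accept"),
                         sum(labels == "Rejection"), lambda)
}

# Accept/Reject counts per interval -> n_intervals x 2 matrix.
interval_counts <- function(labels, intervals, n_intervals) {
  acc <- tabulate(intervals[labels == "Accept"], nbins = n_intervals)
  rej <- tabulate(intervals[labels == "Rejection"], nbins = n_intervals)
  cbind(N_accept = acc, N_rejection = rej)
}

#' Per-interval effect summaries
#'
#' \code{CPM_interval}: per-group mean of fitted CPM over the neighborhoods
#' assigned to the interval; \code{DiffExpr_interval}: mean of
#' \code{logFC * CPM} over those neighborhoods (the signed effect summary).
#' Empty intervals are marked missing, never fabricated.
#'
#' @param results data.frame with columns \code{logFC}, \code{CPM},
#'   \code{cpm_ref}, \code{cpm_alt} (one row per neighborhood).
#' @param intervals integer interval id per neighborhood.
#' @param n_intervals total number of intervals.
#' @return data.frame with one row per interval: \code{interval},
#'   \code{n_nhoods}, \code{occupied}, \code{CPM_ref}, \code{CPM_alt},
#'   \code{DiffExpr}.
#' @export
interval_summaries <- function(results, intervals, n_intervals = 100) {
  iv <- factor(intervals, levels = seq_len(n_intervals))
  n <- as.integer(table(iv))
  mean_by <- function(x) {
    out <- tapply(x, iv, mean)
    as.numeric(out)
  }
  data.frame(interval = seq_len(n_intervals),
             n_nhoods = n,
             occupied = n > 0,
             CPM_ref = mean_by(results$cpm_ref),
             CPM_alt = mean_by(results$cpm_alt),
             DiffExpr = mean_by(results$logFC * results$CPM))
}

# Shared engine for DA and per-gene DE: takes a features(=neighborhoods) x
# samples count matrix and offset scales, runs the NB tests, spatial FDR,
# interval projection, shuffle-based lambda, and the binomial tests.
trajdiff_engine <- function(Y, L, grp, weights, nhood_pt, n_intervals,
                            alpha, perms, disp = NULL) {
  if (is.null(disp)) disp <- estimate_dispersion(Y, L, grp)$shrunk
  fit <- nb_glm_fit(Y, L, grp, disp)
  fit$spatial_fdr <- spatial_fdr(fit$p_value, weights)
  fit$label <- label_accept_reject(fit$spatial_fdr, alpha)
  fit$interval <- assign_intervals(nhood_pt, n_intervals)
  fit$nhood_pseudotime <- nhood_pt

  null_runs <- lapply(perms, function(gp) {
    fb <- nb_glm_fit(Y, L, gp, disp)
    lb <- label_accept_reject(spatial_fdr(fb$p_value, weights), alpha)
    interval_counts(lb, fit$interval, n_intervals)
  })
  lam <- estimate_lambda(null_runs, length(perms))
  obs <- interval_counts(fit$label, fit$interval, n_intervals)
  occ <- rowSums(obs) > 0
  p_iv <- rep(NA_real_, n_intervals)
  ok <- occ & !is.na(lam)
  p_iv[ok] <- binomial_interval_test(obs[ok, 1], obs[ok, 2], lam[ok])
  fdr_iv <- rep(NA_real_, n_intervals)
  fdr_iv[ok] <- stats::p.adjust(p_iv[ok], method = "BH")

  glob_acc <- vapply(null_runs, function(m) sum(m[, 1]), numeric(1))
  glob_tot <- vapply(null_runs, function(m) sum(m), numeric(1))
  lam_overall <- estimate_lambda(
    lapply(seq_along(perms),
           function(b) cbind(glob_acc[b], glob_tot[b] - glob_acc[b])),
    length(perms))
  p_overall <- overall_test(fit$label, lam_overall)

  ivs <- interval_summaries(fit, fit$interval, n_intervals)
  ivs$N_accept <- obs[, 1]
  ivs$N_rejection <- obs[, 2]
  ivs$lambda <- lam
  ivs$p_interval <- p_iv
  ivs$fdr_interval <- fdr_iv
  list(nhood = fit, intervals = ivs, p_overall = p_overall,
       lambda_overall = lam_overall, dispersion = disp)
}

# Shuffle sample -> group assignments (label permutation).
make_group_perms <- function(grp, n_shuffles, seed) {
  with_seed(seed, lapply(seq_len(n_shuffles), function(b) sample(grp)))
}

#' Differential abundance along pseudotime
#'
#' Full DA pipeline over a neighborhood set: per-sample cell counts per
#' neighborhood, NB GLM test per neighborhood (offset = log total cells per
#' sample), spatial FDR, Accept/Rejection labels, projection onto pseudotime
#' intervals, per-interval lambda from sample-to-group shuffles, binomial
#' interval p-values (BH across occupied intervals) and effect summaries.
#'
#' @param ct a \code{cell_table} with \code{group} and \code{pseudotime}.
#' @param nhoods a \code{nhood_set} built on \code{ct}'s cells.
#' @param n_intervals number of pseudotime intervals (default 100).
#' @param alpha spatial-FDR threshold for Rejection labels.
#' @param n_shuffles number of label shuffles for lambda estimation.
#' @param seed seed for the shuffles.
#' @return list with \code{nhood} (per-neighborhood results),
#'   \code{intervals} (per-interval summary: counts, lambda, p, BH fdr, CPM
#'   per group, DiffExpr), \code{p_overall}, \code{lambda_overall},
#'   \code{dispersion}.
#' @export
run_da <- function(ct, nhoods, n_intervals = 100, alpha = 0.05,
                   n_shuffles = 5, seed = 1L) {
  grp <- sample_groups(ct)
  if (nlevels(grp) != 2) stop("run_da: need exactly 2 groups")
  if (min(table(grp)) < 2) stop("run_da: need >= 2 samples per group")
  Y <- count_cells(nhoods, ct)
  lib <- as.numeric(table(factor(as.character(ct$obs$sample),
                                 levels = sample_order(ct))))
  pt <- nhood_pseudotime(nhoods, ct)
  perms <- make_group_perms(grp, n_shuffles, seed)
  trajdiff_engine(Y, lib, grp, nhoods$weights, pt, n_intervals, alpha,
                  perms)
}

#' Differential expression along pseudotime
#'
#' Pseudobulk DE: member-cell counts are summed per neighborhood per sample
#' to form an N x S x G tensor; for each gene the DA machinery runs on its
#' N x S slab with offsets = log pseudobulk totals (all genes). Outputs
#' per-gene interval summaries, an overall p (BH across genes) and a
#' two-stage pattern label.
#'
#' @inheritParams run_da
#' @param genes gene ids or column indices to test (default: all genes).
#' @param stage_split pseudotime boundary between the early and late stage
#'   for pattern labels.
#' @param min_sig_frac minimum fraction of occupied intervals significant
#'   for a stage to be called Up/Down.
#' @return list with \code{table} (per gene: \code{gene_id},
#'   \code{p_overall}, \code{fdr_overall}, \code{pattern}, \code{skipped}),
#'   \code{intervals} (long data.frame gene x interval) and
#'   \code{per_gene} (list of full engine outputs).
#' @export
run_de <- function(ct, nhoods, genes = NULL, n_intervals = 100,
                   alpha = 0.05, n_shuffles = 5, seed = 1L,
                   stage_split = 0.5, min_sig_frac = 0.2) {
  grp <- sample_groups(ct)
  if (nlevels(grp) != 2) stop("run_de: need exactly 2 groups")
  if (is.null(genes)) genes <- ct$var$gene_id
  gidx <- if (is.character(genes)) match(genes, ct$var$gene_id)
          else as.integer(genes)
  if (anyNA(gidx)) stop("run_de: unknown gene id(s)")
  gene_ids <- ct$var$gene_id[gidx]

  so <- sample_order(ct)
  s_of_cell <- as.character(ct$obs$sample)
  memb <- nhoods$membership
  n_nh <- nrow(memb)
  celltot <- Matrix::rowSums(ct$counts)
  # pseudobulk per sample: N x G_selected, and N x S totals over all genes
  pb <- vector("list", length(so))
  Ltot <- matrix(0, n_nh, length(so))
  for (si in seq_along(so)) {
    cols <- which(s_of_cell == so[si])
    pb[[si]] <- as.matrix(memb[, cols, drop = FALSE] %*%
                            ct$counts[cols, gidx, drop = FALSE])
    Ltot[, si] <- as.numeric(memb[, cols, drop = FALSE] %*% celltot[cols])
  }
  pt <- nhood_pseudotime(nhoods, ct)
  perms <- make_group_perms(grp, n_shuffles, seed)

  per_gene <- vector("list", length(gidx))
  skipped <- logical(length(gidx))
  p_overall <- rep(NA_real_, length(gidx))
  iv_long <- vector("list", length(gidx))
  for (gi in seq_along(gidx)) {
    Y <- vapply(pb, function(m) m[, gi], numeric(n_nh))
    Y <- matrix(Y, n_nh, length(so))
    if (sum(Y) == 0) {
      skipped[gi] <- TRUE
      next
    }
    res <- trajdiff_engine(Y, Ltot, grp, nhoods$weights, pt, n_intervals,
                           alpha, perms)
    per_gene[[gi]] <- res
    p_overall[gi] <- res$p_overall
    iv <- res$intervals
    iv$gene_id <- gene_ids[gi]
    iv_long[[gi]] <- iv
  }
  patterns <- vapply(seq_along(gidx), function(gi) {
    if (skipped[gi]) return(NA_character_)
    label_pattern(per_gene[[gi]]$intervals, alpha = alpha,
                  stage_split = stage_split, min_sig_frac = min_sig_frac)
  }, character(1))
  tab <- data.frame(gene_id = gene_ids, p_overall = p_overall,
                    fdr_overall = stats::p.adjust(p_overall, method = "BH"),
                    pattern = patterns, skipped = skipped,
                    stringsAsFactors = FALSE)
  list(table = tab,
       intervals = do.call(rbind, iv_long[!skipped]),
       per_gene = stats::setNames(per_gene, gene_ids))
}

#' Two-stage pattern label for a gene's interval summary
#'
#' Splits intervals at \code{stage_split}; within each stage the call is
#' \code{"0"} when fewer than \code{min_sig_frac} of the occupied intervals
#' are significant (BH interval FDR < alpha), otherwise the sign of the mean
#' \code{DiffExpr} over the significant intervals (\code{"Up"} for positive,
#' i.e. higher in the second group level). Labels are joined early_late,
#' e.g. \code{"Down_0"}; \code{"0_0"} is non-differential.
#'
#' @param gene_summary per-interval data.frame from the engine (columns
#'   \code{interval}, \code{occupied}, \code{fdr_interval},
#'   \code{DiffExpr}).
#' @param alpha significance threshold on the interval FDR.
#' @param stage_split pseudotime boundary (default 0.5).
#' @param min_sig_frac minimum significant fraction for an Up/Down call.
#' @return a single label such as \code{"Up_0"} or \code{"Down_Down"}.
#' @export
label_pattern <- function(gene_summary, alpha = 0.05, stage_split = 0.5,
                          min_sig_frac = 0.2) {
  n_iv <- max(gene_summary$interval)
  mid <- (gene_summary$interval - 0.5) / n_iv
  call_stage <- function(rows) {
    occ <- rows[rows$occupied & !is.na(rows$fdr_interval), , drop = FALSE]
    if (nrow(occ) == 0) {
      warning("label_pattern: no occupied intervals in a stage; calling '0'")
      return("0")
    }
    sig <- occ[occ$fdr_interval < alpha, , drop = FALSE]
    if (nrow(sig) / nrow(occ) < min_sig_frac) return("0")
    if (mean(sig$DiffExpr) > 0) "Up" else "Down"
  }
  early <- call_stage(gene_summary[mid < stage_split, , drop = FALSE])
  late <- call_stage(gene_summary[mid >= stage_split, , drop = FALSE])
  paste(early, late, sep = "_")
}

#' Cluster DiffExpr interval profiles (figure-style grouping)
#'
#' Optional k-means (default k = 8) on per-gene DiffExpr interval profiles,
#' mirroring heatmap-style gene clustering. Missing intervals are imputed
#' as 0 for clustering only.
#'
#' @param intervals_long long data.frame from \code{\link{run_de}} (columns
#'   \code{gene_id}, \code{interval}, \code{DiffExpr}).
#' @param k number of clusters.
#' @param seed seed for k-means initialization.
#' @return data.frame \code{gene_id}, \code{cluster}.
#' @export
cluster_patterns <- function(intervals_long, k = 8, seed = 1L) {
  genes <- unique(intervals_long$gene_id)
  n_iv <- max(intervals_long$interval)
  mat <- matrix(0, length(genes), n_iv, dimnames = list(genes, NULL))
  de <- ifelse(is.na(intervals_long$DiffExpr), 0, intervals_long$DiffExpr)
  mat[cbind(match(intervals_long$gene_id, genes),
            intervals_long$interval)] <- de
  k <- min(k, nrow(mat))
  km <- with_seed(seed, stats::kmeans(mat, centers = k, nstart = 5))
  data.frame(gene_id = genes, cluster = km$cluster,
             stringsAsFactors = FALSE)
}
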