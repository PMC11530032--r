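# TRAVMap: per-trajectory pseudotemporal expression matrices, NMF, pooled
# factor clustering into TRAVs (trajectory-related replicable axes of
# variation), gene modules, activity scoring, and conserved / covariate-
# associated TRAV detection.

#' Pseudotemporal expression matrix of one trajectory
#'
#' Pools the trajectory's cells within each pseudotime interval and computes
#' per-gene CPM (1e6 * gene counts / total counts of pooled cells), drops
#' empty intervals, restricts to a gene vocabulary (given, or the top HVGs
#' of this trajectory) and scales each row by its maximum so rows are
#' comparable while staying non-negative (an NMF requirement).
#'
#' @param ct_sample \code{cell_table} of one trajectory, with pseudotime.
#' @param n_intervals number of pseudotime intervals.
#' @param n_hvg number of highly variable genes when \code{genes} is NULL.
#' @param genes optional character vector fixing the (shared) gene
#'   vocabulary.
#' @param min_intervals minimum occupied intervals; fewer rejects the
#'   trajectory with an error.
#' @param trajectory_id identifier stored with the matrix.
#' @return a \code{traj_matrix}: list with \code{matrix} (genes x occupied
#'   intervals, row-scaled), \code{gene_ids}, \code{interval_ids},
#'   \code{interval_mid} (pseudotime midpoints), \code{trajectory_id}.
#' @export
build_traj_matrix <- function(ct_sample, n_intervals = 100, n_hvg = 2000,
                              genes = NULL, min_intervals = 5,
                              trajectory_id = NULL) {
  pt <- ct_sample$obs$pseudotime
  if (is.null(pt) || anyNA(pt))
    stop("build_traj_matrix: trajectory lacks pseudotime")
  iv <- assign_intervals(pt, n_intervals)
  occupied <- sort(unique(iv))
  if (length(occupied) < min_intervals)
    stop("build_traj_matrix: trajectory '", trajectory_id, "' occupies ",
         length(occupied), " < ", min_intervals, " intervals; rejected")
  if (is.null(genes)) {
    expr <- normalize_log_cpm(ct_sample)
    genes <- ct_sample$var$gene_id[select_hvg(expr, n_top = n_hvg)]
  }
  gidx <- match(genes, ct_sample$var$gene_id)
  if (anyNA(gidx))
    stop("build_traj_matrix: vocabulary gene(s) missing from trajectory")
  ind <- Matrix::sparseMatrix(i = match(iv, occupied), j = seq_along(iv),
                              x = 1,
                              dims = c(length(occupied), length(iv)))
  gsum <- as.matrix(ind %*% ct_sample$counts[, gidx, drop = FALSE])
  tsum <- as.numeric(ind %*% Matrix::rowSums(ct_sample$counts))
  cpm <- t(gsum / tsum * 1e6)                  # genes x intervals
  rmax <- apply(cpm, 1, max)
  scaled <- cpm / ifelse(rmax > 0, rmax, 1)
  rownames(scaled) <- genes
  structure(list(matrix = scaled, gene_ids = genes,
                 interval_ids = occupied,
                 interval_mid = (occupied - 0.5) / n_intervals,
                 trajectory_id = trajectory_id),
            class = "traj_matrix")
}

#' Non-negative matrix factorization of a trajectory matrix
#'
#' Multiplicative-update NMF (Frobenius objective) from a seeded uniform
#' non-negative initialization. The objective is non-increasing per
#' iteration; convergence when the relative objective change drops below
#' \code{tol} or after \code{max_iter} iterations. Loading columns of W are
#' L2-normalized (scale moved into H).
#'
#' @param tm a \code{traj_matrix} or a plain non-negative matrix.
#' @param K rank (number of factors); must be < min(dim).
#' @param seed seed for the initialization.
#' @param max_iter,tol stopping rule.
#' @return a \code{traj_factorization}: list with \code{W} (genes x K),
#'   \code{H} (K x intervals), \code{K}, \code{recon_error} (final
#'   Frobenius norm), \code{objective} (per-iteration trace),
#'   \code{interval_mid}, \code{trajectory_id}.
#' @export
nmf_decompose <- function(tm, K = 15, seed = 1L, max_iter = 500,
                          tol = 1e-6) {
  V <- if (inherits(tm, "traj_matrix")) tm$matrix else as.matrix(tm)
  if (any(V < 0)) stop("nmf_decompose: input has negative entries")
  if (K >= min(dim(V)))
    stop("nmf_decompose: K = ", K, " must be < min(genes, intervals) = ",
         min(dim(V)))
  sc <- sqrt(mean(V) / K + 1e-12)
  init <- with_seed(seed, list(W = matrix(stats::runif(nrow(V) * K), ncol = K),
                               H = matrix(stats::runif(K * ncol(V)), nrow = K)))
  W <- init$W * sc; H <- init$H * sc
  eps <- 1e-12
  obj <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    e <- sqrt(sum((V - W %*% H)^2))
    obj <- c(obj, e)
    if (is.finite(prev) && prev > 0 && abs(prev - e) / prev < tol) break
    prev <- e
  }
  nrm <- sqrt(colSums(W^2))
  nrm[nrm == 0] <- 1
  W <- sweep(W, 2, nrm, "/")
  H <- sweep(H, 1, nrm, "*")
  rownames(W) <- rownames(V)
  structure(list(W = W, H = H, K = as.integer(K),
                 recon_error = obj[length(obj)],
                 objective = obj,
                 interval_mid = if (inherits(tm, "traj_matrix"))
                   tm$interval_mid else NULL,
                 trajectory_id = if (inherits(tm, "traj_matrix"))
                   tm$trajectory_id else NULL),
            class = "traj_factorization")
}

#' Choose the NMF rank by masked cross-validation
#'
#' Randomly masks a fraction of entries, fits NMF on the unmasked part
#' (mask-weighted multiplicative updates) and picks the candidate K
#' minimizing held-out squared error, averaged over \code{n_masks} masks;
#' ties go to the smaller K.
#'
#' @param tm a \code{traj_matrix} or non-negative matrix.
#' @param candidate_Ks integer vector of candidate ranks (>= 1 candidate).
#' @param mask_frac fraction of entries held out per mask.
#' @param n_masks number of random masks.
#' @param seed seed for masks and initializations.
#' @param max_iter NMF iterations per fit.
#' @return the selected K.
#' @export
choose_rank <- function(tm, candidate_Ks, mask_frac = 0.1, n_masks = 3,
                        seed = 1L, max_iter = 200) {
  V <- if (inherits(tm, "traj_matrix")) tm$matrix else as.matrix(tm)
  candidate_Ks <- sort(unique(as.integer(candidate_Ks)))
  if (length(candidate_Ks) == 1) return(candidate_Ks)
  err <- matrix(NA_real_, length(candidate_Ks), n_masks)
  eps <- 1e-12
  for (m in seq_len(n_masks)) {
    mask <- with_seed(seed + 1000L * m, matrix(
      stats::runif(length(V)) >= mask_frac, nrow(V), ncol(V)))
    M <- mask * 1
    for (ki in seq_along(candidate_Ks)) {
      K <- candidate_Ks[ki]
      sc <- sqrt(mean(V) / K + 1e-12)
      init <- with_seed(seed + m + 37L * K, list(
        W = matrix(stats::runif(nrow(V) * K), ncol = K) * sc,
        H = matrix(stats::runif(K * ncol(V)), nrow = K) * sc))
      W <- init$W; H <- init$H
      for (it in seq_len(max_iter)) {
        WH <- W %*% H
        H <- H * crossprod(W, M * V) / (crossprod(W, M * WH) + eps)
        WH <- W %*% H
        W <- W * ((M * V) %*% t(H)) / ((M * WH) %*% t(H) + eps)
      }
      R <- V - W %*% H
      err[ki, m] <- mean(R[!mask]^2)
    }
  }
  mean_err <- rowMeans(err)
  candidate_Ks[which.min(mean_err)]   # which.min takes the first = smaller K
}

#' Cluster-count rule for pooled factors
#'
#' The number of TRAV clusters formed from D trajectories of K factors each:
#' \code{floor(D * K / 8)} (at least 1).
#'
#' @param n_trajectories D.
#' @param n_factors K per trajectory.
#' @return integer cluster count.
#' @export
trav_cluster_count <- function(n_trajectories, n_factors) {
  max(1L, as.integer(floor(n_trajectories * n_factors / 8)))
}

#' Pool NMF factors across trajectories and cluster into TRAVs
#'
#' Pools all loading vectors (columns of W, shared gene vocabulary) from D
#' factorizations, clusters them by average-linkage hierarchical clustering
#' on correlation distance, cuts the tree to \code{floor(D*K/8)} clusters,
#' and defines each TRAV by the mean loading vector of its member factors
#' and the top \code{module_size} genes of that mean loading.
#'
#' @param factorizations list of \code{traj_factorization} objects on the
#'   same gene vocabulary.
#' @param module_size module size (default 100; capped at the vocabulary).
#' @return a \code{trav_set}: list with \code{loading} (genes x C),
#'   \code{travs} (per-TRAV list: id, members, module, peak_stage),
#'   \code{membership} (factor-to-TRAV assignment), \code{C}.
#' @export
pool_and_cluster <- function(factorizations, module_size = 100) {
  D <- length(factorizations)
  W_all <- do.call(cbind, lapply(factorizations, function(f) f$W))
  n_fac <- ncol(W_all)
  src <- data.frame(
    trajectory = rep(vapply(seq_len(D), function(i) {
      id <- factorizations[[i]]$trajectory_id
      if (is.null(id)) paste0("traj", i) else as.character(id)
    }, character(1)), vapply(factorizations, function(f) f$K, integer(1))),
    factor = unlist(lapply(factorizations, function(f) seq_len(f$K))),
    stringsAsFactors = FALSE)
  C <- max(1L, as.integer(floor(n_fac / 8)))   # = floor(D*K/8)
  if (n_fac < 8) warning("pool_and_cluster: fewer than 8 factors; C = 1")
  if (C >= n_fac) C <- n_fac
  cm <- suppressWarnings(stats::cor(W_all))
  cm[!is.finite(cm)] <- 0
  dd <- stats::as.dist(1 - cm)
  hc <- stats::hclust(dd, method = "average")
  cl <- stats::cutree(hc, k = C)
  # per-factor peak pseudotime (argmax of its temporal signal)
  ks <- vapply(factorizations, function(f) f$K, integer(1))
  owner <- rep(seq_len(D), ks)
  within <- unlist(lapply(ks, seq_len))
  fac_peak <- vapply(seq_len(n_fac), function(j) {
    f <- factorizations[[owner[j]]]
    h <- f$H[within[j], ]
    mid <- f$interval_mid
    if (is.null(mid)) mid <- (seq_along(h) - 0.5) / length(h)
    mid[which.max(h)]
  }, numeric(1))
  loading <- vapply(seq_len(C), function(c)
    rowMeans(W_all[, cl == c, drop = FALSE]), numeric(nrow(W_all)))
  loading <- matrix(loading, nrow(W_all), C,
                    dimnames = list(rownames(W_all),
                                    sprintf("TRAV%d", seq_len(C))))
  module_size <- min(module_size, nrow(W_all))
  travs <- lapply(seq_len(C), function(c) {
    lv <- loading[, c]
    list(id = sprintf("TRAV%d", c),
         members = src[cl == c, , drop = FALSE],
         module = names(sort(lv, decreasing = TRUE))[seq_len(module_size)],
         peak_stage = stats::median(fac_peak[cl == c]))
  })
  structure(list(loading = loading, travs = travs, membership = cl, C = C),
            class = "trav_set")
}

#' TRAV activity per trajectory
#'
#' Activity(TRAV, trajectory) = maximum over the trajectory's factors of the
#' Pearson correlation between the TRAV's mean loading vector and the factor
#' loading vector; a TRAV is active in a trajectory if any of its factors
#' matches. Zero-variance vectors give activity 0.
#'
#' @param travset a \code{trav_set}.
#' @param factorizations list of \code{traj_factorization} on the same
#'   vocabulary.
#' @return matrix TRAVs x trajectories, bounded in \[-1, 1\].
#' @export
trav_activity <- function(travset, factorizations) {
  D <- length(factorizations)
  act <- matrix(0, travset$C, D)
  rownames(act) <- colnames(travset$loading)
  colnames(act) <- vapply(seq_len(D), function(i) {
    id <- factorizations[[i]]$trajectory_id
    if (is.null(id)) paste0("traj", i) else as.character(id)
  }, character(1))
  for (i in seq_len(D)) {
    W <- factorizations[[i]]$W
    cc <- suppressWarnings(stats::cor(travset$loading, W))
    cc[!is.finite(cc)] <- 0
    act[, i] <- apply(cc, 1, max)
  }
  act
}

#' Conserved TRAVs
#'
#' A TRAV is conserved when its activity exceeds \code{threshold} in
#' strictly more than \code{frac} of trajectories.
#'
#' @param activity TRAVs x trajectories matrix from
#'   \code{\link{trav_activity}}.
#' @param threshold activity threshold (default 0.4, strict >).
#' @param frac trajectory fraction (default 1/3, strict >).
#' @return character vector of conserved TRAV ids.
#' @export
conserved_travs <- function(activity, threshold = 0.4, frac = 1 / 3) {
  high <- rowMeans(activity > threshold)
  rownames(activity)[high > frac]
}

#' Covariate-associated TRAVs
#'
#' Per TRAV, fits activity ~ covariate with a random project intercept
#' (REML via lme4) when more than one project is present, otherwise plain
#' least squares; Wald p on the covariate coefficient (t reference with
#' n - 2 df), BH-adjusted across TRAVs.
#'
#' @param activity TRAVs x trajectories matrix.
#' @param covariate per-trajectory covariate (numeric, or factor with 2
#'   levels).
#' @param project per-trajectory project/batch id (random intercept).
#' @return data.frame \code{trav}, \code{effect}, \code{p}, \code{fdr}
#'   (NA rows where the fit was degenerate and skipped).
#' @export
covariate_travs <- function(activity, covariate,
                            project = rep("p1", ncol(activity))) {
  if (is.character(covariate)) covariate <- factor(covariate)
  if (is.factor(covariate) && nlevels(droplevels(covariate)) < 2)
    stop("covariate_travs: covariate needs >= 2 levels")
  x <- if (is.factor(covariate)) as.numeric(covariate) - 1
       else as.numeric(covariate)
  project <- factor(project)
  n <- ncol(activity)
  res <- lapply(seq_len(nrow(activity)), function(t) {
    a <- activity[t, ]
    if (stats::sd(a) == 0 || stats::sd(x) == 0)
      return(c(effect = NA_real_, p = NA_real_))
    eff <- se <- NULL
    if (nlevels(project) > 1) {
      fit <- tryCatch(
        suppressWarnings(suppressMessages(
          lme4::lmer(a ~ x + (1 | project), REML = TRUE))),
        error = function(e) NULL)
      if (!is.null(fit)) {
        co <- summary(fit)$coefficients
        if ("x" %in% rownames(co)) {
          eff <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
        }
      }
    }
    if (is.null(eff)) {
      fit <- stats::lm(a ~ x)
      co <- summary(fit)$coefficients
      if (!"x" %in% rownames(co))
        return(c(effect = NA_real_, p = NA_real_))
      eff <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
    }
    tval <- eff / se
    c(effect = eff, p = 2 * stats::pt(-abs(tval), df = n - 2))
  })
  out <- data.frame(trav = rownames(activity),
                    effect = vapply(res, `[[`, numeric(1), "effect"),
                    p = vapply(res, `[[`, numeric(1), "p"),
                    stringsAsFactors = FALSE)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Temporal profile of each TRAV
#'
#' In the trajectory with the highest activity for a TRAV, computes the
#' pseudotemporal attributes (correlation, peak bin, expression) of the
#' TRAV module's mean log-normalized expression via
#' \code{\link{gene_attributes}}.
#'
#' @param travset a \code{trav_set}.
#' @param activity activity matrix from \code{\link{trav_activity}}.
#' @param ct_list named list of per-trajectory \code{cell_table}s (names
#'   matching the activity columns).
#' @param n_bins attribute bins (default 10).
#' @return data.frame \code{trav}, \code{best_trajectory},
#'   \code{correlation}, \code{peak}, \code{expression}.
#' @export
trav_temporal_profile <- function(travset, activity, ct_list, n_bins = 10) {
  out <- lapply(seq_len(travset$C), function(t) {
    best <- colnames(activity)[which.max(activity[t, ])]
    ct <- ct_list[[best]]
    expr <- normalize_log_cpm(ct)
    mod <- intersect(travset$travs[[t]]$module, ct$var$gene_id)
    mexpr <- Matrix::rowMeans(expr[, match(mod, ct$var$gene_id),
                                   drop = FALSE])
    at <- gene_attributes(as.numeric(mexpr), ct$obs$pseudotime,
                          n_bins = n_bins)
    data.frame(trav = travset$travs[[t]]$id, best_trajectory = best,
               correlation = at$correlation, peak = at$peak,
               expression = at$expression, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Low-dimensional trajectory embedding
#'
#' Z-scores each attribute block (activity, expression, peak, correlation --
#' any matrices with one row per trajectory), weights blocks equally
#' (dividing by the square root of the block width), concatenates, and
#' embeds by PCA to 2 dimensions. Fully deterministic.
#'
#' @param blocks named list of matrices, rows = trajectories (same order).
#' @param n_pcs number of PCs retained before taking the first two as
#'   coordinates.
#' @return matrix (trajectories x 2) of embedding coordinates.
#' @export
embed_trajectories <- function(blocks, n_pcs = 10) {
  stopifnot(length(blocks) >= 1)
  n <- nrow(blocks[[1]])
  if (n < 3) stop("embed_trajectories: need >= 3 trajectories")
  zs <- lapply(blocks, function(b) {
    b <- as.matrix(b)
    mu <- colMeans(b); s <- apply(b, 2, stats::sd)
    s[s == 0 | !is.finite(s)] <- 1
    scale(b, center = mu, scale = s) / sqrt(ncol(b))
  })
  x <- do.call(cbind, zs)
  pcs <- pca_embed(x, n_pcs = min(n_pcs, n - 1, ncol(x)))
  coords <- pcs[, 1:2, drop = FALSE]
  colnames(coords) <- c("dim1", "dim2")
  rownames(coords) <- rownames(blocks[[1]])
  coords
}

#' Full TRAVMap pipeline over a list of trajectories
#'
#' Convenience wrapper: shared HVG vocabulary on the pooled cells,
#' per-trajectory pseudotemporal matrices, per-trajectory NMF, pooled
#' clustering into TRAVs, and the activity matrix.
#'
#' @param ct_list named list of per-trajectory \code{cell_table}s.
#' @param K NMF rank per trajectory.
#' @param n_intervals pseudotime intervals.
#' @param n_hvg shared vocabulary size.
#' @param seed base seed (per-trajectory NMF seeds derive from it).
#' @param module_size TRAV module size.
#' @return list with \code{travset}, \code{activity},
#'   \code{factorizations}, \code{matrices}, \code{vocabulary}.
#' @export
fit_travmap <- function(ct_list, K = 15, n_intervals = 100, n_hvg = 2000,
                        seed = 1L, module_size = 100) {
  pooled_counts <- do.call(rbind, lapply(ct_list, function(ct) ct$counts))
  expr <- normalize_log_cpm(pooled_counts)
  colnames(expr) <- ct_list[[1]]$var$gene_id
  vocab <- ct_list[[1]]$var$gene_id[select_hvg(expr, n_top = n_hvg)]
  ids <- names(ct_list)
  if (is.null(ids)) ids <- sprintf("traj%d", seq_along(ct_list))
  mats <- lapply(seq_along(ct_list), function(i)
    build_traj_matrix(ct_list[[i]], n_intervals = n_intervals,
                      genes = vocab, trajectory_id = ids[i]))
  facs <- lapply(seq_along(mats), function(i)
    nmf_decompose(mats[[i]], K = K, seed = seed + i))
  travset <- pool_and_cluster(facs, module_size = module_size)
  act <- trav_activity(travset, facs)
  list(travset = travset, activity = act, factorizations = facs,
       matrices = mats, vocabulary = vocab)
}
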