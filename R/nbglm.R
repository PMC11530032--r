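# Negative-binomial GLM machinery for neighborhood-level differential tests.
#
# Model per feature (a neighborhood for abundance, a (gene, neighborhood)
# slab for expression): y_s ~ NB(mu_s, alpha), mu_s = theta_{g(s)} * L_s,
# i.e. a log-link GLM with a group indicator and log-offset log(L_s).
# Because the only covariate is the binary group, the ML means decompose
# into independent one-parameter fits per group, solved by Fisher scoring
# on eta = log(theta), vectorized across all features at once.
# Variance convention: var = mu + alpha * mu^2.

# Vectorized one-parameter NB mean fit.
# Y, L: features x samples matrices (columns = the samples being pooled);
# alpha: per-feature dispersion. Returns eta = log(theta).
nb_fit_eta <- function(Y, L, alpha, max_iter = 50L, tol = 1e-10) {
  ry <- rowSums(Y)
  rl <- rowSums(L)
  eta <- log((ry + 0.1) / pmax(rl, 1e-300))
  eta <- pmax(pmin(eta, 30), -30)
  active <- rl > 0
  for (it in seq_len(max_iter)) {
    mu <- exp(eta) * L
    w <- 1 + alpha * mu
    U <- rowSums((Y - mu) / w)         # score dLL/deta
    I <- rowSums(mu / w)               # expected information
    step <- ifelse(active & I > 1e-12, U / pmax(I, 1e-12), 0)
    step <- pmax(pmin(step, 5), -5)
    eta <- pmax(pmin(eta + step, 30), -30)
    if (max(abs(step)) < tol) break
  }
  eta[!active] <- -30
  eta
}

# Vectorized NB log-likelihood at mu = exp(eta) * L.
nb_ll <- function(Y, L, eta, alpha) {
  mu <- exp(eta) * L
  r <- 1 / pmax(alpha, 1e-10)
  keep <- L > 0
  term <- matrix(0, nrow(Y), ncol(Y))
  y <- Y[keep]; m <- mu[keep]; rr <- (r * matrix(1, nrow(Y), ncol(Y)))[keep]
  term[keep] <- lgamma(y + rr) - lgamma(rr) - lgamma(y + 1) +
    rr * log(rr / (rr + m)) + ifelse(y > 0, y * log(m / (rr + m)), 0)
  rowSums(term)
}

# Profile log-likelihood of the two-group model at a fixed dispersion.
nb_profile_ll <- function(Y, L, colsA, colsB, alpha) {
  etaA <- nb_fit_eta(Y[, colsA, drop = FALSE], L[, colsA, drop = FALSE],
                     alpha)
  etaB <- nb_fit_eta(Y[, colsB, drop = FALSE], L[, colsB, drop = FALSE],
                     alpha)
  nb_ll(Y[, colsA, drop = FALSE], L[, colsA, drop = FALSE], etaA, alpha) +
    nb_ll(Y[, colsB, drop = FALSE], L[, colsB, drop = FALSE], etaB, alpha)
}

#' Estimate NB dispersions with common-dispersion shrinkage
#'
#' Per-feature maximum-likelihood dispersion on a log-spaced grid (profile
#' likelihood of the two-group model), a common dispersion maximizing the
#' summed profile likelihood, and the working dispersion: a 50/50 average of
#' the two on the log scale.
#'
#' @param Y features x samples count matrix.
#' @param L features x samples matrix (or length-S vector) of offset scales
#'   (library sizes); zero entries are treated as unobserved.
#' @param group factor of length S with two levels.
#' @param grid dispersion candidates (default 1e-6 to 10, log-spaced).
#' @return list with \code{per_feature}, \code{common}, \code{shrunk}.
#' @export
estimate_dispersion <- function(Y, L, group,
                                grid = exp(seq(log(1e-6), log(10),
                                               length.out = 25))) {
  Y <- rbind(Y); L <- expand_lib(L, Y)
  group <- droplevels(factor(group))
  colsA <- which(group == levels(group)[1])
  colsB <- which(group == levels(group)[2])
  nf <- nrow(Y)
  ll <- matrix(-Inf, nf, length(grid))
  for (j in seq_along(grid))
    ll[, j] <- nb_profile_ll(Y, L, colsA, colsB, rep(grid[j], nf))
  best <- max.col(ll, ties.method = "first")
  per_feature <- grid[best]
  common <- grid[which.max(colSums(ll))]
  shrunk <- exp(0.5 * log(per_feature) + 0.5 * log(common))
  list(per_feature = per_feature, common = common, shrunk = shrunk)
}

expand_lib <- function(L, Y) {
  if (is.matrix(L)) L
  else matrix(L, nrow(Y), ncol(Y), byrow = TRUE)
}

#' Fit the two-group NB GLM across many features at once
#'
#' The vectorized engine behind \code{\link{nb_glm_test}},
#' \code{\link{run_da}} and \code{\link{run_de}}: per feature, group-wise NB
#' means with log-offsets, a likelihood-ratio chi-square test (df = 1),
#' log2 fold change (prior count 0.5 per group for finiteness) and fitted
#' counts per million.
#'
#' @param Y features x samples count matrix.
#' @param L features x samples offset-scale matrix or length-S vector.
#' @param group two-level factor over samples; the first level is the
#'   reference (logFC > 0 means higher in the second level).
#' @param alpha per-feature dispersion vector (recycled if length 1).
#' @return data.frame with columns \code{logFC}, \code{CPM},
#'   \code{cpm_ref}, \code{cpm_alt}, \code{p_value}, \code{flag}.
#' @export
nb_glm_fit <- function(Y, L, group, alpha) {
  Y <- rbind(Y); L <- expand_lib(L, Y)
  group <- droplevels(factor(group))
  if (nlevels(group) != 2)
    stop("nb_glm_fit: group must have exactly 2 levels")
  nf <- nrow(Y)
  alpha <- rep_len(pmax(alpha, 1e-8), nf)
  colsA <- which(group == levels(group)[1])
  colsB <- which(group == levels(group)[2])
  YA <- Y[, colsA, drop = FALSE]; LA <- L[, colsA, drop = FALSE]
  YB <- Y[, colsB, drop = FALSE]; LB <- L[, colsB, drop = FALSE]
  etaA <- nb_fit_eta(YA, LA, alpha)
  etaB <- nb_fit_eta(YB, LB, alpha)
  eta0 <- nb_fit_eta(Y, L, alpha)
  ll_full <- nb_ll(YA, LA, etaA, alpha) + nb_ll(YB, LB, etaB, alpha)
  ll_null <- nb_ll(Y, L, eta0, alpha)
  lrt <- pmax(0, 2 * (ll_full - ll_null))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  # moderated logFC: prior count 0.5 per group keeps all-zero groups finite
  thA <- (rowSums(YA) + 0.5) / pmax(rowSums(LA), 1e-300)
  thB <- (rowSums(YB) + 0.5) / pmax(rowSums(LB), 1e-300)
  logFC <- log2(thB / thA)
  cpmA <- exp(etaA) * 1e6
  cpmB <- exp(etaB) * 1e6
  nS <- ncol(Y)
  cpm <- (length(colsA) * cpmA + length(colsB) * cpmB) / nS
  # degenerate contracts
  zero_both <- rowSums(Y) == 0
  no_obs <- rowSums(LA > 0) == 0 | rowSums(LB > 0) == 0
  flag <- ifelse(zero_both, "all_zero", ifelse(no_obs, "singular", "ok"))
  bad <- zero_both | no_obs
  p[bad] <- 1; logFC[bad] <- 0
  data.frame(logFC = logFC, CPM = cpm, cpm_ref = cpmA, cpm_alt = cpmB,
             p_value = pmin(1, p), flag = flag, stringsAsFactors = FALSE)
}

#' Two-group NB GLM test for a single feature
#'
#' Negative binomial GLM with log link, binary group indicator and
#' log-offset. The dispersion is estimated by per-feature maximum likelihood
#' shrunk 50/50 (log scale) toward a common dispersion -- when a single
#' feature is tested in isolation the two coincide. The p-value is a
#' likelihood-ratio chi-square with one degree of freedom; \code{logFC} is
#' the log2 group effect (second level over first); \code{CPM} the fitted
#' grand-mean count per million of offset scale.
#'
#' @param counts_row integer vector of counts over samples.
#' @param group two-level factor over samples.
#' @param offsets log offset per sample (e.g. log total cells, log
#'   pseudobulk totals).
#' @param dispersion optional fixed dispersion; estimated when NULL.
#' @return list with \code{logFC}, \code{CPM}, \code{p_value},
#'   \code{dispersion}, \code{flag}.
#' @export
nb_glm_test <- function(counts_row, group, offsets, dispersion = NULL) {
  Y <- matrix(as.numeric(counts_row), 1)
  L <- matrix(exp(offsets), 1)
  group <- droplevels(factor(group))
  if (nlevels(group) != 2)
    stop("nb_glm_test: group must have exactly 2 levels")
  if (min(table(group[L[1, ] > 0])) < 2)
    warning("nb_glm_test: fewer than 2 samples with nonzero offset in a ",
            "group; test may be degenerate")
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(Y, L, group)$shrunk
  fit <- nb_glm_fit(Y, L, group, dispersion)
  list(logFC = fit$logFC, CPM = fit$CPM, p_value = fit$p_value,
       dispersion = dispersion, flag = fit$flag)
}
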