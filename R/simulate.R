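#' Run code under a local, seeded RNG
#'
#' Sets the seed for the duration of \code{expr} and restores the caller's
#' RNG state afterwards, so seeded package internals never perturb user code.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Stage-localized gene program
#'
#' A set of genes sharing a Gaussian temporal activation bump,
#' \code{amplitude * exp(-(t - t0)^2 / (2 width^2))}, added to the natural-log
#' mean of member genes in the samples where the program is active.
#'
#' @param genes integer gene indices (may overlap other programs).
#' @param t0 bump center in \[0,1\].
#' @param width bump width (Gaussian sd).
#' @param amplitude bump height on the natural-log scale, >= 0.
#' @param samples character vector of sample ids in which the program is
#'   active, or \code{NULL} for all samples.
#' @return a \code{gene_program} list.
#' @export
gene_program <- function(genes, t0, width = 0.12, amplitude = 2,
                         samples = NULL) {
  stopifnot(t0 >= 0, t0 <= 1, width > 0, amplitude >= 0)
  structure(list(genes = as.integer(genes), t0 = t0, width = width,
                 amplitude = amplitude, samples = samples),
            class = "gene_program")
}

#' Stage-specific differential-expression effect
#'
#' Adds \code{lfc} (log2 units) to the mean of \code{genes} in cells of the
#' \code{group} whose pseudotime falls in \code{[t_lo, t_hi]}.
#'
#' @param genes integer gene indices.
#' @param group group label receiving the effect.
#' @param t_lo,t_hi stage window, \code{t_lo < t_hi}, within \[0,1\].
#' @param lfc log2 fold change (signed).
#' @return a \code{de_effect} list.
#' @export
de_effect <- function(genes, group, t_lo = 0, t_hi = 1, lfc = 1.5) {
  stopifnot(t_lo < t_hi, t_lo >= 0, t_hi <= 1)
  structure(list(genes = as.integer(genes), group = as.character(group),
                 t_lo = t_lo, t_hi = t_hi, lfc = lfc),
            class = "de_effect")
}

#' Simulation configuration
#'
#' The stated world of the built-in trajectory generator: a two-group,
#' multi-sample, single-path differentiation trajectory with negative
#' binomial counts (variance = mu + mu^2 * dispersion), per-group Beta
#' pseudotime laws, shared stage-localized gene programs that make expression
#' informative about pseudotime, and optional planted group-specific
#' differential effects.
#'
#' Defaults are the package's toy scale: 2 groups x 4 samples x 500 cells x
#' 300 genes, dispersion 0.1, Beta(2,2) pseudotime, four shared programs of
#' 25 genes each tiling \[0,1\].
#'
#' @param n_samples_per_group samples per group.
#' @param groups group labels (first level is the reference of all
#'   differential tests).
#' @param n_cells_per_sample cells per sample.
#' @param n_genes number of genes.
#' @param library_size_lognormal \code{c(meanlog, sdlog)} of the per-cell
#'   library factor (multiplies all gene means; meanlog 0 = no scaling on
#'   average).
#' @param nb_dispersion NB dispersion alpha >= 0 (0 = Poisson limit).
#' @param pseudotime_law named list (one entry per group) of Beta
#'   \code{c(a, b)} parameters; a group-specific law is an abundance shift.
#' @param programs list of \code{\link{gene_program}}; \code{NULL} for the
#'   default four shared programs.
#' @param de_effects list of \code{\link{de_effect}} (default none).
#' @param baseline_log_mean \code{c(mean, sd)} of per-gene baseline
#'   natural-log mean counts.
#' @param seed integer seed; fixed seed implies identical output.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_samples_per_group = 4,
                       groups = c("A", "B"),
                       n_cells_per_sample = 500,
                       n_genes = 300,
                       library_size_lognormal = c(0, 0.3),
                       nb_dispersion = 0.1,
                       pseudotime_law = NULL,
                       programs = NULL,
                       de_effects = list(),
                       baseline_log_mean = c(log(0.5), 0.8),
                       seed = 1L) {
  stopifnot(n_samples_per_group >= 1, n_cells_per_sample >= 1,
            n_genes >= 1, nb_dispersion >= 0, length(groups) >= 1)
  if (is.null(pseudotime_law)) {
    pseudotime_law <- stats::setNames(
      rep(list(c(2, 2)), length(groups)), groups)
  }
  for (g in groups) {
    ab <- pseudotime_law[[g]]
    if (is.null(ab) || length(ab) != 2 || any(ab <= 0))
      stop("sim_config: pseudotime_law for group '", g,
           "' must be positive Beta c(a, b)")
    if (any(!is.finite(ab)) || all(ab > 1e6))
      stop("sim_config: degenerate Beta law for group '", g, "'")
  }
  if (is.null(programs)) {
    centers <- c(0.10, 0.37, 0.63, 0.90)
    per <- max(1L, min(25L, floor(n_genes / 4)))
    programs <- lapply(seq_along(centers), function(i)
      gene_program(((i - 1) * per + 1):(i * per), t0 = centers[i]))
  }
  structure(list(n_samples_per_group = n_samples_per_group,
                 groups = as.character(groups),
                 n_cells_per_sample = n_cells_per_sample,
                 n_genes = n_genes,
                 library_size_lognormal = library_size_lognormal,
                 nb_dispersion = nb_dispersion,
                 pseudotime_law = pseudotime_law,
                 programs = programs,
                 de_effects = de_effects,
                 baseline_log_mean = baseline_log_mean,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a multi-sample trajectory
#'
#' Draws per-cell pseudotime from the group's Beta law, forms the natural-log
#' mean as baseline + program bumps + applicable DE effects + log library
#' factor, and samples counts from NB(mean, dispersion). Truth tables
#' (per-gene DE truth, per-gene module membership) are attached as
#' attributes \code{de_truth} and \code{module_truth}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return a \code{cell_table} with obs columns \code{cell_id},
#'   \code{sample}, \code{group}, \code{pseudotime}, \code{mito_frac}.
#' @export
simulate_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, simulate_impl(cfg))
}

#' Simulate a matched null trajectory
#'
#' As \code{\link{simulate_trajectories}} with every group-dependent effect
#' forced to zero: all groups share the first group's pseudotime law, DE
#' effects are dropped, and programs are active in all samples. Group labels
#' are retained (pure relabeling), so any detected group difference is a
#' false positive.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return a \code{cell_table}.
#' @export
simulate_null_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  null_cfg <- cfg
  null_cfg$pseudotime_law <- stats::setNames(
    rep(list(cfg$pseudotime_law[[cfg$groups[1]]]), length(cfg$groups)),
    cfg$groups)
  null_cfg$de_effects <- list()
  null_cfg$programs <- lapply(cfg$programs, function(p) {
    p$samples <- NULL
    p
  })
  with_seed(cfg$seed, simulate_impl(null_cfg))
}

simulate_impl <- function(cfg) {
  n_s <- cfg$n_samples_per_group * length(cfg$groups)
  samples <- sprintf("s%02d", seq_len(n_s))
  grp_of_sample <- rep(cfg$groups, each = cfg$n_samples_per_group)
  n_cells <- n_s * cfg$n_cells_per_sample
  base <- stats::rnorm(cfg$n_genes, cfg$baseline_log_mean[1],
                       cfg$baseline_log_mean[2])

  sample_col <- rep(samples, each = cfg$n_cells_per_sample)
  group_col <- rep(grp_of_sample, each = cfg$n_cells_per_sample)
  pt <- numeric(n_cells)
  for (g in cfg$groups) {
    i <- group_col == g
    ab <- cfg$pseudotime_law[[g]]
    pt[i] <- stats::rbeta(sum(i), ab[1], ab[2])
  }
  libfac <- stats::rlnorm(n_cells, cfg$library_size_lognormal[1],
                          cfg$library_size_lognormal[2])

  # natural-log mean: cells x genes, built sparsely by effect blocks
  logmu <- matrix(rep(base, each = n_cells), n_cells, cfg$n_genes)
  for (p in cfg$programs) {
    bump <- p$amplitude * exp(-(pt - p$t0)^2 / (2 * p$width^2))
    rows <- if (is.null(p$samples)) seq_len(n_cells)
            else which(sample_col %in% p$samples)
    logmu[rows, p$genes] <- logmu[rows, p$genes] + bump[rows]
  }
  for (d in cfg$de_effects) {
    rows <- which(group_col == d$group & pt >= d$t_lo & pt <= d$t_hi)
    if (length(rows))
      logmu[rows, d$genes] <- logmu[rows, d$genes] + d$lfc * log(2)
  }
  mu <- exp(logmu) * libfac
  alpha <- cfg$nb_dispersion
  counts <- if (alpha <= 0) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = 1 / alpha)
  }
  counts <- matrix(counts, n_cells, cfg$n_genes)
  gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
  obs <- data.frame(cell_id = sprintf("c%06d", seq_len(n_cells)),
                    sample = sample_col, group = group_col,
                    pseudotime = pt, mito_frac = 0,
                    stringsAsFactors = FALSE)
  colnames(counts) <- gene_ids
  ct <- cell_table(Matrix::Matrix(counts, sparse = TRUE), obs,
                   data.frame(gene_id = gene_ids, stringsAsFactors = FALSE))
  de_truth <- if (length(cfg$de_effects)) do.call(rbind, lapply(
    seq_along(cfg$de_effects), function(i) {
      d <- cfg$de_effects[[i]]
      data.frame(gene_id = gene_ids[d$genes], effect = i, group = d$group,
                 t_lo = d$t_lo, t_hi = d$t_hi, lfc = d$lfc,
                 stringsAsFactors = FALSE)
    })) else data.frame(gene_id = character(), effect = integer(),
                        group = character(), t_lo = numeric(),
                        t_hi = numeric(), lfc = numeric())
  module_truth <- if (length(cfg$programs)) do.call(rbind, lapply(
    seq_along(cfg$programs), function(i) {
      p <- cfg$programs[[i]]
      data.frame(gene_id = gene_ids[p$genes], program = i, t0 = p$t0,
                 stringsAsFactors = FALSE)
    })) else data.frame(gene_id = character(), program = integer(),
                        t0 = numeric())
  attr(ct, "de_truth") <- de_truth
  attr(ct, "module_truth") <- module_truth
  ct
}
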