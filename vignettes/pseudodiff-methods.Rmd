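---
title: "Models and methods behind pseudodiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pseudodiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudodiff)
```

`pseudodiff` analyzes multi-sample single-cell differentiation data along a
pseudotime axis: where along the trajectory do two groups of samples differ
in cell abundance or gene expression, and which pseudotemporal gene modules
recur across trajectories. This vignette documents the statistical models,
the tunable parameters and their defaults, what the built-in simulator does
and does not emulate, the numerical choices, and known limitations.

## 1. Data model and preprocessing

The universal container is the `cell_table`: a sparse cells x genes matrix
of raw UMI counts with per-cell metadata (`sample`, per-sample `group`,
`pseudotime` in [0,1], `mito_frac`). Pseudotime is an *input*: the package
deliberately treats trajectory inference as an upstream step (any tool that
produces a [0,1] ordering works) and concentrates on what happens *along*
a given axis. QC follows the standard first-round rules — cells with fewer
than 300 detected genes or 800 counts or more than 20% mitochondrial counts
are dropped, then genes detected in fewer than 3 surviving cells — and
normalization is log1p of counts-per-10k (`normalize_log_cpm`). Highly
variable genes are ranked by the classical binned dispersion statistic
(variance/mean of log-normalized expression, z-scored within 20
equal-frequency mean bins). One property of that statistic worth knowing:
if a set of genes occupies a mean bin on its own, its members are z-scored
only against each other, so planted-variability simulations should spread
gene means.

## 2. Differential abundance and expression along pseudotime

### Neighborhoods

Cells are embedded by PCA (30 components by default) on log-normalized HVG
expression and covered by neighborhoods of a KNN graph: an index cell plus
its `k` nearest neighbors. Index cells are sampled (10% of cells by
default) and *refined* to the local medoid of the candidate's neighbor set,
which concentrates them in dense regions and deduplicates near-identical
candidates (ties broken toward the lowest cell id, making the procedure
deterministic given the seed). The KNN search is exact — at desk scale
there is no reason to accept the nondeterminism of approximate indexes.

Each neighborhood gets:

* a per-sample cell count (`count_cells`), forming the N x S matrix tested
  for differential abundance;
* a pseudotime position — the **median** member pseudotime. The projection
  statistic was an open choice; the median is robust to the handful of
  straggler cells that KNN neighborhoods pick up at trajectory ends;
* a spatial-FDR weight — the distance from the index cell to its k-th
  neighbor, a density-inverse proxy: in dense regions many overlapping
  neighborhoods test nearly the same cells, and down-weighting them keeps
  the FDR honest.

### The negative binomial test

Per feature (a neighborhood row for abundance; a (gene, neighborhood)
pseudobulk row for expression) the model is

  y_s ~ NB(mu_s, alpha),  log mu_s = beta_0 + beta_1 * group_s + log L_s,

with variance mu + alpha mu^2 and offsets L_s (total cells per sample for
abundance, total pseudobulk counts per neighborhood-sample for expression).
Because the only covariate is binary, the ML means decompose into two
one-parameter fits solved by Fisher scoring, vectorized across all features
at once. The dispersion is estimated per feature by profile maximum
likelihood on a log-spaced grid (1e-6 to 10, 25 points) and shrunk 50/50
*on the log scale* toward the common (all-feature) ML dispersion —
a deliberately simple stand-in for empirical-Bayes dispersion moderation
that keeps single-feature estimates from collapsing to 0 or exploding at
S = 8 samples. The test is a likelihood-ratio chi-square with one degree of
freedom. The reported `logFC` (log2, second group level over first) uses a
prior count of 0.5 per group so all-zero groups stay finite; `CPM` is the
fitted mean count per million units of offset. Degenerate rows (all zero,
or a group with no observed samples) return p = 1, logFC = 0 with a flag
rather than an error, because they routinely occur inside genome-wide
loops.

Samples with zero offset (no cells of that sample in the neighborhood)
contribute nothing to the score, the information, or the likelihood — they
are dropped implicitly rather than by bookkeeping.

### Spatial FDR

`spatial_fdr` is weighted Benjamini-Hochberg: order p ascending,
`fdr_j = min_{l >= j} p_l * sum(w) / cumsum(w)_l`, clipped at 1, returned in
input order. With unit weights it reduces *exactly* to classical BH (this
is asserted against `p.adjust` and an O(n^2) definitional oracle).

### The binomial interval test

Neighborhoods with spatial FDR strictly below `alpha` (0.05) are labeled
*Rejection*, the rest *Accept*. The pseudotime axis is divided into
`n_intervals` equal-width bins ([ (i-1)/n, i/n ), last bin closed; the same
convention everywhere a bin appears in the package) and each interval is
scored by the binomial CDF at `N_accept` out of `N_accept + N_rejection`
trials with success probability `lambda` — small p means more rejections
than the null tolerates.

`lambda` is the *null acceptance rate*: the sample-to-group assignment is
shuffled (`n_shuffles` = 5), the whole test pipeline re-run at fixed
dispersions (shuffling labels does not change counts, so re-estimating
dispersion would only add noise and cost), and lambda is the mean interval
acceptance fraction across shuffles. Two numerical guards:

* if the mean fraction is 0, lambda falls back to the *precision of the
  calculation*, `1 / ((N_accept + N_rejection) * n_shuffles)`;
* symmetrically, a mean fraction of 1 (the common case under a true null)
  is capped at `1 - 1/(N * n_shuffles)`. Without the cap, lambda = 1 makes
  the CDF degenerate (p = 0 as soon as one rejection occurs) and a single
  noisy neighborhood would dominate an interval. The cap is this package's
  own choice; the source method only defines the zero-side fallback.

Lambda is estimated per interval; the same estimate pooled over all
neighborhoods (`lambda_overall`) drives `p_overall`, the global
trajectory-association test. Interval p-values are BH-adjusted across
occupied intervals; empty intervals are reported as missing, never
interpolated.

### Effect summaries and pattern labels

`CPM_interval` is the per-group mean fitted CPM over the neighborhoods in
the interval; `DiffExpr_interval = mean(logFC * CPM)` is the signed,
expression-weighted effect plotted in stage heatmaps. Per-gene interval
profiles are condensed to a two-stage label: intervals before/after
pseudotime 0.5 form the early/late stage; a stage is called `0` when fewer
than 20% of its occupied intervals are significant (interval FDR < alpha),
otherwise `Up`/`Down` by the sign of mean DiffExpr over the significant
intervals. The thresholds (0.5 split, 0.2 minimum significant fraction) are
exposed; the split at half matches the early/late reading of the labels,
and 0.2 keeps single noisy intervals from flipping a stage. A k-means
(k = 8) over DiffExpr profiles (`cluster_patterns`) is provided for
figure-style clustering; the eight-cluster count mirrors common practice,
not a derived rule.

### Interval resolution at small scale

The binomial CDF at N trials cannot produce p below (1-lambda)^N, so an
interval needs enough neighborhoods for the test to resolve anything. With
the default 100 intervals that requires thousands of neighborhoods (the
regime the method was designed for). At this package's toy scale (~4,000
cells, ~400 neighborhoods) the test suites therefore run `n_intervals = 20`
and `k = 30` (larger neighborhoods also give per-gene pseudobulks usable
counts). These are analysis parameters, not new defaults — the package
defaults remain 100 intervals and k = 15.

## 3. TRAVMap: recurring pseudotemporal gene modules

Each trajectory (in practice: one sample's cells) is reduced to a genes x
intervals matrix of pooled CPM per occupied interval, restricted to a
shared HVG vocabulary, each row divided by its maximum. Row-scaling had to
preserve non-negativity (NMF input), ruling out z-scoring; max-scaling
keeps every gene's temporal shape on [0,1] without distorting zeros.
Trajectories occupying fewer than 5 intervals are rejected outright.

NMF uses multiplicative updates (Frobenius objective, seeded uniform
initialization, eps = 1e-12 in denominators). The objective is
non-increasing per iteration — asserted, not assumed — and iteration stops
at relative change < 1e-6 or 500 iterations. Loadings are L2-normalized
with the scale moved into the temporal signals. The rank (default K = 15)
can be chosen by masked cross-validation: hold out a fraction of entries,
fit mask-weighted NMF, pick the K minimizing held-out squared error over
several masks, ties to the smaller K.

All D x K loading vectors are pooled and clustered by average-linkage
hierarchical clustering on correlation distance, cut at `floor(D*K/8)`
clusters — the TRAVs. Clustering operates on gene loadings, not temporal
signals, because loadings live in the shared gene vocabulary while interval
masks differ per trajectory. Each TRAV is summarized by its mean loading,
its top-100-gene module, and a peak stage (median over member factors of
the argmax of their temporal signal). *Activity* of a TRAV in a trajectory
is the **maximum** correlation between the TRAV loading and the
trajectory's factor loadings — max, not mean, because a module is "active"
if any factor matches it; averaging against the trajectory's unrelated
factors would dilute every signal. Conserved TRAVs exceed activity 0.4 in
strictly more than one third of trajectories (both comparisons strict, and
tested at their boundaries). Covariate-associated TRAVs are found by
`activity ~ covariate` with a random project intercept (REML via lme4; the
Wald t is referred to a t distribution with n - 2 df; plain least squares
when only one project exists).

Trajectory embeddings z-score each attribute block (activity, expression,
peak, correlation), weight blocks equally (1/sqrt(block width)),
concatenate and project by PCA to two dimensions. A neighbor embedding
(UMAP/t-SNE) would be conventional here, but no implementation is available
in the offline toolchain; PCA is deterministic, needs no seed, and
separates trajectory families well enough to pass the silhouette check.
This is the one place the implementation substitutes a simpler projection
for the conventional one.

## 4. Trajectory features

*Gene attributes.* Three per (gene, trajectory): Pearson correlation of
per-cell expression with pseudotime; the peak — the equal-width bin (of 10)
with maximal mean expression, lowest index on ties; and expression — the
mean of the occupied bin means. Constant genes get correlation 0 with an
explicit flag. The implementation is asserted equal to a brute-force loop
oracle on random cases.

*Common pseudotime.* A gradient-boosted regression-tree ensemble maps
log-normalized expression of a shared feature set to pseudotime, so an axis
learned on a reference can be transferred to queries. No gradient-boosting
or even CART package exists in the offline environment, so the base
learner is a depth-limited greedy regression tree implemented in Rcpp,
wrapped by least-squares boosting (default 200 trees, learning rate 0.1,
depth 4, 80% row subsampling). Predictions are clipped to [0,1] and
min-max rescaled per query sample (monotone, so rank-based accuracy is
unaffected). Missing query features are imputed as zero with a reported
count; feature overlap below 50% warns, below 10% errors.

*Bin similarity and merging.* Trajectories are partitioned into 10
equal-width pseudotime bins. Two bins are compared by downsampling to equal
size and estimating the out-of-fold misclassification rate of a bagged
randomized-tree classifier (5-fold CV, 50 trees, sqrt-p features per tree)
on a PCA representation; indistinguishable bins misclassify at chance, so
similarity is the chance-normalized rate m/0.5 in [0,1]. The bin pair is
internally ordered canonically so similarity is exactly symmetric. Bins
with similarity at or above 0.75 are merged by union-find. The 0.75
threshold is this package's default, not an inherited constant: on the
chance-normalized scale it demands misclassification of at least 0.375 of
the 0.5 ceiling, i.e. the classifier must be closer to guessing than to
separating. It is exposed as a parameter.

## 5. The simulator: the stated world

`sim_config` defaults describe the toy world every suite runs in: 2 groups
x 4 samples x 500 cells x 300 genes; NB counts with variance
mu + alpha mu^2, alpha = 0.1; per-gene baseline log-means N(log 0.5, 0.8)
(moderately expressed suites raise this to N(log 1.5, 0.6) so neighborhood
pseudobulks carry counts); per-cell lognormal library factors (sd 0.3);
pseudotime Beta(2,2) per group unless a law is planted; four shared
Gaussian-bump programs of 25 genes tiling the axis (centers 0.10, 0.37,
0.63, 0.90, width 0.12, amplitude 2 on the natural-log scale), which make
expression informative about pseudotime — the property every downstream
step relies on. Abundance shifts are planted as per-group Beta laws
(Beta(2,2) vs Beta(3,1.5) is the canonical late shift), DE effects as
stage-windowed log2 fold changes for one group. `simulate_null_trajectories`
zeroes every group-dependent effect and keeps labels, so any detected group
difference is a false positive. Truth tables (module membership, DE
effects, true pseudotime) ride along as attributes.

What the simulator does *not* emulate — and therefore what a green test
does not establish — includes dropout/ambient contamination, batch effects,
doublets, multi-branch topologies, and pseudotime *estimation* error (true
pseudotime is handed to the pipeline). Type-I and power results transfer to
real data only to the extent those factors are handled upstream.

## 6. Numerical choices and degenerate inputs

* Fisher scoring on log-mean with steps clamped to ±5 and eta to ±30;
  convergence at step < 1e-10 or 50 iterations. All-zero groups land on the
  eta floor and the likelihood limit is exact for y = 0.
* Binomial CDF via `pbinom`; the acceptance suite pins it to a direct-sum
  oracle with exact binomial coefficients to 1e-12 for all totals <= 20 and
  to exact-rational spot values.
* NMF denominators carry eps = 1e-12; monotonicity is asserted to 1e-9.
* Equal-width bins are half-open with the last bin closed; pseudotime 0 is
  bin 1 and pseudotime 1 is bin n, everywhere.
* Ties: HVG ranking breaks ties by gene id; peak bins by lowest index;
  neighborhood refinement by lowest cell id; rank selection by smaller K.
* Every stochastic step takes an explicit seed, and seeded code restores
  the caller's RNG state (`with_seed`), so pipelines compose without
  clobbering user randomness.

## 7. Known limitations

* Single-path trajectories only; no branch-aware tests.
* The NB test is a deliberate simplification of quasi-likelihood empirical
  Bayes machinery; its guarantees here are its own calibration and power
  contracts (type-I <= 0.08 at nominal 0.05 on nulls, planted-effect
  recovery), not equivalence with any external tool.
* Interval resolution degrades gracefully but really does degrade below ~10
  neighborhoods per interval; scale `n_intervals` to your neighborhood
  count.
* The mixed-model covariate test uses a t reference with n - 2 df, adequate
  for dozens of trajectories but approximate for very few.
* Trajectory embedding is PCA, chosen for determinism and offline
  availability; with many trajectories a neighbor embedding may reveal
  finer structure.
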