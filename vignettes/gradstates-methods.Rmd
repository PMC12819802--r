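---
title: "Functional gradients and dynamic brain states: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional gradients and dynamic brain states: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradstates)
```

`gradstates` analyses parcellated resting-state BOLD time series along two
complementary axes: the *static hierarchy* of cortical connectivity
(functional gradients) and the *temporal dynamics* of connectivity
(recurring dFC states). This vignette explains the models behind each stage,
the tunable parameters and their defaults, what the synthetic cohort
generator does and does not emulate, and the numerical choices that were
genuinely open.

## Temporal cleaning

Cleaning operates at the parcel level, after any volume-space preprocessing
(slice timing, realignment, normalization, smoothing) has happened upstream;
the package deliberately does not reimplement those steps, and the synthetic
generator bypasses them entirely. The fixed order is:

1. **volume discard** — `discard_initial_volumes()`, default 10 volumes, the
   standard allowance for signal equilibration (a 240-volume run keeps 230);
2. **polynomial detrending** — least squares, linear by default with a
   quadratic option, per parcel;
3. **confound regression** — any user-supplied nuisance regressors
   (e.g. CSF signal); the confound interface is generic because no canonical
   confound set exists at parcel level;
4. **band-pass** — zero-phase (forward-backward) order-4 Butterworth,
   0.01-0.08 Hz by default, the conventional low-frequency BOLD band. The
   filter realization is a package choice: a zero-phase IIR filter has a
   testable magnitude response and introduces no phase shift, which the test
   suite verifies by periodogram (out-of-band tones attenuated by more than
   20 dB, in-band tones preserved within 3 dB, cross-correlation peak at lag
   zero).

Missing values are rejected rather than imputed: silent imputation distorts
correlation estimates, which are the substrate of everything downstream.

## Functional gradients

For each subject, connectivity profiles are Fisher-z Pearson correlations of
each unit (a parcel, or the parcels of one seven-network community) against
all parcels. The embedding pipeline is:

* **sparsification** — each profile row keeps its top 10 % of entries; this
  is the convention of the gradient-mapping literature (the affinity should
  reflect strong connections, not estimation noise);
* **cosine similarity**, negatives clipped to 0 so the affinity admits a
  Markov normalization, then symmetrization;
* **diffusion-map embedding** — anisotropic normalization
  `W' = D^-alpha W D^-alpha` with `alpha = 0.5` (balancing local and global
  geometry), row-normalization to a Markov matrix, eigendecomposition through
  the symmetric conjugate (so eigenvalues are exactly real), the trivial
  constant eigenvector dropped, and components left unscaled at diffusion
  time `t = 0`. Variance explained is reported as
  `lambda_i^2 / sum(lambda^2)` over the retained components — the quantity is
  not uniquely defined in the literature, so the definition is stated here
  and in `diffusion_embedding()`.
* **group template and alignment** — the template embeds the elementwise
  mean of the subject matrices; individual embeddings are aligned to it by
  orthogonal Procrustes (rotation/reflection only, no scaling), z-scored per
  component, and gradient 1 is oriented so the somatomotor mean score is
  negative. The orientation rule exists purely to make reports
  deterministic: eigenvectors have no intrinsic sign.

Gradient dispersion is computed both ways the phrase is used in the
field — within-network spread (sum of squared distances to the network
centroid) and between-network centroid distances — because the two measure
different things and either may be wanted.

No spatial smoothing is applied to gradients (`standardize_components()`
documents this); a smoothing kernel over parcels is not well defined without
geometry, and the package's unit of analysis is the parcel.

## Dynamic connectivity states

Sliding windows default to 50 timepoints with step 1 (about 100 s at
TR = 2 s), rectangular taper; `W = floor((T - L)/step) + 1` windows result,
e.g. 181 for a 230-volume series. Note that published window counts for this
design vary; the formula above is definitional and is what the package
reports. Each window's correlation matrix is Fisher-z transformed and its
upper triangle vectorized; per-edge variability is the sample standard
deviation of z across windows.

States are k-means centroids of the pooled window vectors across all
subjects of both groups (pooling is what lets states "recur across
subjects"; per-group clustering is available by passing per-group series
lists). The implementation uses k-means++ seeding, Lloyd iterations capped
at 300, 50 restarts by default keeping the lowest within-cluster SSE, and is
exactly reproducible under a seed. Cluster-number selection
(`cluster_quality_scan()`) fits each k in 2..20, computes the SSE curve
(anchored at the single-cluster SSE), the mean silhouette and the
Calinski-Harabasz index, and chooses the k with the best silhouette among
elbow candidates (positive second difference of SSE), ties broken by larger
CH then smaller k. A strict "argmax of the second difference" elbow is not
used on its own: under realistic estimation noise the k=1 to k=2 drop
dominates the curvature and the raw elbow collapses to 2.

Temporal metrics per subject: fractional occupancy (FO, fraction of
windows per state), mean dwell time (MDT, mean consecutive-run length, in
windows and seconds), and number of transitions (NT). MDT of an unvisited
state is missing data, not zero; FO = 0 is retained.

## Group inference and classification

Per-feature contrasts fit `feature ~ group + covariates` by least squares —
with an empty covariate set this is algebraically the pooled two-sample t
test, and the suite asserts that equivalence to 1e-6. Multiplicity control
is Benjamini-Hochberg FDR (optionally within networks, via `fdr_bh(by = )`)
and, for family-wise control, a max-statistic permutation test
(Freedman-Lane residualization, corrected
`p = (1 + #(null max >= observed))/(n_perm + 1)`). Random-field cluster
correction is deliberately absent: the package's features are parcels, not
smooth voxel lattices, so the permutation test provides the family-wise
guarantee instead. Clinical correlations use Pearson or Spearman; the
`"auto"` rule screens both variables with Shapiro-Wilk (p < 0.05 sends the
pair to Spearman) and reports which method was used.

Classification is a linear SVM under leave-one-out cross-validation
(cost 1 by default; the constant is a package choice). Standardization
happens inside each training fold only — the suite plants a held-out
outlier and asserts the fold statistics exclude it. The ROC is built from
the pooled held-out decision scores and the AUC uses the rank
(Mann-Whitney) formulation with midrank ties. Class imbalance is not
reweighted by default.

## The synthetic cohort generator

`simulate_cohort()` is the package's testbed: it plants exactly the
structure the analyses assume, with analytic ground truth.

* **Hierarchy.** A latent axis `g` spans [-1, 1] across parcels; the base
  correlation kernel decays as `exp(-|g_p - g_q| / 0.8)`. The seven
  networks occupy contiguous spans of the axis. The within-network block
  boost defaults to 0: prototyping showed that a boost of 0.15 or more
  masks the planted hierarchy even at the population level (the first
  gradient then separates blocks instead of tracking the axis), so network
  structure is carried by the kernel itself.
* **States.** Each of K states scales the kernel by a coupling strength
  `b_s` (0.25 to 0.5 across states by default) and modulates it with a
  smooth harmonic field `1 + a f_s(g_p) f_s(g_q)`,
  `f_s(g) = cos(pi s (g+1)/2)`, `a = 1`. Every state therefore remains
  smooth in the axis (gradients survive state mixing) while states are
  strongly separated as window-level patterns. Covariances are floored to
  PSD at eigenvalue 1e-8, needed because clipping and modulation can
  introduce tiny negative eigenvalues.
* **Switching.** States switch on an epoch grid (10 timepoints) following
  group-specific row-stochastic transition matrices; the default is a
  sticky chain with uniform stationary occupancy and self-transition 0.95
  (mean dwell 200 timepoints, i.e. four 50-TR windows), so that dwell
  structure survives windowing — 50-TR windows cannot resolve per-TR
  switching. `sticky_transition_matrix()` constructs reversible chains with
  any target stationary distribution, and `analytic_expectations()` returns
  the exact occupancy and `1/(1 - p_ss)` dwell for recovery tests.
* **Observation model.** Timepoints are zero-mean multivariate normal draws
  from the active state's covariance, AR(1)-smoothed (0.3) and corrupted
  with white noise (sd 0.1). Defaults: 60 parcels, 240 timepoints at
  TR = 2 s, K = 4 states, 20 subjects per group.
* **Group effects.** Group-B targets are re-wired toward the opposite end
  of the axis (each target's covariance rows mixed with those of its
  axis-mirrored parcel). Gradient scores are emergent, so planted offsets
  are validated empirically in tests rather than assumed exact. Clinical
  covariates are linear in a planted per-subject feature plus noise; age
  and sex are generated independently of group (a matched design) unless
  the user wires them otherwise.

What the generator does **not** emulate: hemodynamics (no HRF convolution),
scanner physics, motion, voxel geometry, spatial autocorrelation beyond the
axis kernel, and non-Gaussian BOLD marginals. Passing recovery tests on this
cohort therefore demonstrates that the pipeline's machinery is correct and
calibrated — not that real acquisitions satisfy its assumptions.

## Problem sizes and study designs used by the test suite

The suite exercises the pipeline at desk scale, with sizes chosen once:

* gradient recovery: 100 parcels, 20 subjects, 230 analyzed volumes; the
  check runs on the full template-plus-Procrustes pipeline, since that is
  how individual gradients are produced; aligned gradient 1 correlates with
  the planted axis at |Spearman| >= 0.9 in at least 18 of 20 subjects.
* state-label recovery: the default cohort (60 parcels, 20 subjects,
  K = 4), 50-TR windows at step 1; adjusted Rand index against the modal
  window truth >= 0.9. Windows that straddle a state transition are the
  irreducible disagreement source: the pure-window ARI is 1.0 in
  prototyping.
* cluster-number selection: planted K in {3, 4, 5} over 20 seeded cohorts
  with *equal-strength* states (`base_strength = c(0.4, 0.4)`), slow
  switching (self-transition 0.99) and 100-TR windows. With the default
  graded strengths the states lie along a coupling-strength continuum and
  internal validity indices legitimately prefer k = 2 — a real property of
  such data, not an implementation flaw; equal-strength states give the
  near-equidistant geometry under which "how many states" is a well-posed
  question for silhouette-type indices.
* chain metrics: FO from a single 5000-step chain (within 0.03 of the
  stationary distribution); MDT pooled over five 5000-step chains, because
  dwell lengths are geometric (sd of order the mean) and a single chain
  only pins the mean dwell to ~6 % at self-transition 0.95.
* statistical calibration: BH at m = 100 over 200 null replicates
  (empirical FDR <= 0.06); permutation FWER over 200 replicates of 20 null
  features, 199 permutations each; power for a planted 0.10 occupancy
  shift through the full simulate -> window -> cluster -> contrast path in
  25 cohorts of 20 + 20 subjects (detection in at least 80 %).

## Known limitations

* The per-network embedding mirrors the voxel-within-network design of
  gradient studies but at parcel resolution; voxelwise embedding of real
  volumes is out of scope.
* Internal cluster-validity indices cannot recover K when states form a
  graded continuum (see above); reporting the full scan
  (`autoplot()` on the scan object) matters more than the single chosen k.
* MDT comparisons between groups exclude subjects who never visit a state
  (missing, pairwise); with very sticky chains and short runs this loses
  subjects, and FO is then the better-powered metric.
* The permutation test permutes residualized group labels (Freedman-Lane);
  with strong covariate-group confounding its null is approximate, as for
  all permutation schemes under nuisance parameters.
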