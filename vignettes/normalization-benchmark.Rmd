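---
title: "Methods: comparing normalization strategies for one-color miRNA profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing normalization strategies for one-color miRNA profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

MicroRNA expression is routinely profiled on one-color hybridization arrays
(log2 intensities) and RT-qPCR cards (Cq values). Both carry systematic
technical variation — per-sample additive shifts, smooth intensity-dependent
distortion on arrays, higher replicate noise on qPCR — that must be removed
before differential-expression calling, yet the usual mRNA normalization
assumptions (few differential features, symmetric regulation) are strained
for miRNA panels, where a quarter or more of expressed miRNAs can respond to
a treatment. `mirnorm` implements seven normalization strategies used in
this setting and the metrics by which their intra- and inter-platform
performance is compared, together with a synthetic two-platform study
generator that provides ground truth for all of it.

The reference design throughout is a muscle-cell experiment: myoblasts
(`MB`), differentiated myotubes (`MT`) and TNF-alpha-treated myotubes
(`MT_TNF`), each in biological triplicate, profiled in human and mouse on
both platforms. The two contrasts of interest are differentiation
(`MB -> MT`) and cytokine response (`MT -> MT_TNF`).

## Data model and orientation

An `ExpressionMatrix` holds miRNAs x samples on a declared scale. Cq values
behave like negated log2 abundances, so before normalization all qPCR data
are re-oriented as `e = C - Cq` with a fixed `C = 40` (the usual cycle
ceiling): one order-reversing bijection, recorded so fold-change reporting
can invert it. This gives a single code path for both platforms; every
method below operates on "higher = more expressed" log-like values.

Detection filtering retains a miRNA if it is seen in at least two replicates
of *at least one* group (array: signal > 0; qPCR: Cq < 35 for human, < 32
for mouse — the vendor-recommended quality criteria). Requiring one group
rather than all groups preserves condition-specific miRNAs (a miRNA switched
on only in myotubes must survive filtering to be testable). Undetected wells
in retained rows are imputed at the platform's detection bound and flagged;
flagged cells are excluded from smoother fits but participate in quantile
ranking, so no retained row is ever dropped silently.

## The seven normalization strategies

* **RGI** (reference gene index): subtract, per sample, the arithmetic mean
  of two stably expressed miRNAs, chosen by geNorm stepwise exclusion
  (NormFinder scoring is also provided). The grand mean of the index is
  added back so values stay on the input scale. Corrects only global
  additive (on log scale: multiplicative) effects.
* **geomean**: shift every sample to the grand mean of all cells — the
  global geometric mean on raw scale equals the arithmetic mean on log
  scale. Same correction class as RGI but uses all expressed miRNAs.
* **quantile**: classic order-statistic substitution; after normalization
  all columns share one empirical distribution exactly. Ties receive the
  mean of their rank positions. Assumes the overall signal distribution is
  condition-independent.
* **INV** (rank-invariant selection): build a reference pseudo-array
  (row-wise medians), select miRNAs whose rank spread across samples is
  below `rank_tolerance` (default 0.15 of the row count) while spanning at
  least 3 of 10 equal-count intensity bins, then map each sample through a
  loess curve fitted on the invariant set (span 0.5). Appropriate even when
  many miRNAs are differential, since it only assumes an unchanging
  subpopulation. The selection thresholds are declared defaults chosen to
  yield non-empty sets on ~300-row matrices, and are exposed as arguments.
* **loess** (cyclic pairwise): for each column pair, fit `M = x_j - x_k`
  on `A = (x_j + x_k)/2` with a robust local-linear smoother (span 2/3,
  fitted on a rank-stratified subset of 400 points, interpolated
  elsewhere), charge half the fitted trend to each column, average
  corrections over pairs, and cycle (default 3 cycles or until the largest
  adjustment < 1e-3). Removes smooth intensity-dependent bias without a
  baseline array.
* **loessM**: cyclic loess plus one global constant — the median of the
  accumulated loess adjustment — added back so normalized values stay
  bounded away from zero. Because the constant is a single additive shift,
  loessM and loess are *identical* under every shift-invariant downstream
  statistic (replicate SDs, d-statistics, t-values, AUC, DE lists); the
  package asserts this end to end. The choice of constant is therefore
  observationally neutral downstream, which is why the median of the
  adjustment field (rather than any other global summary) can be adopted
  without consequence.
* **GPA** (generalized Procrustes analysis): an assumption-free method
  adapted here to one-color data by treating each biological group's
  replicate columns as one configuration of points (rows = miRNAs,
  dimensions = replicates) and superimposing the group configurations by
  translation, isotropic scaling and rotation onto an iterated consensus.

## GPA details and design choices

Where the two-color original aligns red/green channel pairs, the one-color
adaptation must pick what a "configuration" is; we map each group's
replicates to one configuration, which mirrors the two-color case with
minimal reinterpretation (points = features, dimensions = channels) and is
isolated behind `normalize_gpa()` so other mappings could be swapped in.

Translation aligns each configuration's centroid to the *common* centroid
(not the origin) and isotropic scaling matches each configuration's
centroid size to the mean size, so the output remains on the input scale —
a rotation-only inner loop then alternates orthogonal Procrustes solutions
(SVD; reflections excluded unless requested) with consensus updates.
Translation and common-size scaling are fixed points of that iteration, so
applying them once up front leaves the alternating minimization property
intact: the residual sum of squares is non-increasing sweep by sweep, which
the tests assert. After superimposition a single global factor restores the
grand mean exactly. A pure multiplicative restoration is ill-posed for
zero-centred data, which is why configurations are recentred to the common
centroid first. Convergence is declared when the residual decrease falls
below `tol = 1e-10` (cap 1000 sweeps; a warning reports non-convergence and
the result at the cap).

With two configurations the procedure reduces to classical orthogonal
Procrustes; the tests verify the recovered relative rotation against the
closed-form SVD solution to 1e-8.

## Differential expression: SAM

The two-class statistic is `d_i = (mean2 - mean1) / (s_i + s0)` with `s_i`
the pooled standard error and `s0` a fudge factor chosen Tusher-style:
candidates are the 0th-100th percentiles (step 5) of the `s` vector, and
the candidate minimizing the coefficient of variation of the median
absolute `d` across ten `s`-percentile windows is selected (ties to the
smallest candidate). The null distribution permutes group labels; at the
design's 3v3 replicate count only 20 distinct assignments exist and all are
enumerated, making the null exact and the result bit-reproducible. Larger
designs fall back to seeded draws capped at `n_perm`.

A miRNA is called at threshold Delta when its ordered `d` deviates from the
permutation-expected order statistic by more than Delta; the FDR at Delta
is the median permutation count of calls beyond the observed cut points
divided by the observed call count (no null-proportion correction — the
conservative choice). `select_significant()` returns the calls at the
smallest Delta achieving the target FDR, default 0.05, which is exposed in
every report because the threshold choice materially changes the
significant counts.

Fold changes follow the Livak delta-delta rule: `FC = 2^(-ddCq)` on Cq
scale, `2^(ddlog2)` on expression scale — exactly equal after the
orientation transform. t-values use the pooled-variance two-sample form,
consistent with SAM's pooled scatter.

## Evaluation metrics

* **Inter-replicate SD**: per-miRNA SD across a group's replicates
  (n - 1), averaged over miRNAs; summarised as the mean and SD over the
  group x species cells. Lower = less residual technical variation.
* **ROC/AUC**: scores are `|d|` by default (`|t|` is a drop-in); the AUC is
  the rank/Mann-Whitney estimator with ties counted 1/2. Truth on synthetic
  data is the generator's DE labels; on real data a truth rule must be
  supplied explicitly (there is no canonical gold standard, so the package
  refuses to invent one silently).
* **Jaccard concordance**: `|A n B| / |A u B|` over significant sets,
  averaged over contrast x species cells; method x method within one
  platform (intra) or across the two platforms (inter). Empty-vs-empty is
  defined as 1 with a flag so averages stay defined and the case remains
  auditable.
* **Compression**: OLS of one platform's log2 fold changes on the other's;
  slope < 1 reports fold-change compression. The companion t-value
  regression is returned alongside. Note that measurement noise in the
  regressor attenuates OLS slopes (errors-in-variables), so cross-platform
  slopes understate the generative compression factor; parameter-recovery
  checks therefore regress against the noise-free true effects.
* **Symmetry**: mean +/- SD of the delta-delta values per contrast and
  platform — the check that up- and down-regulation are balanced, which
  quantile and plain loess implicitly assume.

## The synthetic study generator

`simulate_study()` draws one latent log2 profile per miRNA (baselines
uniform on 6-14) and derives both platforms from it — the latent-variable
design is what makes inter-platform concordance measurable at all. Per
contrast, a `de_fraction = 0.2` subset (between the 26.3% and 13.0%
differential fractions measured on the two real platforms) receives effects
of magnitude uniform on 0.5-3 log2 units with Bernoulli(0.5) signs; effects
accumulate along the group sequence MB -> MT -> MT_TNF.

Array values add per-sample shifts (SD 0.5), a per-array smooth quadratic
distortion in latent intensity (coefficients uniform on +/-0.4 — low-order
by design, so cyclic loess can provably remove it), Gaussian noise
(SD 0.2), and fold-change compression: effects enter scaled by 0.45. qPCR
values are `Cq = 40 - latent` plus shifts and noise (SD 0.6, the noisier
platform), right-censored at Cq 35 with censored cells flagged. All
randomness flows from one integer seed; identical seeds give bit-identical
studies.

What the generator does *not* emulate: probe-sequence effects, saturation
at the high end, amplification-efficiency differences between assays,
correlated noise between miRNAs, and miRBase annotation drift beyond simple
species-prefix differences. Passing tests therefore demonstrate that the
methods behave as designed under the stated noise model, not that any
method is optimal for a particular real dataset.

## Problem sizes and numerical choices

The test suite and the acceptance script run at the study's natural desk
scale: 300 miRNAs (matching the ~302/282 retained on the real arrays),
3 groups x 3 replicates, both species; null-calibration experiments use
1000 miRNAs across 20-50 seeds, and property checks use 40-200 rows.
Degenerate inputs are handled explicitly rather than by accident: constant
M-vectors bypass the loess smoother (a zero-residual robust fit is
undefined), all-equal scatter vectors make `s0` unidentifiable and return
the smallest candidate with a warning, loess calibration curves extend flat
beyond the fitted range, and ties in geNorm's stepwise exclusion resolve to
the first index.

## Known limitations

* The SAM threshold policy (smallest Delta meeting the FDR target) is one
  of several defensible conventions; absolute significant counts depend on
  it, so concordance and AUC — which are threshold-robust — are the
  primary comparison metrics.
* NormFinder's sample-effect removal uses the candidate-panel column means;
  with few candidates a single aberrant gene perturbs all stabilities.
* GPA assumes equal replicate counts across groups (configurations must be
  superimposable) and complete rows.
* Cross-platform OLS slopes are attenuated by regressor noise; they order
  platforms correctly but are not unbiased estimates of generative
  compression.
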