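---
title: "Methods: contrast PLS, NPAIRS validation and subspace selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrast PLS, NPAIRS validation and subspace selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the model and its assumptions, what every tunable default
means and why it has the value it has, what the synthetic cohort
generator does and does not emulate, the numerical conventions, and the
limitations we know about.

## The model

Each scan is a masked parametric volume (for instance a PET
binding-potential map) flattened to a row of the data matrix
$\mathbf{X}$ (scans × voxels).  The design matrix $\mathbf{Y}$
(scans × 4) one-hot codes the four group × season cells, in the fixed
column order nonSAD-summer, nonSAD-winter, SAD-summer, SAD-winter.  Both
matrices are standardized columnwise (mean 0, sample SD 1 with
denominator $n-1$) and the cross-product
$\mathbf{E} = \mathbf{Y}^\top \mathbf{X}$ is decomposed by SVD,
$\mathbf{E} = \mathbf{U}\,\Delta\,\mathbf{V}^\top$.  A latent variable
(LV) is a pair of singular vectors: a design salience $\mathbf{u}_l$
(a contrast over the four cells) and a voxel salience $\mathbf{v}_l$
(a brain pattern).  The covariance fraction of LV $l$ is
$\delta_l^2 / \sum_m \delta_m^2$; squared singular values are the common
PLS convention, and the unsquared alternative
(`fit_pls(..., cov_mode = "linear")`) changes only this reported
fraction, never the decomposition.  A scan's expression of a pattern is its brain score, the
corresponding row of $\mathbf{X}_{\mathrm{std}}\mathbf{V}$.

Assumptions worth stating: effects are additive in image units and
shared across subjects within a cell; the design is balanced across
seasons within subject (each subject contributes exactly one summer and
one winter scan); voxels are isotropic and already in a common space
(this package performs no registration).

## NPAIRS split-half validation

Subjects — never individual scans — are randomly divided into two
halves, stratified by group so each half holds both groups and, since
every subject has both seasons, both seasons (matched sampling).  With
13 + 6 subjects the halves hold 7/6 or 6/7 and 3/3 subjects, i.e. 20/18
scans; exactly equal 19-scan halves are impossible at subject level, and
we accept the one-scan-pair imbalance rather than split a subject.

Each half is standardized with its own column statistics (the halves are
self-contained; a global-standardization variant would leak test
information into the training half).  PLS is fitted per half and three
metrics are recorded per split:

* $r_\mathrm{train,i}$ — Pearson correlation between the vectorized
  standardized $\mathbf{Y}_i$ and the vectorized projection
  $\mathbf{X}_i \mathbf{E}_i^\top$ (all four columns jointly);
* $r_\mathrm{test,i}$ — the same with the *other* half's data projected
  through $\mathbf{E}_i$;
* $r_\mathrm{spatial}$ — the correlation of the two halves' retained
  voxel saliences.

The joint-column ("matrix") correlation is the default because the
quantities being correlated are matrices; a per-LV variant
(`cor_mode = "perlv"`, correlating $\mathbf{Y}\mathbf{u}_l$ with
$\mathbf{X}\mathbf{v}_l$) is provided and reduces, on the degenerate
whole-data "split", to the correlation between design scores and brain
scores.

Three sign/identification conventions make these metrics well defined:

1. **Canonical LV sign.**  Within any fitted model the element of
   $\mathbf{u}_l$ largest in magnitude is made positive (flipping
   $\mathbf{v}_l$ with it), so output is deterministic across
   linear-algebra backends.
2. **LV tracking.**  The LV compared across halves is the one whose
   voxel salience correlates most strongly, in absolute value, with the
   full-data LV-1 salience (the reference pattern).  This guards against
   LV order swaps between halves.
3. **Sign alignment.**  Half-B's salience is negated when its inner
   product with half-A's is negative (SVD sign is arbitrary per half);
   the averaged pair — the split-map — is further aligned to the
   reference pattern, because the pair's *overall* sign is also
   arbitrary and averaging unaligned split-maps across splits would
   cancel.

Across `n_splits` splits (protocol default 1000), the per-voxel mean and
SD of the split-maps give the salience mean, its split-half standard
error, and the ratio Z-map (`Z-score_split`); voxels whose SE is exactly
zero are reported as missing rather than infinite.  The significance of
the pattern is empirical: $p = (1 + \#\{r \le 0\})/(1 + n)$ over the
pooled $r_\mathrm{test}$ values (two per split) and over
$r_\mathrm{spatial}$, one-sided against zero with add-one smoothing so
$p$ is never zero.

## Adaptive PC-subspace selection

Before the per-half PLS fit, each half can be reduced to its top-$k$
principal components (SVD of the standardized half; the back-projection
basis is orthonormal, so subspace saliences map to voxel space with
norms preserved).  The PC scores are deliberately *not* re-standardized:
rescaling them would distort the subspace geometry and break the exact
equivalence between full-rank-subspace PLS and PLS on the raw data,
which the test suite asserts to 1e-9.  PCA is computed per training
half — never globally — so no test information enters the subspace.

`select_optimal_k()` sweeps $k = 1 .. k_\mathrm{max}$ (default: the
smallest attainable half size minus one) on one *shared* split schedule,
so the per-$k$ curves differ only in $k$, and selects
$k^\* = \arg\min_k D(k)$ with
$D(k) = (1 - \bar r_\mathrm{spatial}(k))^2 + (1 - \bar r_\mathrm{test}(k))^2$.
$D$ is printed as a sum of squares; the text description "Euclidean
distance from (1, 1)" is its square root, and the argmin is identical
either way.  Ties break toward the smallest $k$ (parsimony).  A no-PCA
reference analysis runs on the same schedule for comparison, and the
robustness of the selected pattern is quantified by correlating each
$k$'s sign-aligned mean salience map with the $k^\*$ map.

## The synthetic cohort generator

The generator is first-class, tested code, not a fixture.  Scan volumes
are

$$\mathrm{vol}(s, g, \mathrm{season}) = \mathrm{baseline}
  + c(g, \mathrm{season})\cdot \mathrm{effect\_map}
  + \mathrm{offset}(s) + \varepsilon,$$

with default contrast weights $c(\mathrm{nonSAD, winter}) = +1$,
$c(\mathrm{SAD, winter}) = -1$ and both summers 0 — a seasonal
dissociation between groups.  The effect map is a sum of rasterized
spheres (a voxel belongs to a sphere iff its center is strictly within
the radius, in mm); the subject offset is a single scalar intercept
constant over the volume (the simplest model of whole-brain
inter-subject level differences — spatially varying random effects are
out of scope); $\varepsilon$ is i.i.d. Gaussian voxel noise.  One RNG
stream is seeded per cohort and all subject offsets are drawn before any
noise field, so adding noise realizations never changes the offsets.

Default study conditions, chosen once for realism on the BP_ND scale and
not revisited: a 16³ grid of 2 mm voxels; baseline 1.5 (a mid-range
[^11^C]DASB binding-potential level); two 6-mm-radius spheres of
opposite sign with effect size 0.25 (a strong but not dominant regional
seasonal change, ~17% of baseline); between-subject SD 0.15 (~10% of
baseline, typical between-subject spread); voxel noise SD 0.10 (PET
test–retest variability of roughly 5–10%); 13 + 6 subjects × 2 seasons
(38 scans).  Gray-matter probability is 1 inside a 7-voxel-radius
ellipsoid (1472 masked voxels) and CSF 0, so the default mask thresholds
(GM > 0.1, CSF < 0.3, both strict) keep the whole phantom brain.

What the phantom does *not* emulate: Poisson/reconstruction-dependent
PET noise, kinetic-model bias, anatomical structure, spatially
correlated noise, registration error.  Passing tests on this phantom
therefore demonstrates the statistical machinery — recovery of an
additive, spatially compact, rank-1 planted pattern under Gaussian noise
and subject intercepts — not robustness to the full messiness of real
parametric images.

## Reporting

The Z-map is thresholded at ±2.8 (two-sided normal tail
$p \approx 0.005$); positive and negative exceedance sets are labeled
separately by connected components (default 26-connectivity — the most
inclusive 3-D neighborhood and the common default in imaging software;
6 and 18 are available and recorded in output metadata), so clusters of
opposite sign can never merge.  Components smaller than 640 mm³ of
tissue are discarded — note the threshold is volume, not voxel count
(80 voxels at 2 mm, 640 at 1 mm).  Cluster peaks are the voxel of
maximum |z|, ties broken toward the lexicographically smallest
coordinate.  Coordinates are 1-based voxel indices; real-space reporting
requires an affine, taken from the NIfTI header when present.

Condition brain scores are centered by the grand mean over *all scans*;
the phrase "grand mean across conditions" could also mean the unweighted
mean of the four condition means, which differs under unequal group
sizes, so that convention is available as `center = "condition_means"`.
Percentile bootstrap CIs (default 1000 resamples, 95%) are computed by
resampling scans within each condition; BCa offers no practical benefit
at these condition sizes (6–13 scans).  The six condition contrasts use
paired t-tests within group (paired on subject) and pooled-variance
(Student) two-sample t-tests otherwise — pooled, not Welch, because the
package's summary-statistic t-test (`t_from_summary()`) is meant to
reproduce demographics-table p-values that match the pooled
recomputation.  The Bonferroni column multiplies by exactly 6 and is
deliberately not capped at 1, so corrected values above 1 remain visible
as raw multiples.

## Numerical choices

* Standardization uses the sample SD ($n-1$); zero-variance columns are
  set to zero rather than dropped, preserving voxel indexing so maps can
  always be scattered back into volumes.
* Smoothing uses a separable truncated Gaussian (half-width 4σ,
  renormalized) with reflective boundaries;
  $\sigma_\mathrm{voxels} = \mathrm{FWHM}/(2\sqrt{2\ln 2})/\mathrm{voxel\ size}$.
  FWHM 0 is the identity.  Anisotropic voxels raise an error instead of
  being silently resampled.  Smoothing defaults to off in the pipeline:
  the canonical protocol smooths dynamic images *before* kinetic
  modeling, a stage outside this package's scope; smoothing parametric
  volumes instead is offered as an option but is not assumed
  equivalent.
* SVD rank is truncated at $10^{-12}$ of the leading singular value;
  an all-zero cross-product is an error.
* The split schedule derives one child seed per split from the master
  seed, making runs bitwise reproducible (asserted in tests) and safely
  parallelizable in principle.
* In the subspace sweep the two half-SVDs are computed once per split
  and truncated at each $k$, which is exactly the computation
  `reduce_to_pcs()` performs, so sweep results and a direct
  `run_npairs(k = k_star)` rerun agree bitwise given the same schedule.

## Problem sizes

Desk-scale defaults keep every stage fast while leaving the protocol
intact: the subspace curve uses 200 shared splits and the final NPAIRS
run 500 (the function default remains the protocol's 1000; at the
default phantom size the full pipeline takes seconds either way).  The
calibration suite uses 100 null cohorts × 100 splits on an 8³ grid, and
recovery checks use the 16³ study-sized phantom with 200 splits.

## Known limitations

* **Calibration under subject random effects.**  The empirical
  split-half p-value for prediction is well calibrated when scans are
  exchangeable given the design (pure-noise null: the type-I rate over
  100 null cohorts sits inside the exact binomial 95% band of 0.05).
  When strong subject-level random intercepts are present, the
  within-cohort split distribution cannot represent cohort-level
  variance (a random group difference in intercepts looks identical in
  every split), and we measure type-I rates of 0.11–0.17 at the default
  intercept SD.  This is a property of the validation scheme, not of
  the implementation; p_test should be read accordingly in designs with
  large stable inter-subject level differences, and whole-volume
  normalization before analysis is a sensible mitigation on real data.
* **Prediction correlations are bounded below 1 by design.**  The
  joint-column r_test correlates a four-column indicator matrix with a
  rank-limited projection; even a perfectly recovered rank-1 contrast
  explains only part of that variance, so planted-cohort p_test is
  often non-significant while p_spatial is reliably significant.  The
  per-LV mode gives larger r values; the default follows the matrix
  formulation.
* **The k = 1 subspace can capture the intercept direction.**  With
  subject intercepts the data's structural rank is 2 (global level +
  planted pattern); at $k = 1$ the retained subspace is usually the
  global direction and the recovered pattern correlates poorly with the
  $k^\*$ pattern.  Robustness claims therefore apply from the
  structural rank upward.
* **Cohort-to-cohort variability is real.**  With 6 subjects in the
  smaller group, some simulated cohorts draw group-mean intercept
  differences large enough that LV 1 mixes a global level difference
  with the planted pattern (and the cluster table shows one large
  global cluster instead of the two planted spheres).  This mirrors the
  small-sample caveat of the design itself.
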