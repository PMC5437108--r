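---
title: "Mapping brain network measures to single-case behavior: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping brain network measures to single-case behavior: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netbeh)
```

## The analysis problem

Semantic dementia (SD) produces selective loss of conceptual knowledge
together with progressive, focal gray-matter atrophy. A natural question is
which *network* property of the atrophic territory — a region's functional
degree centrality, the strength of specific functional connections, or the
integrity of a white-matter tract — tracks the severity of each patient's
semantic deficit. `netbeh` implements that mapping as a tested pipeline:

1. **Behavior.** Each patient observation's raw task score is standardized
   against a healthy control sample with the Crawford–Howell single-case
   statistic, $t = (x - \bar{m}) / \left(s\sqrt{(n+1)/n}\right)$ with
   $df = n - 1$; the three semantic tasks are z-transformed across patient
   observations and averaged into a semantic composite, which is the
   behavioral outcome everywhere downstream.
2. **Atrophic network.** A voxel-wise two-sample $t$ contrast of smoothed
   gray-matter volume (patients vs. controls), thresholded at voxel
   $p < .05$ with a Monte-Carlo (AlphaSim-style) cluster-extent correction
   at $\alpha = .05$. Surviving clusters form the atrophic-network mask and
   every functional analysis is restricted to it.
3. **Disconnected region.** Within the mask, every voxel pair's Pearson
   correlation is computed from preprocessed BOLD (discard 10 frames,
   motion exclusion at >2.5 mm / >2.5°, 4 mm FWHM smoothing, linear detrend,
   0.01–0.10 Hz band-pass, nuisance regression). Connections with
   $r > 0.10$ count toward a voxel's degree; per-subject degree maps are
   z-standardized and contrasted between groups with the same cluster
   correction. A 3 mm-radius spherical seed is placed at the contrast peak,
   and the seed's mean z-degree is correlated with the composite.
4. **Semantic connections.** The seed's Fisher-z connectivity map (seed mean
   time series vs. every remaining mask voxel) is correlated with the
   composite per voxel; clusters surviving voxel $p < .05$ with corrected
   $\alpha = .001$ are the candidate semantic connections. Each cluster's
   correlation is re-estimated partialling out, singly and jointly: total
   gray-matter volume, seed gray-matter volume, seed mfALFF, and the
   observation index (1/2/3), and on the first-observation subset.
   Specificity is checked against two non-semantic scores.
5. **Structural basis.** Diffusion tensors are fitted voxel-wise by
   log-linear least squares; deterministic FACT tractography (100 random
   seeds per voxel, 45° turning limit, FA ≥ 0.15) is run in each control
   from the disconnected region toward each semantic cluster. Voxels
   traversed in more than 3 of the 18 controls form the group tract; its
   mean FA and mean LDH (local diffusion homogeneity, Kendall's W of the
   raw diffusion-weighted series over the 27-voxel neighborhood) are
   compared between groups and correlated with the composite.

The original patient scans are not public, so the quantitative claims this
package can test are *property-based*: a synthetic cohort with planted,
recoverable ground truth.

## The synthetic world

`synthetic_config()` fixes a 20×20×14 grid of 3 mm voxels shared by all
subjects (a desk-scale stand-in for a normalized common space; spatial
normalization itself is out of scope). The cohort mirrors the study design:
17 patients, three of them re-observed (two twice, one three times) for 21
observations, and 18 controls. Each patient carries a latent severity
$s \in [0,1]$ (first observations uniform on [0.2, 0.8]; repeats drift
upward by 0.1, emulating progression and motivating the observation-index
covariate). Controls have $s = 0$.

Planted effects, each behind a single coupling coefficient:

- **Atrophy** (`beta_gmv = 0.35`): gray-matter volume inside a box-shaped
  atrophic region is reduced by `beta_gmv * s` against a smooth anatomical
  baseline plus voxel noise (sd 0.08).
- **Hub disconnection** (`beta_fc = 1`): a shared band-limited
  (0.01–0.08 Hz) latent signal drives a hub and two target regions inside
  the atrophic territory. The hub's loading is `1 - beta_fc * s`; the
  targets keep full loading. BOLD noise sd is 2, so the full-loading
  between-region correlation is ≈ 0.4 after band-passing and falls through
  the 0.10 degree threshold as severity grows — hub degree and seed–target
  connectivity both decline with severity, which is exactly the structure
  the pipeline is supposed to find.
- **Behavior** (`beta_behavior`): semantic task scores decline linearly in
  $s$ with task-scale intercepts and noise chosen to resemble the published
  score ranges; the two non-semantic tasks have slope 0 by construction, so
  specificity tests have a true null.
- **Tract degradation** (`beta_tract = 4e-4` mm²/s): an anisotropic path
  (principal eigenvalue 1.7×10⁻³, radial 3×10⁻⁴ mm²/s, oriented +x)
  connects hub to first target; severity subtracts from the principal
  eigenvalue, lowering FA. Elsewhere diffusion is isotropic
  (0.7×10⁻³ mm²/s), so FA < 0.15 stops streamlines leaving the path. DWI
  uses 40 spherical-Fibonacci directions at b = 1000 s/mm² plus one b0,
  Gaussian noise by default (Rician optional).

No effect size is reported for the real cohort, so these defaults are the
package's own stated world: chosen once so planted effects are detectable
at n ≈ 21 vs 18 and exposed in the configuration, not claimed as the
study's values.

What the generator does **not** emulate: anatomy, registration error,
physiological noise spectra, susceptibility artifacts, motion beyond
summary parameters, and tissue compartments (there is no white matter/CSF,
so nuisance regression uses the six motion series; the confound hook
accepts arbitrary columns). A green parameter-recovery test therefore
establishes that the pipeline's statistics recover the planted generative
structure at realistic n and noise — not that it would reproduce any
particular clinical dataset.

Two practical notes. BOLD series are materialized lazily
(`cohort_bold()`) from stored per-observation sub-seeds: a fully
materialized default cohort would occupy gigabytes; determinism (same
seed, identical data) is preserved and tested. And the functional ROIs
(hub, targets) are deliberately *inside* the atrophic region, with the
hub/targets/tract mutually disjoint — the downstream analyses are all
restricted to the atrophic mask, so a hub outside it would be
unrecoverable by construction.

## Numerical choices

- **Smoothing** is a separable Gaussian with
  $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$ per axis, truncated at
  4σ and row-renormalized so constants are preserved at boundaries.
- **Band-pass** is a hard frequency mask on the FFT after linear
  detrending (inclusive band edges). This matches common resting-state
  toolchains and is exactly testable; it is not an FIR/Butterworth filter.
- **mfALFF** is computed on smoothed, unfiltered series (band-passing first
  would make the in-band/total amplitude ratio degenerate); the map is
  divided by its within-mask mean.
- **Smoothness estimation** uses the classic first-difference estimator
  $\mathrm{FWHM}_d = v_d^{\mathrm{size}}\sqrt{-2\ln 2 / \ln(1 - v_d/2v)}$
  pooled over residual volumes. On truly independent (white) fields the
  lag-one correlation estimate sits near zero and the estimator returns
  unstable sub-voxel values or an unresolvable flag — that is a property of
  the estimator, not a bug — so the pipeline clamps estimates below voxel
  size up to voxel size (conservative for cluster inference) and logs it.
- **AlphaSim** simulates iid Gaussian fields, smooths them to the estimated
  FWHM, re-standardizes within the mask, thresholds two-sided at the voxel
  p, and records the maximum cluster per iteration (default 1000,
  26-connectivity, seeded). The minimum cluster size is the smallest $k$
  with empirical $P(\max \ge k) \le \alpha$. Iterations are simulated in
  batches through one separable-smoothing matrix multiply; per-iteration
  semantics are unchanged. The published cluster thresholds (301/103/189
  voxels) depend on the original data's estimated smoothness and are not
  reproduction targets.
- **Degree** counts strict $r > 0.10$ (binary), following the "total
  number" reading; a weighted variant (sum of suprathreshold r) is exposed
  because degree is sometimes defined by number *and/or* strength.
  Constant/degenerate voxels are flagged NA and excluded rather than
  zero-filled.
- **Seeds** use center-to-center distance with an inclusive boundary on a
  0-based voxel-to-mm affine; the seed time series is the unweighted mean
  over seed voxels. On a 3 mm isotropic grid a 3 mm seed is the center
  voxel plus its six face neighbors, intersected with the mask.
- **FACT** steps voxel-boundary-to-voxel-boundary along the per-voxel
  principal eigenvector, launched bidirectionally (±e1), re-orienting each
  entered voxel with the sign that minimizes turning. Stopping is strict:
  FA < 0.15, turning angle > 45°, grid exit, or a near-degenerate tensor
  (λ1 ≈ λ2, flagged unreliable). The terminal voxel stays in the visited
  set — a streamline *terminating in* the target region counts as reaching
  it. All streamlines are propagated simultaneously (vectorized), with
  per-streamline semantics identical to one-at-a-time stepping.
- **Fisher z** is used for the "standardized FC" (the plausible alternative,
  across-voxel standardization, is available via `z_standardize()` but is
  not the default reading).
- **Classification cutoff**: impaired strictly below −1.96, spared strictly
  above, indeterminate exactly at the cutoff — the dichotomy the diagnostic
  rules use.
- **Group tests**: the published behavioral table mixes forms — only Welch
  reproduces six rows and only the pooled form reproduces the episodic
  memory row — so the pipeline computes and reports both for every row.
- **Partial correlations** residualize both variables on an intercept plus
  covariates by least squares ($df = n - 2 - q$). Degenerate partials
  (e.g. a covariate identical to the scores) are flagged NA in tables
  rather than aborting.

## Open design points, resolved

- *Observations as units.* Repeated observations are treated as independent
  units in the correlations (as in the source design), with the observation
  index available as a covariate and a first-observations-only subset
  reported; every analysis records its n.
- *Null calibration needs a mask.* With all couplings zero there is no
  atrophy to detect, and the pipeline correctly aborts at the empty-mask
  gate. `pipeline_config(atrophy_mask_override=)` supplies the planted
  geometry so the *behavior-association* stages can be audited under the
  null; in that regime the pipeline almost never reports a significant
  association because the degree-contrast gate itself is FWER-controlled.
- *Strong covariates in a one-factor world.* Severity is the only latent
  variable, so total gray-matter volume is itself strongly coupled to the
  composite; partialling it out removes real shared variance and can
  shrink the FC–behavior correlation far more than in the richer real
  data. The validation table reports this honestly rather than emulating
  the published partial-r stability.
- *LDH neighborhood rule.* Kendall's W needs at least two series; voxels
  whose 27-neighborhood holds fewer than two in-mask voxels are NA.
  Weighted-only series are used (b0 excluded), with an option to include
  b0 volumes.

## Limitations

Single common space (no registration), box-shaped ROIs, one latent
severity factor, Gaussian DWI noise by default, and a Monte-Carlo
correction that assumes stationary Gaussian smoothness. The acceptance
suite scales some checks to a desk-size budget (scaled-down cohorts for
the determinism test; stage subsets where later stages are not under
test); every scaling is stated next to the test it affects.
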