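---
title: "Harmonizing diffusion MRI across scanners with RISH features and voxel-wise linear models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing diffusion MRI across scanners with RISH features and voxel-wise linear models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rishglm)
```

## The model

A single diffusion shell — the volumes acquired at one b-value — is a
sampling of a smooth, antipodally symmetric function on the sphere at each
voxel. `rishglm` represents it in the real, even-order spherical harmonic
(SH) basis: with directions $g_1,\dots,g_N$ and basis matrix $B$ the
per-voxel coefficients solve the L2-regularized least-squares problem

$$\hat c = (B^\top B + \lambda R)^{-1} B^\top s,$$

where $R$ is either the identity or the Laplace–Beltrami penalty
$\mathrm{diag}\,l^2(l+1)^2$. For each even order $l$ the rotational
invariant (RISH) feature is the energy $L_l = \sum_m c_{l,m}^2$, which does
not depend on head orientation or on the sign/ordering convention of the
basis.

Scanner harmonization rests on one assumption: after preprocessing and
spatial normalization, cross-site differences in the *expected* RISH
features at a voxel are scanner-induced, multiplicative per order, and
smooth functions of space. Training subjects from a reference and a target
site yield voxel-wise scaling maps $\vartheta_l$; a new target-site subject
is harmonized by fitting SH, multiplying order-$l$ coefficients by
$\sqrt{\vartheta_l}$ (so the feature is multiplied by $\vartheta_l$
exactly), and reconstructing the signal at the subject's own directions.

Two estimators of $\vartheta_l$ are provided:

* **mean ratio** (`method = "means"`): $\vartheta_l = \bar
  L_{l,\mathrm{ref}} / \bar L_{l,\mathrm{target}}$ over the training
  subjects. Valid only when the groups are matched on everything that
  affects the signal.
* **voxel-wise GLM** (`method = "glm"`): per voxel and order, ordinary
  least squares of $L_l$ on one 0/1 indicator column per site (no global
  intercept) plus covariates. Site coefficients are covariate-adjusted
  site means, and $\vartheta_l = \beta_{\mathrm{ref}} /
  \beta_{\mathrm{target}}$. This relaxes the matching requirement —
  the model assumes the covariate–feature relation is linear in the
  observed range and not collinear with site membership — and fits any
  number of sites in one pass. With no covariates the two estimators are
  algebraically identical (OLS on orthogonal indicators returns group
  means), which the test suite asserts to $10^{-10}$.

Percentage covariate-effect maps, $100\,\beta_{\mathrm{cov}} /
\beta_{\mathrm{ref}}$, quantify how much one covariate unit changes each
order's energy relative to the reference site's adjusted mean.

## Parameters that matter

* `max_order` (default 6): even SH order. 28 coefficients at order 6
  require at least 28 directions for an exact fit; the packaged scheme has
  60.
* `lambda` (default `5e-3`, Laplace–Beltrami): SH regularization. The
  default is a conventional light smoothness penalty that leaves $l = 0$
  untouched. All phantom experiments in the tests and the acceptance
  script use `lambda = 0` instead: with 60 well-spread directions the
  order-6 fit is an exact projection, which makes the simulator's ground
  truth exact and keeps oracle comparisons crisp. The ratio
  $\vartheta$ is insensitive to this choice because numerator and
  denominator are shrunk identically.
* `clip` (default `c(0.1, 10)`) and `eps` (default $10^{-6}\times$ the
  grand mean of the reference feature, per order): degenerate-voxel
  handling. Where the denominator feature is at or below `eps` — e.g.
  higher-order energy in isotropic tissue — $\vartheta$ is undefined; such
  voxels are set to 1 (pass-through), flagged in a validity mask, and
  counted, never silently extrapolated.
* covariate centering: continuous covariates are mean-centered over the
  pooled training sample, so site betas are adjusted means at the
  cohort-average covariate value rather than at covariate zero (an
  uncentered age axis would evaluate the ratio at age 0, far outside the
  data). The centering record is stored in the model.
* `b0_threshold` (50 s/mm²) and shell tolerance (100 s/mm²): robust to
  vendor rounding of nominal b-values. b=0 volumes pass through
  harmonization unchanged; scaling them by $\sqrt{\vartheta_0}$ is
  deliberately not a default because the method is defined on
  diffusion-weighted shells.
* negative reconstructed samples are clipped to zero at output time only
  (magnitude MR signals are non-negative); coefficients are untouched and
  the clipped count is reported.

## The phantom simulator

`simulate_cohort()` generates the study conditions every claim in this
package is tested under: a 16³ voxel grid split into a prolate-tensor
"white matter" slab (axial/radial diffusivity 1.7/0.35 × 10⁻³ mm²/s, FA ≈
0.78), an isotropic "gray matter" block (0.9 × 10⁻³) and a "CSF" block
(3.0 × 10⁻³); one b=0 volume plus 60 directions at b = 1000 s/mm² (a fixed
electrostatic-repulsion set shipped with the package); per-site cohorts
with configurable size, age and sex distributions (default: 18 vs 18 with
mean ages 35.4 and 56.4 years, an unmatched two-decade gap).

Biology enters through the tensor: radial diffusivity in white matter
grows 0.5%/year around age 46 (so FA declines with age), males carry a 2%
radial-diffusivity offset, and a per-subject lognormal factor with 3% SD
provides between-subject variability — chosen so the single-site age–FA
correlation lands near −0.8 at SNR 30, a realistic strength for a strong
age effect in a narrow cohort. Scanner effects are injected in the model's
own domain: per site and order, a smooth random field $g_l(x)$ in [0.7,
1.3] multiplies the SH energy (coefficients scaled by $\sqrt{g_l}$ after
an exact order-6 fit), so the ground-truth scaling map is exactly $1/g_l$
and recovery can be asserted to machine precision in the noiseless case.
Noise is Rician at SNR 30 referenced to the b=0 signal (Gaussian and
noise-free modes exist for linear-theory tests). Two seeds separate
concerns: `effect_seed` fixes the site-effect fields, `seed` everything
else, so held-out cohorts can be drawn under identical scanner effects.

What the phantom does *not* emulate: anatomy, partial-volume ramps between
tissues, motion/eddy/ghosting artifacts, spatial normalization error, and
preprocessing (denoising, drift, Gibbs). Passing tests therefore
demonstrate the estimators' statistical behavior under the model's own
assumptions, not robustness to real-world preprocessing failures.

## Evaluation choices

Tensor fits are plain log-linear least squares with a signal floor of
$10^{-6} S_0$ before the log; eigenvalues come from the closed-form
symmetric 3×3 solution, and FA/MD from their standard definitions. Group
comparisons are parametric per-voxel t-tests on the site contrast of
`metric ~ intercept + site + centered covariates`, reported as the
fraction of tested voxels with $p \le \alpha$; zero-variance voxels are
excluded and counted. The white-matter block plays the role a skeleton
mask plays in real studies. Permutation inference and cluster enhancement
are intentionally out of scope: the object of interest is the before/after
contrast of the significant fraction, not the inference machinery.

One design decision deserves emphasis: the three-site harmonization
experiment trains on one 3 × 15 cohort and evaluates the significant-voxel
fractions on an *independent* matched 3 × 15 cohort simulated under the
same site-effect fields. Evaluating on the training subjects is circular —
the fitted scaling maps absorb those subjects' sampling noise, deflating
the post-harmonization fraction below what any new subject would show.

## Numerical behavior and known limitations

The estimated feature is biased upward by the noise energy of the fitted
coefficients: $E[\hat L_l] \approx L_l + (2l+1)\,\sigma^2\,4\pi/N$ for
Gaussian noise of standard deviation $\sigma$. For a b = 1000 tensor-like
white-matter signal the true energies fall steeply with order (roughly
$3\times10^4 / 3.5\times10^3 / 10^2 / 1$ for $l = 0/2/4/6$ at $S_0 =
100$), while the noise floor at SNR 30 is about $2.3 / 12 / 21 / 30$.
Orders 0 and 2 — which carry essentially all of the harmonized signal —
are therefore estimated to ~1–3% from 15–18 subjects per site, but the
$\vartheta_4$ and especially $\vartheta_6$ ratio estimates collapse toward
1 regardless of cohort size. This is a property of the energy statistic at
this b-value and SNR, not of the implementation (the noiseless pipeline is
exact to $10^{-14}$), and it matches the common observation that
high-order scaling maps from in vivo cohorts look noise-dominated. Users
harmonizing low-SNR data should treat high-order maps with suspicion or
cap `max_order` at 4.

Other limitations: scaling maps are estimated and applied per voxel with
no spatial smoothing by default (`smooth_scaling_maps()` offers opt-in
Gaussian smoothing, since true site-effect fields are spatially smooth
while per-voxel ratios carry estimation noise); covariate effects are
additive and linear with no site-by-covariate interactions; shells of a
multi-shell acquisition are harmonized independently with separate models;
and all inputs must already live on a common voxel grid — the package
performs no registration or resampling.

## Problem sizes

All shipped tests and the acceptance script run on 16³ (occasionally 8³)
grids with 6–45 subjects per experiment, 61 volumes each; the full test
suite completes in well under five minutes on one CPU and the acceptance
script in about one minute. These sizes were chosen so every experiment —
including the 45-subject three-site one — reruns comfortably on a laptop
while keeping ≥ 2000 white-matter voxels for stable medians and fractions.
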