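# rishglm

Multi-site harmonization of diffusion MRI signals from rotational
invariant spherical harmonic (RISH) features, with a voxel-wise general
linear model that separates scanner effects from biological covariates.

## The problem

Diffusion-weighted MRI signals measured on different scanners (or after a
hardware/software upgrade) differ systematically, which confounds pooled
analyses of tensor metrics such as fractional anisotropy (FA) and mean
diffusivity (MD). RISH-based harmonization removes these differences at the
signal level: a single shell is expressed in a real, even-order spherical
harmonic (SH) basis, and for each order *l* the rotation-invariant energy

    L_l = sum_m c_{l,m}^2

is rescaled voxel-wise by a learned factor so that a target scanner's
expected features match a reference scanner's.

The conventional estimator is the ratio of per-site mean features over
matched training groups,

    theta_l(x) = sigma_{l,ref}(x) / sigma_{l,target}(x),

and harmonization multiplies each order-*l* SH coefficient by
`sqrt(theta_l)` before reconstructing the signal. Matching the training
groups on everything that affects the signal (age, sex, ...) is the weak
point: residual demographic differences leak into the scaling maps. This
package additionally implements a GLM formulation that fits, per voxel and
per order,

    L_l ~ S_ref + S_t1 + S_t2 + ... + COV

with one 0/1 indicator column per site (no global intercept) and
mean-centered covariates. Each site's coefficient is then a
covariate-adjusted site mean, `theta_l = beta_ref / beta_target` replaces
the raw ratio, unmatched training cohorts become usable, and any number of
sites is harmonized in a single fit. Percentage covariate-effect maps
(`100 * beta_cov / beta_ref`) come out of the same fit.

The package includes everything needed to exercise the method end to end
without real data: a three-tissue multi-site phantom simulator with known
ground-truth site effects injected in the SH-energy domain (so the true
scaling map is available exactly), a log-linear diffusion tensor fit with
FA/MD, covariate-adjusted voxel-wise group tests, and a command-line
interface.

## Worked example

```r
library(rishglm)

# a two-site phantom: 18 young vs 18 old subjects, SNR 30, order-6 site effect
cfg <- phantom_config(seed = 7)
cohort <- simulate_cohort(cfg)
cohort$subjects[[1]]
#> dwi_volume: 16 x 16 x 16 grid, 61 volumes
#> gradient table: 61 volumes, 1 b=0, shells ~ {1000} s/mm^2

# one-step GLM harmonization, adjusting for age and sex
model <- train_harmonization(cohort$subjects, cohort$covariates,
                             reference = "SiteA", method = "glm",
                             covariates = c("age", "sex"),
                             spec = sh_basis_spec(6, lambda = 0))
model
#> harmonization model (glm): reference SiteA, targets SiteB
#>   shell b=1000, orders 0,2,4,6, grid 16x16x16

# how well did we recover the injected site effect? (WM block)
scaling_recovery_error(model$scaling$SiteB, cohort$truth$theta$SiteB,
                       cohort$truth$wm_mask)
#>   order     median        q90    n
#> 1     0 0.01031404 0.02398948 2048
#> 2     2 0.02547413 0.06143012 2048
#> 3     4 0.12087935 0.30471689 2048
#> 4     6 0.18544303 0.42271719 2048

# harmonize a target-site subject and look at white-matter FA
harmonized <- harmonize_subject(cohort$subjects[[19]], model, "SiteB")
fa_before <- fa_md(fit_dti(select_shell(cohort$subjects[[19]], 1000)))$fa
fa_after  <- fa_md(fit_dti(select_shell(harmonized, 1000)))$fa
fa_ref    <- fa_md(fit_dti(select_shell(cohort$subjects[[1]], 1000)))$fa
wm <- cohort$truth$wm_mask
round(c(reference = mean(fa_ref[wm]), target_before = mean(fa_before[wm]),
        target_after = mean(fa_after[wm])), 3)
#>     reference target_before  target_after
#>         0.769         0.732         0.736
```

Reading the numbers: the low-order scaling maps (which carry almost all of
the signal energy) are recovered to 1–3% from 18 noisy subjects per site;
the order-4/6 maps are noise-dominated at this SNR, as expected for a
b=1000 tensor-like signal whose high-order energy sits below the noise
floor. Harmonization shifts the target subject's white-matter FA by the
scanner component only (0.732 → 0.736): the remaining gap to the young
reference subject (0.769) is the age effect, which the GLM deliberately
leaves in the data — the single-site age–FA correlation is preserved after
harmonization instead of being absorbed into the scaling maps as the
means-based estimator would.

The same pipeline is available from the shell:

```sh
Rscript inst/cli/rishglm.R simulate --out cohort --seed 7
Rscript inst/cli/rishglm.R train --covariates cohort/covariates.csv \
    --reference SiteA --method glm --covariate-names age,sex --out model
Rscript inst/cli/rishglm.R apply --model model --dwi cohort/sub-SiteB_01_dwi.nii.gz \
    --bval cohort/sub-SiteB_01.bval --bvec cohort/sub-SiteB_01.bvec \
    --site SiteB --out harmonized
Rscript inst/cli/rishglm.R evaluate --covariates cohort/covariates.csv \
    --covariate-names age,sex --model model --truth cohort/truth --out report.json
```

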