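#' Packaged 60-direction gradient scheme
#'
#' A fixed set of 60 unit vectors optimized by electrostatic repulsion of
#' antipodal point pairs (minimum angular separation ~18 degrees), so
#' simulations and tests never depend on an optimizer.
#'
#' @return 60 x 3 matrix of unit vectors.
#' @export
default_directions <- function() {
  path <- system.file("extdata", "dirs60.txt", package = "rishglm")
  v <- as.matrix(read.table(path))
  dimnames(v) <- NULL
  v / sqrt(rowSums(v^2))
}

#' Site description for the phantom simulator
#'
#' @param name Site label.
#' @param n Number of subjects (>= 2).
#' @param age_mean,age_sd Gaussian age distribution (years).
#' @param female_fraction Probability a subject is female.
#' @return A `site_spec` list.
#' @export
site_spec <- function(name, n, age_mean, age_sd, female_fraction = 0.5) {
  if (n < 2) stop("each site needs >= 2 subjects", call. = FALSE)
  structure(list(name = name, n = as.integer(n), age_mean = age_mean,
                 age_sd = age_sd, female_fraction = female_fraction),
            class = "site_spec")
}

#' Configuration of the multi-site diffusion phantom
#'
#' The phantom is a blocky three-tissue volume (prolate-tensor "WM" slab,
#' isotropic "GM", high-diffusivity "CSF") imaged with one b=0 volume and a
#' fixed 60-direction shell. Scanner/site effects are injected as smooth
#' multiplicative perturbations g_l of the per-order SH energy, which makes
#' the ground-truth scaling map exactly 1/g_l. Age acts linearly on the WM
#' radial diffusivity (anisotropy decreasing with age), sex as a small
#' offset, and a lognormal per-subject factor provides between-subject
#' biological variability.
#'
#' Default cohort: two sites of 18 subjects with mean ages 35.4 and 56.4
#' years — an unmatched two-decade age gap typical of convenience cohorts.
#'
#' @param sites List of [site_spec()]s; the first is the reference site
#'   (its g_l are identically 1).
#' @param grid Voxel grid dimensions (default 16^3).
#' @param bvalue Shell b-value in s/mm^2 (default 1000).
#' @param directions Unit direction matrix (default [default_directions()]).
#' @param max_order SH order of the injected site effect (default 6).
#' @param g_range Range of the per-order multiplicative site effect fields
#'   (default `c(0.7, 1.3)`).
#' @param g_smooth Gaussian smoothing (voxels) of the site-effect fields.
#' @param age_slope Relative change of WM radial diffusivity per year
#'   (default 0.005: +0.5%/year, i.e. FA decreases with age).
#' @param sex_effect Relative WM radial-diffusivity offset for males
#'   (default 0.02).
#' @param subject_sd Log-SD of the per-subject radial-diffusivity factor
#'   (default 0.03, ~3% biological coefficient of variation).
#' @param age_ref Age (years) at which the WM tensor takes its nominal value.
#' @param wm_evals Nominal WM eigenvalues `c(axial, radial)` in mm^2/s.
#' @param gm_adc,csf_adc Isotropic diffusivities (mm^2/s).
#' @param S0 b=0 signal level (arbitrary units).
#' @param snr Signal-to-noise ratio referenced to S0 (default 30).
#' @param noise `"rician"`, `"gaussian"`, or `"none"`.
#' @param seed Seed for demographics and noise.
#' @param effect_seed Seed for the site-effect fields (defaults to `seed`,
#'   so fixing it while varying `seed` redraws noise under identical
#'   ground-truth g maps).
#' @param keep_noiseless Keep per-subject noiseless volumes in the ground
#'   truth (memory permitting).
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(sites = list(
                             site_spec("SiteA", 18, 35.4, 6.1, 0.44),
                             site_spec("SiteB", 18, 56.4, 8.5, 0.39)),
                           grid = c(16, 16, 16), bvalue = 1000,
                           directions = default_directions(),
                           max_order = 6, g_range = c(0.7, 1.3),
                           g_smooth = 2, age_slope = 0.005,
                           sex_effect = 0.02, subject_sd = 0.03,
                           age_ref = 46,
                           wm_evals = c(1.7e-3, 0.35e-3),
                           gm_adc = 0.9e-3, csf_adc = 3.0e-3,
                           S0 = 100, snr = 30,
                           noise = c("rician", "gaussian", "none"),
                           seed = 1, effect_seed = seed,
                           keep_noiseless = FALSE) {
  noise <- match.arg(noise)
  if (!length(sites) || !all(vapply(sites, inherits, TRUE, "site_spec")))
    stop("sites must be a list of site_spec objects", call. = FALSE)
  nm <- vapply(sites, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate site names", call. = FALSE)
  if (any(g_range <= 0)) stop("g_range must be positive", call. = FALSE)
  if (snr <= 0) stop("snr must be positive", call. = FALSE)
  check_even_order(max_order)
  structure(list(sites = sites, grid = as.integer(grid), bvalue = bvalue,
                 directions = as.matrix(directions), max_order = max_order,
                 g_range = g_range, g_smooth = g_smooth,
                 age_slope = age_slope, sex_effect = sex_effect,
                 subject_sd = subject_sd, age_ref = age_ref,
                 wm_evals = wm_evals, gm_adc = gm_adc, csf_adc = csf_adc,
                 S0 = S0, snr = snr, noise = noise,
                 seed = as.integer(seed), effect_seed = as.integer(effect_seed),
                 keep_noiseless = keep_noiseless),
            class = "phantom_config")
}

# Blocky tissue layout: slabs along x. WM = first half, GM = next ~30%,
# CSF = remainder.
tissue_labels <- function(grid) {
  nx <- grid[1]
  wm_end <- max(1, floor(nx * 0.5))
  gm_end <- max(wm_end + 1, floor(nx * 0.8))
  lab <- array("CSF", grid)
  lab[seq_len(wm_end), , ] <- "WM"
  if (gm_end > wm_end) lab[(wm_end + 1):gm_end, , ] <- "GM"
  lab
}

# Smooth random field: white noise smoothed by a separable Gaussian kernel
# (reflection at the edges), min-max rescaled to `range`.
smooth_random_field <- function(grid, sigma, range) {
  x <- array(rnorm(prod(grid)), grid)
  if (sigma > 0) {
    half <- max(1L, ceiling(3 * sigma))
    k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
    k <- k / sum(k)
    conv1 <- function(v) { # reflect-pad 1D convolution
      n <- length(v)
      idx <- c(rev(seq_len(half)), seq_len(n), n + 1 - rev(seq_len(half)))
      vp <- v[pmin(pmax(idx, 1), n)]
      as.numeric(stats::filter(vp, k, sides = 2))[(half + 1):(half + n)]
    }
    for (d in 1:3) {
      perm <- c(d, setdiff(1:3, d))
      xp <- aperm(x, perm)
      dimp <- dim(xp)
      xm <- matrix(xp, dimp[1], prod(dimp[2:3]))
      xm <- apply(xm, 2, conv1)
      x <- aperm(array(xm, dimp), order(perm))
    }
  }
  lo <- min(x); hi <- max(x)
  if (hi - lo < 1e-12) return(array(mean(range), grid))
  range[1] + (x - lo) / (hi - lo) * diff(range)
}

# Noiseless shell signals (X x Y x Z x Ndir) for one subject's tensor field.
# WM: prolate tensor with principal axis along z; GM/CSF isotropic.
phantom_signals <- function(config, age, sex, subj_factor) {
  grid <- config$grid
  lab <- tissue_labels(grid)
  rd <- config$wm_evals[2] *
    (1 + config$age_slope * (age - config$age_ref)) *
    (1 + config$sex_effect * (sex == "M")) * subj_factor
  rd <- max(rd, 1e-5)
  ad <- config$wm_evals[1]
  dirs <- config$directions
  z2 <- dirs[, 3]^2
  b <- config$bvalue
  att_wm <- exp(-b * (rd * (1 - z2) + ad * z2)) # per direction
  att_gm <- exp(-b * config$gm_adc)
  att_csf <- exp(-b * config$csf_adc)
  sig <- array(0, c(grid, nrow(dirs)))
  wm <- lab == "WM"; gm <- lab == "GM"; csf <- lab == "CSF"
  for (d in seq_len(nrow(dirs))) {
    sl <- array(att_gm * config$S0, grid)
    sl[wm] <- att_wm[d] * config$S0
    sl[csf] <- att_csf * config$S0
    sig[, , , d] <- sl
  }
  sig
}

# Inject the site effect in the SH-energy domain: fit exact (lambda = 0) SH,
# multiply order-l coefficients by sqrt(g_l(x)), reconstruct.
inject_site_effect <- function(signals, config, g_site) {
  shell <- structure(list(dwi_signals = signals,
                          directions = config$directions,
                          bvalue = config$bvalue,
                          b0_mean = array(config$S0, config$grid)),
                     class = "shell_data")
  coeffs <- fit_sh(shell, sh_basis_spec(config$max_order, lambda = 0))
  scaling <- structure(list(theta = g_site,
                            valid = array(TRUE, config$grid),
                            orders = seq(0, config$max_order, by = 2)),
                       class = "scaling_maps")
  scaled <- apply_rish_scaling(coeffs, scaling)
  sh_reconstruct(scaled, config$directions)
}

add_noise <- function(x, sigma, type) {
  switch(type,
         none = x,
         gaussian = x + sigma * array(rnorm(length(x)), dim(x)),
         rician = sqrt((x + sigma * array(rnorm(length(x)), dim(x)))^2 +
                         (sigma * array(rnorm(length(x)), dim(x)))^2))
}

#' Simulate a multi-site diffusion phantom cohort
#'
#' Deterministic given the config seeds: the site-effect fields are drawn
#' under `effect_seed`, then demographics, per-subject biology and noise
#' under `seed`. The reference site (first in `config$sites`) has g_l = 1;
#' for the others the exact ground-truth scaling map is theta_l = 1 / g_l.
#'
#' @param config A [phantom_config()].
#' @return List of class `phantom_cohort`: `subjects` (list of
#'   `dwi_volume`, b=0 volume first), `covariates` (a [covariate_table()]
#'   with age and sex), and `truth` with elements `g` and `theta`
#'   (per site, per order 3D maps), `tissue`, `wm_mask`, `gm_mask`,
#'   `csf_mask`, `mask`, `subject_params`, optionally `noiseless`, and the
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  grid <- config$grid
  orders <- seq(0, config$max_order, by = 2)
  site_names <- vapply(config$sites, `[[`, character(1), "name")
  reference <- site_names[1]

  set.seed(config$effect_seed)
  g <- lapply(seq_along(site_names), function(i) {
    maps <- lapply(orders, function(l) {
      if (i == 1) array(1, grid)
      else smooth_random_field(grid, config$g_smooth, config$g_range)
    })
    names(maps) <- paste0("L", orders)
    maps
  })
  names(g) <- site_names
  theta <- lapply(g, function(maps) lapply(maps, function(m) 1 / m))

  set.seed(config$seed)
  subjects <- list()
  rows <- list()
  noiseless <- if (config$keep_noiseless) list() else NULL
  params <- list()
  sigma <- config$S0 / config$snr
  bvals <- c(0, rep(config$bvalue, nrow(config$directions)))
  bvecs <- rbind(c(0, 0, 0), config$directions)
  gt <- gradient_table(bvals, bvecs)
  k <- 0L
  for (s in config$sites) {
    for (i in seq_len(s$n)) {
      k <- k + 1L
      age <- rnorm(1, s$age_mean, s$age_sd)
      sex <- if (runif(1) < s$female_fraction) "F" else "M"
      subj_factor <- exp(rnorm(1, 0, config$subject_sd))
      sig <- phantom_signals(config, age, sex, subj_factor)
      if (s$name != reference)
        sig <- inject_site_effect(sig, config, g[[s$name]])
      vol <- array(0, c(grid, length(bvals)))
      vol[, , , 1] <- config$S0
      vol[, , , -1] <- sig
      if (config$keep_noiseless) noiseless[[k]] <- vol
      vol <- add_noise(vol, if (config$noise == "none") 0 else sigma,
                       config$noise)
      subjects[[k]] <- dwi_volume(vol, diag(c(2, 2, 2, 1)), gt)
      rows[[k]] <- data.frame(subject_id = sprintf("%s_%02d", s$name, i),
                              site = s$name, age = age, sex = sex)
      params[[k]] <- data.frame(subject_id = sprintf("%s_%02d", s$name, i),
                                subj_factor = subj_factor)
    }
  }
  covs <- covariate_table(do.call(rbind, rows), c("age", "sex"))
  lab <- tissue_labels(grid)
  structure(list(
    subjects = subjects, covariates = covs,
    truth = list(g = g, theta = theta, tissue = lab,
                 wm_mask = lab == "WM", gm_mask = lab == "GM",
                 csf_mask = lab == "CSF",
                 mask = array(TRUE, grid),
                 subject_params = do.call(rbind, params),
                 noiseless = noiseless, config = config,
                 reference = reference)
  ), class = "phantom_cohort")
}

#' Ground-truth covariate slopes of the RISH features
#'
#' Brute-force oracle: synthesizes noiseless reference-site signals at the
#' pooled mean covariate value, perturbs the requested covariate by +/-
#' delta, and returns the central finite difference of each order's RISH
#' energy (for `"sex"`, the M - F difference at the mean age).
#'
#' @param config A [phantom_config()].
#' @param covariate `"age"` or `"sex"`.
#' @param delta Finite-difference step in years (age only).
#' @return Named list of per-order 3D slope maps.
#' @export
truth_rish_slopes <- function(config, covariate = c("age", "sex"), delta = 1) {
  stopifnot(inherits(config, "phantom_config"))
  covariate <- match.arg(covariate)
  ns <- vapply(config$sites, `[[`, integer(1), "n")
  mean_age <- sum(vapply(config$sites, `[[`, numeric(1), "age_mean") * ns) / sum(ns)
  rish_at <- function(age, sex) {
    sig <- phantom_signals(config, age, sex, 1)
    shell <- structure(list(dwi_signals = sig, directions = config$directions,
                            bvalue = config$bvalue,
                            b0_mean = array(config$S0, config$grid)),
                       class = "shell_data")
    compute_rish(fit_sh(shell, sh_basis_spec(config$max_order, lambda = 0)))
  }
  if (covariate == "age") {
    up <- rish_at(mean_age + delta, "F")
    dn <- rish_at(mean_age - delta, "F")
    out <- lapply(seq_along(up$orders), function(k)
      (up$features[, , , k] - dn$features[, , , k]) / (2 * delta))
    names(out) <- paste0("L", up$orders)
  } else {
    m <- rish_at(mean_age, "M")
    f <- rish_at(mean_age, "F")
    out <- lapply(seq_along(m$orders), function(k)
      m$features[, , , k] - f$features[, , , k])
    names(out) <- paste0("L", m$orders)
  }
  out
}
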