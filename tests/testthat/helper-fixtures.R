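# Shared in-code fixtures: tiny shells, band-limited signals, small cohorts.

fixture_dirs <- function() default_directions()

# shell_data holding the same signal vector at every voxel of a small grid
fixture_shell <- function(signal, directions, grid = c(2, 2, 2), bvalue = 1000,
                          b0 = 100) {
  arr <- array(rep(signal, each = prod(grid)), c(grid, length(signal)))
  structure(list(dwi_signals = arr, directions = directions, bvalue = bvalue,
                 b0_mean = array(b0, grid)), class = "shell_data")
}

# strictly positive band-limited signal of given max order
fixture_bandlimited <- function(directions, max_order = 6, seed = 42,
                                mean_level = 50) {
  set.seed(seed)
  M <- num_sh_coefficients(max_order)
  ctrue <- c(mean_level * 2 * sqrt(pi), rnorm(M - 1, 0, mean_level / 20))
  B <- sh_basis(directions, max_order)
  list(coeffs = ctrue, signal = as.numeric(B %*% ctrue))
}

# random 3D rotation matrix
fixture_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# small noiseless matched phantom for fast pipeline tests
fixture_cohort <- function(n = 3, noise = "none", snr = 30, seed = 5,
                           age_slope = 0, sex_effect = 0, subject_sd = 0,
                           sites = NULL, grid = c(8, 8, 8), max_order = 4) {
  if (is.null(sites))
    sites <- list(site_spec("Ref", n, 50, 8, 0.5),
                  site_spec("Tgt", n, 50, 8, 0.5))
  phantom_config(sites = sites, grid = grid, max_order = max_order,
                 noise = noise, snr = snr, seed = seed,
                 age_slope = age_slope, sex_effect = sex_effect,
                 subject_sd = subject_sd)
}

tissue_labels_for_test <- function(grid) rishglm:::tissue_labels(grid)

# read a NIfTI as a bare numeric array (no image attributes)
nifti_array <- function(path) {
  x <- RNifti::readNifti(path)
  array(as.numeric(x), dim(x))
}

fixture_covariates <- function(n_per_site = 4, sites = c("S1", "S2"),
                               seed = 3) {
  set.seed(seed)
  df <- data.frame(
    subject_id = sprintf("sub%02d", seq_len(n_per_site * length(sites))),
    site = rep(sites, each = n_per_site),
    age = round(rnorm(n_per_site * length(sites), 50, 10), 1),
    sex = sample(c("F", "M"), n_per_site * length(sites), replace = TRUE))
  # guarantee both sexes present
  df$sex[1:2] <- c("F", "M")
  df
}
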