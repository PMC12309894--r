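#' Per-site voxel-wise mean RISH features
#'
#' The conventional harmonization statistic: the arithmetic mean of each
#' order's RISH energy over the training subjects of each site.
#'
#' @param features List of `rish_image`, one per subject, on one grid.
#' @param sites Character vector of site labels aligned with `features`.
#' @return Object of class `site_means`: `means[[site]][[paste0("L", l)]]`
#'   3D arrays, plus `orders`, `sites`, `mask`.
#' @export
fit_site_means <- function(features, sites) {
  check_feature_list(features)
  sites <- as.character(sites)
  if (length(sites) != length(features))
    stop("sites must align with the feature list", call. = FALSE)
  tab <- table(sites)
  if (any(tab < 2))
    stop("every site needs >= 2 training subjects; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  orders <- features[[1]]$orders
  dims <- dim(features[[1]]$features)[1:3]
  means <- lapply(unique(sites), function(s) {
    idx <- which(sites == s)
    per_order <- lapply(seq_along(orders), function(k) {
      acc <- array(0, dims)
      for (i in idx) acc <- acc + slice4(features[[i]]$features, k)
      acc / length(idx)
    })
    names(per_order) <- paste0("L", orders)
    per_order
  })
  names(means) <- unique(sites)
  structure(list(means = means, orders = orders, sites = unique(sites),
                 mask = features[[1]]$mask),
            class = "site_means")
}

# slice channel j of a 4D array without dropping singleton spatial dims
slice4 <- function(a, j) array(a[, , , j], dim(a)[1:3])

check_feature_list <- function(features) {
  if (!length(features) || !all(vapply(features, inherits, TRUE, "rish_image")))
    stop("features must be a non-empty list of rish_image objects", call. = FALSE)
  d0 <- dim(features[[1]]$features)
  o0 <- features[[1]]$orders
  for (f in features[-1]) {
    if (!identical(dim(f$features), d0) || !identical(f$orders, o0))
      stop("all feature images must share one grid and one order list", call. = FALSE)
  }
  invisible(TRUE)
}

# Shared ratio -> scaling-map construction with eps guard and clipping.
make_scaling_maps <- function(num, den, orders, reference, target,
                              clip, eps_per_order) {
  dims <- dim(num[[1]])
  valid <- array(TRUE, dims)
  theta <- vector("list", length(orders))
  names(theta) <- paste0("L", orders)
  n_low <- n_high <- setNames(integer(length(orders)), names(theta))
  for (k in seq_along(orders)) {
    ok <- is.finite(den[[k]]) & den[[k]] > eps_per_order[k] & is.finite(num[[k]])
    th <- array(1, dims)
    th[ok] <- num[[k]][ok] / den[[k]][ok]
    lo <- ok & th < clip[1]; hi <- ok & th > clip[2]
    th[lo] <- clip[1]; th[hi] <- clip[2]
    n_low[k] <- sum(lo); n_high[k] <- sum(hi)
    valid <- valid & ok
    theta[[k]] <- th
  }
  structure(list(theta = theta, valid = valid, orders = orders,
                 reference = reference, target = target, clip = clip,
                 eps = eps_per_order, n_clipped_low = n_low,
                 n_clipped_high = n_high, n_invalid = sum(!valid)),
            class = "scaling_maps")
}

default_eps <- function(ref_maps) {
  # 1e-6 x grand mean of the reference-site feature, per order
  vapply(ref_maps, function(m) 1e-6 * mean(m[is.finite(m)]), numeric(1))
}

#' Scaling maps from per-site mean features (conventional RISH)
#'
#' theta_l = sigma_{l,ref} / sigma_{l,target}, guarded where the denominator
#' is at or below `eps` (theta = 1, flagged invalid) and clipped to `clip`.
#'
#' @param means A `site_means` object.
#' @param reference,target Site labels.
#' @param clip Length-2 bounds on theta (default `c(0.1, 10)`).
#' @param eps Scalar or per-order denominator guard; default
#'   `1e-6 * grand mean of the reference feature` per order.
#' @return A `scaling_maps` object.
#' @export
scaling_from_means <- function(means, reference, target, clip = c(0.1, 10),
                               eps = NULL) {
  stopifnot(inherits(means, "site_means"))
  for (s in c(reference, target))
    if (!s %in% means$sites)
      stop("site '", s, "' not in the trained means", call. = FALSE)
  num <- means$means[[reference]]
  den <- means$means[[target]]
  eps_per_order <- resolve_eps(eps, num, means$orders)
  make_scaling_maps(num, den, means$orders, reference, target, clip, eps_per_order)
}

resolve_eps <- function(eps, ref_maps, orders) {
  if (is.null(eps)) default_eps(ref_maps)
  else if (length(eps) == 1) rep(eps, length(orders))
  else if (length(eps) == length(orders)) eps
  else stop("eps must be NULL, a scalar, or one value per order", call. = FALSE)
}

#' Spatially smooth scaling maps
#'
#' Optional Gaussian smoothing of the per-order theta maps (site-effect
#' fields are spatially smooth, while per-voxel ratio estimates carry voxel
#' noise). Off by default in the training pipeline; invalid voxels keep
#' theta = 1 and are excluded from the smoothing average.
#'
#' @param scaling A `scaling_maps` object.
#' @param fwhm Kernel full width at half maximum, in millimetres.
#' @param voxel_size Voxel edge length in millimetres (default 2).
#' @return The smoothed `scaling_maps`.
#' @export
smooth_scaling_maps <- function(scaling, fwhm, voxel_size = 2) {
  stopifnot(inherits(scaling, "scaling_maps"))
  if (fwhm <= 0) return(scaling)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size # voxels
  w <- array(as.numeric(scaling$valid), dim(scaling$valid))
  wsm <- gaussian_smooth3(w, sigma)
  for (l in names(scaling$theta)) {
    th <- scaling$theta[[l]]
    num <- gaussian_smooth3(th * w, sigma)
    sm <- ifelse(wsm > 1e-8, num / wsm, 1)
    sm[!scaling$valid] <- 1
    scaling$theta[[l]] <- array(sm, dim(th))
  }
  scaling$smoothed_fwhm <- fwhm
  scaling
}

# separable Gaussian convolution with reflected edges
gaussian_smooth3 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    idx <- c(pmin(rev(seq_len(half)) + 1, n), seq_len(n),
             pmax(n - seq_len(half), 1))
    as.numeric(stats::filter(v[idx], k, sides = 2))[(half + 1):(half + n)]
  }
  for (d in 1:3) {
    perm <- c(d, setdiff(1:3, d))
    xp <- aperm(x, perm)
    dimp <- dim(xp)
    xm <- apply(matrix(xp, dimp[1], prod(dimp[2:3])), 2, conv1)
    x <- aperm(array(xm, dimp), order(perm))
  }
  x
}

#' Voxel-wise GLM fit of RISH features on site dummies and covariates
#'
#' Per voxel and order, ordinary least squares of the subjects' RISH energy
#' on the design matrix. With a dummies-only design, each site's beta equals
#' that site's voxel-wise mean exactly.
#'
#' @param features List of per-subject `rish_image` aligned with the design
#'   rows.
#' @param design A [build_design()] result.
#' @param mask Optional 3D logical array restricting the fit.
#' @return Object of class `glm_maps`: `betas[[paste0("L", l)]]`
#'   (X x Y x Z x p array), `resvar` (residual variance per order),
#'   `columns`, `site_columns`, `covariate_columns`, `reference`,
#'   `centering`, `orders`, `mask`.
#' @export
fit_rish_glm <- function(features, design, mask = NULL) {
  check_feature_list(features)
  stopifnot(inherits(design, "design_matrix"))
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  if (length(features) != n)
    stop(sprintf("design has %d rows but %d feature images given", n,
                 length(features)), call. = FALSE)
  if (n <= p)
    stop(sprintf("need more subjects (%d) than design columns (%d)", n, p),
         call. = FALSE)
  dims <- dim(features[[1]]$features)[1:3]
  if (is.null(mask)) mask <- features[[1]]$mask
  mask <- array(as.logical(mask), dims)
  idx <- which(mask)
  orders <- features[[1]]$orders
  XtXinv <- chol2inv(chol(crossprod(X)))
  H <- XtXinv %*% t(X) # p x n
  betas <- resvar <- vector("list", length(orders))
  names(betas) <- names(resvar) <- paste0("L", orders)
  for (k in seq_along(orders)) {
    Y <- vapply(features, function(f) slice4(f$features, k)[idx],
                numeric(length(idx))) # V x n
    Bm <- Y %*% t(H) # V x p
    fit <- Bm %*% t(X) # V x n
    rv <- rowSums((Y - fit)^2) / (n - p)
    barr <- array(0, c(dims, p))
    Bfull <- matrix(0, prod(dims), p)
    Bfull[idx, ] <- Bm
    betas[[k]] <- array(Bfull, c(dims, p))
    rvfull <- numeric(prod(dims)); rvfull[idx] <- rv
    resvar[[k]] <- array(rvfull, dims)
  }
  structure(list(betas = betas, resvar = resvar, columns = design$columns,
                 site_columns = design$site_columns,
                 covariate_columns = design$covariate_columns,
                 reference = design$reference, centering = design$centering,
                 orders = orders, mask = mask, n = n),
            class = "glm_maps")
}

#' Scaling maps from GLM site coefficients
#'
#' theta_l = beta_{l,ref} / beta_{l,target}. Because continuous covariates
#' are mean-centered, the site betas are covariate-adjusted site means at
#' the pooled-average covariate value, so with a dummies-only design this
#' reproduces [scaling_from_means()] exactly.
#'
#' @param betas A `glm_maps` object.
#' @inheritParams scaling_from_means
#' @return A `scaling_maps` object.
#' @export
scaling_from_glm <- function(betas, reference, target, clip = c(0.1, 10),
                             eps = NULL) {
  stopifnot(inherits(betas, "glm_maps"))
  for (s in c(reference, target))
    if (!s %in% betas$site_columns)
      stop("site '", s, "' has no column in the fitted GLM", call. = FALSE)
  jr <- match(reference, betas$columns)
  jt <- match(target, betas$columns)
  num <- lapply(betas$betas, function(b) slice4(b, jr))
  den <- lapply(betas$betas, function(b) slice4(b, jt))
  eps_per_order <- resolve_eps(eps, num, betas$orders)
  make_scaling_maps(num, den, betas$orders, reference, target, clip, eps_per_order)
}

#' Percentage covariate effect on RISH features
#'
#' 100 * beta_cov / beta_ref per order and voxel: the percent change of the
#' order-l energy per unit of the covariate, relative to the reference
#' site's adjusted mean. Voxels where |beta_ref| <= eps are NA.
#'
#' @param betas A `glm_maps` object.
#' @param covariate Covariate column name (expanded name for categoricals,
#'   e.g. `"sexM"`).
#' @param reference Reference-site label (defaults to the design's).
#' @param eps Denominator guard (default as in [scaling_from_means()]).
#' @return Named list of 3D percent maps, one per order.
#' @export
covariate_effect_percent <- function(betas, covariate,
                                     reference = betas$reference, eps = NULL) {
  stopifnot(inherits(betas, "glm_maps"))
  if (!covariate %in% betas$covariate_columns)
    stop("unknown covariate '", covariate, "'; available: ",
         paste(betas$covariate_columns, collapse = ", "), call. = FALSE)
  jr <- match(reference, betas$columns)
  jc <- match(covariate, betas$columns)
  ref_maps <- lapply(betas$betas, function(b) slice4(b, jr))
  eps_per_order <- resolve_eps(eps, ref_maps, betas$orders)
  out <- lapply(seq_along(betas$orders), function(k) {
    bref <- ref_maps[[k]]
    bcov <- slice4(betas$betas[[k]], jc)
    m <- array(NA_real_, dim(bref))
    ok <- is.finite(bref) & abs(bref) > eps_per_order[k]
    m[ok] <- 100 * bcov[ok] / bref[ok]
    m
  })
  names(out) <- paste0("L", betas$orders)
  out
}

#' Train a harmonization model
#'
#' Chains SH fitting, RISH feature computation and scaling-map estimation
#' for every non-reference site in one pass. With `method = "glm"` all sites
#' and covariates are fit jointly (one-step multi-site harmonization); with
#' `method = "means"` each target site is scaled by the ratio of per-site
#' mean features, which assumes demographically matched groups.
#'
#' All inputs must already live on one common voxel grid: the method is
#' purely voxel-wise and performs no registration.
#'
#' @param subjects List of `dwi_volume`, `shell_data` or `sh_image` objects,
#'   aligned with the rows of `table`.
#' @param table A [covariate_table()] (or plain data frame with
#'   `subject_id`, `site` and covariates).
#' @param reference Reference site label; its subjects are never modified.
#' @param method `"glm"` or `"means"`.
#' @param covariates Covariate names for the GLM (ignored with a warning by
#'   `"means"`).
#' @param spec [sh_basis_spec()] used for SH fitting.
#' @param bvalue Shell to harmonize; defaults to the most common
#'   diffusion-weighted b-value of the first subject.
#' @param mask Optional 3D logical array.
#' @param clip,eps Passed to the scaling-map constructors.
#' @param shell_tol Shell selection tolerance (s/mm^2).
#' @return Object of class `harmonization_model`.
#' @export
train_harmonization <- function(subjects, table, reference,
                                method = c("glm", "means"),
                                covariates = character(),
                                spec = sh_basis_spec(), bvalue = NULL,
                                mask = NULL, clip = c(0.1, 10), eps = NULL,
                                shell_tol = 100) {
  method <- match.arg(method)
  if (!inherits(table, "covariate_table"))
    table <- covariate_table(table, covariates)
  if (length(subjects) != nrow(table))
    stop("subject list and covariate table have different lengths", call. = FALSE)
  if (method == "means" && length(covariates))
    warning("method = 'means' ignores covariates; use method = 'glm' to adjust for them")

  prep <- lapply(subjects, function(s) {
    if (inherits(s, "dwi_volume")) {
      if (is.null(bvalue)) {
        bs <- s$gradients$bvals
        bvalue <<- as.numeric(names(sort(table(bs[bs > s$gradients$b0_threshold]),
                                         decreasing = TRUE))[1])
      }
      s <- select_shell(s, bvalue, shell_tol)
    }
    if (inherits(s, "shell_data")) s <- fit_sh(s, spec, mask)
    if (!inherits(s, "sh_image"))
      stop("subjects must be dwi_volume, shell_data or sh_image", call. = FALSE)
    s
  })
  if (is.null(bvalue)) bvalue <- prep[[1]]$bvalue
  dims <- dim(prep[[1]]$coeffs)[1:3]
  feats <- lapply(prep, compute_rish)
  targets <- sort(setdiff(unique(table$site), reference))
  if (!length(targets)) stop("no target sites besides the reference", call. = FALSE)

  glm_fit <- NULL
  if (method == "glm") {
    design <- build_design(table, covariates, reference)
    glm_fit <- fit_rish_glm(feats, design, mask)
    scaling <- lapply(targets, function(s)
      scaling_from_glm(glm_fit, reference, s, clip, eps))
  } else {
    sm <- fit_site_means(feats, table$site)
    scaling <- lapply(targets, function(s)
      scaling_from_means(sm, reference, s, clip, eps))
  }
  names(scaling) <- targets
  structure(list(reference = reference, targets = targets,
                 orders = seq(0, spec$max_order, by = 2), bvalue = bvalue,
                 method = method, spec = spec, scaling = scaling,
                 glm = glm_fit, covariates = covariates,
                 centering = if (!is.null(glm_fit)) glm_fit$centering else NULL,
                 grid = as.integer(dims), clip = clip,
                 version = "rishglm-1"),
            class = "harmonization_model")
}

#' @export
print.harmonization_model <- function(x, ...) {
  cat(sprintf("harmonization model (%s): reference %s, targets %s\n",
              x$method, x$reference, paste(x$targets, collapse = ", ")))
  cat(sprintf("  shell b=%g, orders %s, grid %s\n", x$bvalue,
              paste(x$orders, collapse = ","), paste(x$grid, collapse = "x")))
  invisible(x)
}

#' Harmonize one subject's DWI volume
#'
#' Fits the SH representation of the configured shell, multiplies order-l
#' coefficients by sqrt(theta_l) of the subject's site, and reconstructs the
#' signal at the subject's own directions. b=0 volumes (and any volume
#' outside the shell) pass through unchanged; reference-site subjects are
#' returned untouched.
#'
#' @param dwi A `dwi_volume`.
#' @param model A `harmonization_model`.
#' @param site The subject's site label.
#' @param mask Optional 3D logical array.
#' @param shell_tol Shell selection tolerance (s/mm^2).
#' @return A harmonized `dwi_volume`; attribute `n_clipped` counts
#'   negative reconstructed samples clipped to zero.
#' @export
harmonize_subject <- function(dwi, model, site, mask = NULL, shell_tol = 100) {
  stopifnot(inherits(dwi, "dwi_volume"), inherits(model, "harmonization_model"))
  if (site == model$reference) return(dwi)
  if (!site %in% model$targets)
    stop("site '", site, "' is not a target of this model (targets: ",
         paste(model$targets, collapse = ", "), ")", call. = FALSE)
  dims <- dim(dwi$data)
  if (!identical(as.integer(dims[1:3]), model$grid))
    stop(sprintf("grid mismatch: subject %s vs model %s",
                 paste(dims[1:3], collapse = "x"),
                 paste(model$grid, collapse = "x")), call. = FALSE)
  gt <- dwi$gradients
  in_shell <- abs(gt$bvals - model$bvalue) <= shell_tol & gt$bvals > gt$b0_threshold
  if (!any(in_shell))
    stop(sprintf("subject has no volumes at the model shell b=%g", model$bvalue),
         call. = FALSE)
  shell <- select_shell(dwi, model$bvalue, shell_tol)
  coeffs <- fit_sh(shell, model$spec, mask)
  scaled <- apply_rish_scaling(coeffs, model$scaling[[site]])
  recon <- sh_reconstruct(scaled, shell$directions)
  out <- dwi$data
  out[, , , in_shell] <- recon
  res <- dwi_volume(out, dwi$affine, gt)
  attr(res, "n_clipped") <- attr(recon, "n_clipped")
  attr(res, "n_invalid") <- attr(scaled, "n_invalid")
  res
}
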