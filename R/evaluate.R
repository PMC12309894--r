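#' Covariate-adjusted voxel-wise two-site group test
#'
#' Per voxel fits metric ~ intercept + site indicator + centered covariates
#' by least squares and reports the t statistic and two-sided p-value of the
#' site contrast, plus the fraction of tested voxels with p <= alpha.
#' Zero-residual-variance voxels are excluded and counted. With no
#' covariates this reduces to the classical equal-variance two-sample
#' t-test.
#'
#' @param metrics List of 3D metric maps (e.g. FA), one per subject,
#'   aligned with the rows of `table`.
#' @param table A [covariate_table()] (or data frame) with `site` and the
#'   covariates.
#' @param sites Length-2 character vector: the site pair to compare.
#' @param covariates Covariate names to adjust for (default none).
#' @param alpha Significance level (default 0.05).
#' @param mask Optional 3D logical array.
#' @return Object of class `group_test`: `t` and `p` (3D maps, NA outside
#'   mask/excluded), `fraction` of tested voxels with p <= alpha, `alpha`,
#'   `n_excluded`, `sites`, `df`.
#' @export
adjusted_group_test <- function(metrics, table, sites,
                                covariates = character(), alpha = 0.05,
                                mask = NULL) {
  if (!inherits(table, "covariate_table"))
    table <- covariate_table(table, covariates)
  if (length(sites) != 2) stop("sites must name exactly two sites", call. = FALSE)
  if (length(metrics) != nrow(table))
    stop("metric list and covariate table have different lengths", call. = FALSE)
  keep <- table$site %in% sites
  if (sum(table$site == sites[1]) < 3 || sum(table$site == sites[2]) < 3)
    stop("need >= 3 subjects per site", call. = FALSE)
  sub <- as.data.frame(table)[keep, , drop = FALSE]
  metrics <- metrics[keep]
  dims <- dim(metrics[[1]])
  if (is.null(mask)) mask <- array(TRUE, dims)
  mask <- array(as.logical(mask), dims)

  cov_cols <- resolve_covariate_columns(table, covariates)
  X <- cbind(`(Intercept)` = 1, site = as.numeric(sub$site == sites[2]))
  if (length(cov_cols)) {
    Xc <- as.matrix(sub[, cov_cols, drop = FALSE])
    storage.mode(Xc) <- "double"
    Xc <- sweep(Xc, 2, colMeans(Xc))
    X <- cbind(X, Xc)
  }
  n <- nrow(X); p <- ncol(X)
  if (qr(X)$rank < p)
    stop("rank-deficient test design (covariate collinear with site?)", call. = FALSE)
  XtXinv <- chol2inv(chol(crossprod(X)))
  H <- XtXinv %*% t(X)
  idx <- which(mask)
  Y <- vapply(metrics, function(m) m[idx], numeric(length(idx))) # V x n
  B <- Y %*% t(H)
  res <- Y - B %*% t(X)
  df <- n - p
  s2 <- rowSums(res^2) / df
  se <- sqrt(s2 * XtXinv[2, 2])
  excluded <- se <= .Machine$double.eps * (abs(B[, 2]) + 1)
  tval <- ifelse(excluded, NA_real_, B[, 2] / se)
  pval <- 2 * pt(-abs(tval), df)
  tested <- sum(!excluded)
  frac <- if (tested) sum(pval <= alpha, na.rm = TRUE) / tested else NA_real_
  tmap <- array(NA_real_, dims); tmap[idx] <- tval
  pmap <- array(NA_real_, dims); pmap[idx] <- pval
  structure(list(t = tmap, p = pmap, fraction = frac, alpha = alpha,
                 n_excluded = sum(excluded), sites = sites, df = df),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("group test %s vs %s: %.1f%% of voxels p <= %g (df = %d, %d excluded)\n",
              x$sites[1], x$sites[2], 100 * x$fraction, x$alpha, x$df,
              x$n_excluded))
  invisible(x)
}

#' Recovery error of estimated scaling maps against ground truth
#'
#' @param estimated A `scaling_maps` object.
#' @param truth Named list of per-order true theta maps (e.g.
#'   `cohort$truth$theta[[site]]`).
#' @param mask Optional 3D logical array (e.g. the WM block).
#' @return Data frame with one row per order: `order`, `median`, `q90` of
#'   the relative error |theta_hat - theta| / theta over valid voxels, and
#'   `n` voxels used.
#' @export
scaling_recovery_error <- function(estimated, truth, mask = NULL) {
  stopifnot(inherits(estimated, "scaling_maps"))
  dims <- dim(estimated$valid)
  if (is.null(mask)) mask <- array(TRUE, dims)
  mask <- array(as.logical(mask), dims)
  rows <- lapply(estimated$orders, function(l) {
    key <- paste0("L", l)
    if (is.null(truth[[key]]))
      stop("truth lacks order ", l, call. = FALSE)
    sel <- mask & estimated$valid & is.finite(truth[[key]]) & truth[[key]] > 0
    err <- abs(estimated$theta[[key]][sel] - truth[[key]][sel]) / truth[[key]][sel]
    data.frame(order = l, median = median(err), q90 = quantile(err, 0.9,
               names = FALSE), n = sum(sel))
  })
  do.call(rbind, rows)
}

#' Correlation between age and a subject-level summary metric
#'
#' Pearson correlation between age and the subject-mean of the metric
#' within the mask, with its 95% confidence interval.
#'
#' @param metrics List of 3D metric maps, aligned with `table`.
#' @param table Covariate table with an `age` column.
#' @param mask Optional 3D logical array over which subject means are taken.
#' @return List: `r`, `ci` (length 2), `p`, `n`, `means` (per-subject
#'   summary values). `r` is NA with a message element when a variance is
#'   degenerate.
#' @export
age_metric_correlation <- function(metrics, table, mask = NULL) {
  if (length(metrics) != nrow(table))
    stop("metric list and covariate table have different lengths", call. = FALSE)
  if (length(metrics) < 4) stop("need >= 4 subjects", call. = FALSE)
  dims <- dim(metrics[[1]])
  if (is.null(mask)) mask <- array(TRUE, dims)
  mask <- array(as.logical(mask), dims)
  means <- vapply(metrics, function(m) mean(m[mask]), numeric(1))
  age <- as.numeric(table$age)
  if (sd(age) == 0 || sd(means) == 0)
    return(list(r = NA_real_, ci = c(NA_real_, NA_real_), p = NA_real_,
                n = length(means), means = means,
                message = "zero variance: correlation undefined"))
  ct <- cor.test(age, means)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       p = ct$p.value, n = length(means), means = means)
}
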