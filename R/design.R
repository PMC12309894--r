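#' Build the voxel-wise GLM design matrix
#'
#' One indicator column per site (no global intercept; each site's beta is
#' that site's adjusted mean), followed by the covariates. Continuous
#' covariates are mean-centered over the pooled training sample, so site
#' betas are evaluated at the cohort-average covariate value; categorical
#' covariates enter as centered k-1 indicators. The centering record is kept
#' so the design is reproducible at apply time.
#'
#' @param table A [covariate_table()] (a plain data frame is validated
#'   on the fly).
#' @param covariate_names Covariates to include (original column names;
#'   categorical ones expand automatically). May be empty (dummies-only
#'   design, equivalent to per-site means).
#' @param reference_site Site whose column comes first and whose beta is the
#'   harmonization numerator.
#' @return Object of class `design_matrix`: `X` (n x p), `columns`,
#'   `site_columns`, `covariate_columns`, `sites` (per-row site label),
#'   `reference`, `centering` (named vector of subtracted means).
#' @export
build_design <- function(table, covariate_names = character(), reference_site) {
  if (!inherits(table, "covariate_table"))
    table <- covariate_table(table, covariate_names)
  sites <- unique(table$site)
  if (!reference_site %in% sites)
    stop("reference site '", reference_site, "' not present; sites: ",
         paste(sites, collapse = ", "), call. = FALSE)
  if (length(sites) < 2)
    stop("need at least 2 sites", call. = FALSE)
  site_levels <- c(reference_site, sort(setdiff(sites, reference_site)))
  S <- vapply(site_levels, function(s) as.numeric(table$site == s),
              numeric(nrow(table)))
  colnames(S) <- site_levels

  cov_cols <- resolve_covariate_columns(table, covariate_names)
  missing <- setdiff(cov_cols, names(table))
  if (length(missing))
    stop("covariates not found in table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  centering <- setNames(numeric(0), character(0))
  Xc <- NULL
  if (length(cov_cols)) {
    Xc <- as.matrix(as.data.frame(table)[, cov_cols, drop = FALSE])
    storage.mode(Xc) <- "double"
    mns <- colMeans(Xc)
    Xc <- sweep(Xc, 2, mns)
    centering <- setNames(mns, cov_cols)
  }
  X <- cbind(S, Xc)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  structure(list(X = X, columns = colnames(X), site_columns = site_levels,
                 covariate_columns = cov_cols, sites = table$site,
                 reference = reference_site, centering = centering),
            class = "design_matrix")
}

# Map user-facing covariate names to the (possibly expanded) columns of a
# covariate_table: a categorical covariate 'sex' with levels F/M became 'sexM'.
resolve_covariate_columns <- function(table, covariate_names) {
  cat_enc <- attr(table, "categorical")
  unlist(lapply(covariate_names, function(nm) {
    if (!is.null(cat_enc[[nm]]))
      paste0(nm, cat_enc[[nm]]$levels[-1])
    else nm
  }), use.names = FALSE)
}
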