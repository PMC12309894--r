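#' Rotational invariant spherical harmonic (RISH) features
#'
#' For each even order l the RISH feature is the SH energy
#' L_l = sum_m c_{l,m}^2, which is invariant to rotations of the head or of
#' the sampling directions.
#'
#' @param coeffs An `sh_image` (see [fit_sh()]).
#' @return Object of class `rish_image`: `features` (X x Y x Z x K array,
#'   channel k holding order l = 2(k-1)), `orders`, `mask`, `bvalue`.
#' @export
compute_rish <- function(coeffs) {
  stopifnot(inherits(coeffs, "sh_image"))
  dims <- dim(coeffs$coeffs)
  orders <- seq(0, coeffs$max_order, by = 2)
  C <- matrix(coeffs$coeffs, prod(dims[1:3]), dims[4])
  feats <- vapply(orders, function(l) {
    cols <- which(coeffs$index_map$l == l)
    rowSums(C[, cols, drop = FALSE]^2)
  }, numeric(nrow(C)))
  structure(list(features = array(feats, c(dims[1:3], length(orders))),
                 orders = orders, mask = coeffs$mask, bvalue = coeffs$bvalue),
            class = "rish_image")
}

#' Rescale SH coefficients so each order's RISH feature is multiplied
#'
#' Every coefficient of order l is multiplied by sqrt(theta_l) so the output
#' energy is exactly theta_l * L_l. Voxels flagged invalid in the scaling
#' maps carry theta = 1 and pass through unscaled; their count inside the
#' mask is attached as attribute `n_invalid`.
#'
#' @param coeffs An `sh_image`.
#' @param scaling A `scaling_maps` object (see [scaling_from_means()]).
#' @return A rescaled `sh_image`.
#' @export
apply_rish_scaling <- function(coeffs, scaling) {
  stopifnot(inherits(coeffs, "sh_image"), inherits(scaling, "scaling_maps"))
  dims <- dim(coeffs$coeffs)
  if (!identical(as.integer(dim(scaling$valid)), as.integer(dims[1:3])))
    stop("scaling maps are on a different voxel grid than the coefficients",
         call. = FALSE)
  orders <- seq(0, coeffs$max_order, by = 2)
  if (!all(orders %in% scaling$orders))
    stop("scaling maps lack orders: ",
         paste(setdiff(orders, scaling$orders), collapse = ", "), call. = FALSE)
  C <- matrix(coeffs$coeffs, prod(dims[1:3]), dims[4])
  for (l in orders) {
    fac <- sqrt(as.numeric(scaling$theta[[paste0("L", l)]]))
    cols <- which(coeffs$index_map$l == l)
    C[, cols] <- C[, cols, drop = FALSE] * fac
  }
  res <- coeffs
  res$coeffs <- array(C, dims)
  attr(res, "n_invalid") <- sum(!scaling$valid & coeffs$mask)
  res
}
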