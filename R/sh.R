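#' Number of real even-order spherical harmonic coefficients
#'
#' @param max_order Even, non-negative maximum SH order.
#' @return `(max_order + 1) * (max_order + 2) / 2`.
#' @export
num_sh_coefficients <- function(max_order) {
  check_even_order(max_order)
  as.integer((max_order + 1) * (max_order + 2) / 2)
}

check_even_order <- function(max_order) {
  if (length(max_order) != 1 || !is.finite(max_order) || max_order < 0 ||
      max_order %% 2 != 0)
    stop("max_order must be a single even non-negative integer", call. = FALSE)
  invisible(max_order)
}

#' Index map of an even-order real SH basis
#'
#' Coefficients are ordered by order l ascending and degree m ascending
#' within each order (m = -l, ..., l).
#'
#' @inheritParams num_sh_coefficients
#' @return Data frame with columns `l` and `m`, one row per coefficient.
#' @export
sh_index_map <- function(max_order) {
  check_even_order(max_order)
  ls <- seq(0, max_order, by = 2)
  data.frame(
    l = rep(ls, times = 2 * ls + 1),
    m = unlist(lapply(ls, function(l) seq(-l, l)))
  )
}

#' Spherical harmonic fitting specification
#'
#' @param max_order Maximum even SH order (default 6).
#' @param lambda L2 regularization weight (default 5e-3).
#' @param regularizer `"laplace_beltrami"` (penalty l^2 (l+1)^2 per
#'   coefficient, leaving l = 0 untouched) or `"identity"` (ridge).
#' @return Object of class `sh_basis_spec`.
#' @export
sh_basis_spec <- function(max_order = 6, lambda = 5e-3,
                          regularizer = c("laplace_beltrami", "identity")) {
  check_even_order(max_order)
  regularizer <- match.arg(regularizer)
  if (length(lambda) != 1 || !is.finite(lambda) || lambda < 0)
    stop("lambda must be a single non-negative number", call. = FALSE)
  structure(list(max_order = as.integer(max_order), lambda = lambda,
                 regularizer = regularizer), class = "sh_basis_spec")
}

#' Real even-order spherical harmonic design matrix
#'
#' Real, antipodally symmetric convention with orthonormal normalization:
#' the column for (l, m) evaluates sqrt(2) * Im(Y_l^|m|) for m < 0, the real
#' m = 0 harmonic for m = 0, and sqrt(2) * Re(Y_l^m) for m > 0, with the
#' Condon-Shortley phase carried by the associated Legendre functions.
#'
#' @param directions N x 3 matrix of unit vectors.
#' @param max_order Maximum even order.
#' @return N x M design matrix, with the [sh_index_map()] attached as
#'   attribute `index_map`.
#' @export
sh_basis <- function(directions, max_order) {
  check_even_order(max_order)
  directions <- as.matrix(directions)
  if (ncol(directions) != 3) stop("directions must be N x 3", call. = FALSE)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-4))
    stop("directions must be unit vectors (max deviation ",
         format(max(abs(nrm - 1))), ")", call. = FALSE)
  z <- pmin(pmax(directions[, 3] / nrm, -1), 1)
  phi <- atan2(directions[, 2], directions[, 1])
  n <- nrow(directions)
  imap <- sh_index_map(max_order)
  B <- matrix(0, n, nrow(imap))
  col <- 1L
  for (l in seq(0, max_order, by = 2)) {
    P <- pracma::legendre(l, z) # (l+1) x n, rows m = 0..l, Condon-Shortley
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    for (m in seq(-l, l)) {
      am <- abs(m)
      # orthonormal normalization sqrt((2l+1)/(4 pi) (l-m)!/(l+m)!)
      N <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      B[, col] <- if (m < 0) {
        sqrt(2) * N * P[am + 1, ] * sin(am * phi)
      } else if (m == 0) {
        N * P[1, ]
      } else {
        sqrt(2) * N * P[am + 1, ] * cos(am * phi)
      }
      col <- col + 1L
    }
  }
  attr(B, "index_map") <- imap
  B
}

#' Diagonal of the SH regularizer matrix
#'
#' @inheritParams num_sh_coefficients
#' @param regularizer `"laplace_beltrami"` or `"identity"`.
#' @return Numeric vector of length M (the per-coefficient penalty).
#' @export
sh_regularizer <- function(max_order, regularizer = c("laplace_beltrami", "identity")) {
  regularizer <- match.arg(regularizer)
  imap <- sh_index_map(max_order)
  if (regularizer == "laplace_beltrami") imap$l^2 * (imap$l + 1)^2 else rep(1, nrow(imap))
}

#' Fit spherical harmonic coefficients to shell signals
#'
#' Per voxel solves the L2-regularized least-squares problem
#' c = (B'B + lambda R)^-1 B' s. With `lambda = 0` the direction count must
#' be at least the coefficient count.
#'
#' @param shell A `shell_data` object (see [select_shell()]).
#' @param spec An [sh_basis_spec()].
#' @param mask Optional 3D logical array; voxels outside are set to zero.
#' @return Object of class `sh_image`: `coeffs` (X x Y x Z x M array),
#'   `index_map`, `max_order`, `bvalue`, `mask`, `spec`.
#' @export
fit_sh <- function(shell, spec = sh_basis_spec(), mask = NULL) {
  stopifnot(inherits(shell, "shell_data"))
  dims <- dim(shell$dwi_signals)
  n_dir <- dims[4]
  M <- num_sh_coefficients(spec$max_order)
  if (spec$lambda == 0 && n_dir < M)
    stop(sprintf("%d directions cannot support %d coefficients with lambda = 0",
                 n_dir, M), call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  mask <- array(as.logical(mask), dims[1:3])
  B <- sh_basis(shell$directions, spec$max_order)
  Rdiag <- sh_regularizer(spec$max_order, spec$regularizer)
  A <- crossprod(B) + spec$lambda * diag(Rdiag, nrow = M)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  cond <- max(ev) / max(min(ev), .Machine$double.eps)
  if (min(ev) <= max(ev) * 1e-14)
    stop(sprintf("singular SH normal matrix (condition number %.3g); degenerate direction set?",
                 cond), call. = FALSE)
  if (cond > 1e8)
    warning(sprintf("ill-conditioned SH normal matrix (condition number %.3g)", cond))
  Pinv <- solve(A, t(B)) # M x n_dir
  S <- matrix(shell$dwi_signals, prod(dims[1:3]), n_dir)
  C <- matrix(0, prod(dims[1:3]), M)
  idx <- which(mask)
  C[idx, ] <- S[idx, , drop = FALSE] %*% t(Pinv)
  coeffs <- array(C, c(dims[1:3], M))
  structure(list(coeffs = coeffs, index_map = attr(B, "index_map"),
                 max_order = spec$max_order, bvalue = shell$bvalue,
                 mask = mask, spec = spec),
            class = "sh_image")
}

#' Reconstruct shell signals from SH coefficients
#'
#' Negative reconstructed values (non-physical for magnitude MR data) are
#' clipped to zero at output; the number of clipped samples is attached as
#' attribute `n_clipped`.
#'
#' @param coeffs An `sh_image`.
#' @param directions N x 3 unit vectors at which to evaluate the signal.
#' @return 4D array X x Y x Z x N of reconstructed signals.
#' @export
sh_reconstruct <- function(coeffs, directions) {
  stopifnot(inherits(coeffs, "sh_image"))
  B <- sh_basis(directions, coeffs$max_order)
  dims <- dim(coeffs$coeffs)
  C <- matrix(coeffs$coeffs, prod(dims[1:3]), dims[4])
  S <- C %*% t(B)
  n_clipped <- sum(S < 0 & matrix(coeffs$mask, nrow(S), ncol(S)))
  S[S < 0] <- 0
  out <- array(S, c(dims[1:3], nrow(directions)))
  attr(out, "n_clipped") <- n_clipped
  out
}
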