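#' Log-linear least-squares diffusion tensor fit
#'
#' Per voxel solves log(S/S0) = -b g' D g for the six unique tensor
#' elements. Signals are floored at `floor_frac * S0` before the log.
#' Eigenvalues are computed in closed form (symmetric 3x3); negative
#' eigenvalues are permitted (noise) but counted.
#'
#' @param shell A `shell_data` (needs >= 6 non-collinear directions).
#' @param mask Optional 3D logical array.
#' @param floor_frac Signal floor as a fraction of S0 (default 1e-6).
#' @return Object of class `tensor_image`: `D` (X x Y x Z x 6, order xx,
#'   yy, zz, xy, xz, yz in mm^2/s), `evals` (X x Y x Z x 3, descending),
#'   `mask`, `n_negative_evals`.
#' @export
fit_dti <- function(shell, mask = NULL, floor_frac = 1e-6) {
  stopifnot(inherits(shell, "shell_data"))
  dims <- dim(shell$dwi_signals)
  if (dims[4] < 6) stop("tensor fit needs >= 6 directions", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  mask <- array(as.logical(mask), dims[1:3])
  g <- shell$directions
  b <- shell$bvalue
  G <- -b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                  2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  qrG <- qr(G)
  if (qrG$rank < 6)
    stop("degenerate direction set: tensor design has rank ", qrG$rank, call. = FALSE)
  H <- chol2inv(chol(crossprod(G))) %*% t(G) # 6 x N
  S0 <- as.numeric(shell$b0_mean)
  S0[S0 <= 0] <- NA_real_
  S <- matrix(shell$dwi_signals, prod(dims[1:3]), dims[4])
  floor_v <- floor_frac * S0
  Sl <- pmax(S, floor_v) # recycles floor_v down columns
  Y <- log(Sl / S0)
  Dm <- matrix(0, prod(dims[1:3]), 6)
  idx <- which(mask & is.finite(S0))
  Dm[idx, ] <- Y[idx, , drop = FALSE] %*% t(H)
  ev <- sym3_eigenvalues(Dm)
  ev[setdiff(seq_len(nrow(ev)), idx), ] <- 0
  structure(list(D = array(Dm, c(dims[1:3], 6)),
                 evals = array(ev, c(dims[1:3], 3)),
                 mask = mask,
                 n_negative_evals = sum(ev[idx, ] < 0)),
            class = "tensor_image")
}

# Closed-form eigenvalues of symmetric 3x3 matrices, vectorized over rows
# (columns xx, yy, zz, xy, xz, yz); returned in descending order.
sym3_eigenvalues <- function(Dm) {
  a <- Dm[, 1]; b <- Dm[, 2]; c <- Dm[, 3]
  d <- Dm[, 4]; e <- Dm[, 5]; f <- Dm[, 6]
  q <- (a + b + c) / 3
  p2 <- (a - q)^2 + (b - q)^2 + (c - q)^2 + 2 * (d^2 + e^2 + f^2)
  p <- sqrt(pmax(p2, 0) / 6)
  iso <- p < .Machine$double.eps * (abs(q) + 1)
  A1 <- a - q; B1 <- b - q; C1 <- c - q
  detB <- A1 * (B1 * C1 - f^2) - d * (d * C1 - f * e) + e * (d * f - B1 * e)
  r <- detB / (2 * pmax(p, .Machine$double.xmin)^3)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  out <- cbind(l1, l2, l3)
  out[iso, 1] <- out[iso, 2] <- out[iso, 3] <- q[iso]
  out
}

#' Fractional anisotropy and mean diffusivity maps
#'
#' MD = mean eigenvalue; FA = sqrt(3/2) ||lambda - MD|| / ||lambda||,
#' defined as 0 where the tensor is all zero.
#'
#' @param tensor A `tensor_image`.
#' @return List with 3D arrays `fa` and `md`.
#' @export
fa_md <- function(tensor) {
  stopifnot(inherits(tensor, "tensor_image"))
  dims <- dim(tensor$evals)
  ev <- matrix(tensor$evals, prod(dims[1:3]), 3)
  md <- rowMeans(ev)
  num <- sqrt(rowSums((ev - md)^2))
  den <- sqrt(rowSums(ev^2))
  fa <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  list(fa = array(fa, dims[1:3]), md = array(md, dims[1:3]))
}
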