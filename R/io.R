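#' Gradient table for a diffusion acquisition
#'
#' Bundles b-values and unit gradient directions. Directions paired with a
#' b-value above `b0_threshold` are normalized to unit length; zero vectors
#' are only accepted for b=0 volumes.
#'
#' @param bvals Numeric vector of diffusion weightings (s/mm^2), length N.
#' @param bvecs N x 3 numeric matrix of gradient directions (image frame).
#' @param b0_threshold b-values at or below this count as b=0 (default 50).
#' @return An object of class `gradient_table` with elements `bvals`,
#'   `bvecs` (unit rows for diffusion-weighted volumes), `b0_threshold`.
#' @export
gradient_table <- function(bvals, bvecs, b0_threshold = 50) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3 && nrow(bvecs) == 3) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3)
    stop("bvecs must be an N x 3 (or 3 x N) matrix", call. = FALSE)
  if (length(bvals) != nrow(bvecs))
    stop(sprintf("bval/bvec count mismatch: %d b-values vs %d vectors",
                 length(bvals), nrow(bvecs)), call. = FALSE)
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("b-values must be finite and non-negative", call. = FALSE)
  nrm <- sqrt(rowSums(bvecs^2))
  dw <- bvals > b0_threshold
  if (any(dw & nrm < 1e-8))
    stop("zero gradient vector paired with a diffusion-weighted b-value",
         call. = FALSE)
  bvecs[dw, ] <- bvecs[dw, , drop = FALSE] / nrm[dw]
  bvecs[!dw & nrm < 1e-8, ] <- 0
  structure(list(bvals = bvals, bvecs = bvecs, b0_threshold = b0_threshold),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  shells <- sort(unique(round(x$bvals[x$bvals > x$b0_threshold], -1)))
  cat(sprintf("gradient table: %d volumes, %d b=0, shells ~ {%s} s/mm^2\n",
              length(x$bvals), sum(x$bvals <= x$b0_threshold),
              paste(shells, collapse = ", ")))
  invisible(x)
}

read_bvalbvec <- function(bval_path, bvec_path) {
  if (!file.exists(bval_path)) stop("bval file not found: ", bval_path, call. = FALSE)
  if (!file.exists(bvec_path)) stop("bvec file not found: ", bvec_path, call. = FALSE)
  bvals <- scan(bval_path, quiet = TRUE)
  raw <- lapply(strsplit(trimws(readLines(bvec_path)), "\\s+"), as.numeric)
  raw <- raw[lengths(raw) > 0]
  bv <- do.call(rbind, raw)
  # FSL dialect: 3 rows x N; accept N x 3 as well (auto-detect by shape)
  if (nrow(bv) == 3 && ncol(bv) != 3) bv <- t(bv)
  if (nrow(bv) == 3 && ncol(bv) == 3) bv <- t(bv) # ambiguous 3x3: treat rows as components
  if (ncol(bv) != 3)
    stop("bvec file is not 3 x N or N x 3: ", bvec_path, call. = FALSE)
  list(bvals = bvals, bvecs = bv)
}

#' Read a diffusion-weighted NIfTI volume with its gradient scheme
#'
#' @param image_path Path to a 4D NIfTI image (.nii or .nii.gz).
#' @param bval_path,bvec_path FSL-dialect whitespace text files.
#' @param b0_threshold Passed to [gradient_table()].
#' @return An object of class `dwi_volume`: `data` (4D array), `affine`
#'   (4 x 4), `gradients` (a `gradient_table`).
#' @export
read_dwi <- function(image_path, bval_path, bvec_path, b0_threshold = 50) {
  if (!file.exists(image_path)) stop("image not found: ", image_path, call. = FALSE)
  img <- RNifti::readNifti(image_path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 4)
    stop("expected a 4D image, got ", length(dim(arr)), "D: ", image_path, call. = FALSE)
  g <- read_bvalbvec(bval_path, bvec_path)
  if (length(g$bvals) != dim(arr)[4])
    stop(sprintf("gradient count mismatch: image has %d volumes, bval file has %d entries",
                 dim(arr)[4], length(g$bvals)), call. = FALSE)
  gt <- gradient_table(g$bvals, g$bvecs, b0_threshold)
  dwi_volume(arr, affine = RNifti::xform(img), gradients = gt)
}

#' Construct a DWI volume object from in-memory pieces
#'
#' @param data 4D array X x Y x Z x N of non-negative signal intensities.
#' @param affine 4 x 4 voxel-to-world matrix (defaults to identity spacing).
#' @param gradients A [gradient_table()].
#' @return Object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, affine = diag(4), gradients) {
  stopifnot(inherits(gradients, "gradient_table"))
  if (length(dim(data)) != 4)
    stop("data must be a 4D array", call. = FALSE)
  if (dim(data)[4] != length(gradients$bvals))
    stop("4th dimension does not match gradient table", call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4 x 4 matrix", call. = FALSE)
  structure(list(data = data, affine = affine, gradients = gradients),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("dwi_volume: %d x %d x %d grid, %d volumes\n", d[1], d[2], d[3], d[4]))
  print(x$gradients)
  invisible(x)
}

#' Extract one shell (plus the mean b=0 image) from a DWI volume
#'
#' Harmonization operates per shell; this selects the volumes whose b-value
#' is within `tol` of `target_b` and averages all b=0 volumes.
#'
#' @param dwi A `dwi_volume`.
#' @param target_b Nominal shell b-value (s/mm^2).
#' @param tol Shell tolerance (default 100 s/mm^2, robust to vendor rounding).
#' @return Object of class `shell_data`: `dwi_signals` (X x Y x Z x M),
#'   `directions` (M x 3 unit vectors), `bvalue`, `b0_mean` (3D array).
#' @export
select_shell <- function(dwi, target_b, tol = 100) {
  stopifnot(inherits(dwi, "dwi_volume"))
  gt <- dwi$gradients
  in_shell <- abs(gt$bvals - target_b) <= tol & gt$bvals > gt$b0_threshold
  is_b0 <- gt$bvals <= gt$b0_threshold
  if (!any(in_shell))
    stop(sprintf("no volumes within %g of b=%g; available b-values: %s",
                 tol, target_b, paste(sort(unique(gt$bvals)), collapse = ", ")),
         call. = FALSE)
  if (!any(is_b0))
    stop("no b=0 volume found (required for reference signal)", call. = FALSE)
  b0 <- dwi$data[, , , is_b0, drop = FALSE]
  b0_mean <- apply(b0, 1:3, mean)
  structure(list(
    dwi_signals = dwi$data[, , , in_shell, drop = FALSE],
    directions = gt$bvecs[in_shell, , drop = FALSE],
    bvalue = target_b,
    b0_mean = b0_mean
  ), class = "shell_data")
}

#' Write a DWI volume as NIfTI + bval/bvec text files
#'
#' Image data are written as 32-bit float; bvecs are written in the 3-row
#' dialect readable by [read_dwi()].
#'
#' @param dwi A `dwi_volume`.
#' @param image_path,bval_path,bvec_path Output paths.
#' @return Invisibly, `image_path`.
#' @export
write_dwi <- function(dwi, image_path, bval_path, bvec_path) {
  stopifnot(inherits(dwi, "dwi_volume"))
  img <- RNifti::asNifti(dwi$data, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(dwi$affine, code = 2L))
  tryCatch({
    RNifti::writeNifti(img, image_path)
    writeLines(paste(format(dwi$gradients$bvals, trim = TRUE, scientific = FALSE),
                     collapse = " "), bval_path)
    bv <- t(dwi$gradients$bvecs)
    writeLines(apply(bv, 1, function(r)
      paste(formatC(r, digits = 9, format = "g"), collapse = " ")), bvec_path)
  }, error = function(e) {
    stop(sprintf("failed writing DWI to %s / %s / %s: %s",
                 image_path, bval_path, bvec_path, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(image_path)
}

#' Read and validate a covariate table
#'
#' Categorical covariates (character or factor columns) with k levels are
#' expanded into k-1 indicator columns against the lexicographically first
#' level; the expansion is recorded so designs built later are reproducible.
#'
#' @param csv_path CSV file with a header row.
#' @param covariate_columns Character vector of covariate column names.
#' @param site_column,id_column Names of the site and subject-id columns.
#' @return A `data.frame` of class `covariate_table` with columns
#'   `subject_id`, `site`, the numeric covariates, and any extra columns
#'   (e.g. file paths) untouched. Attribute `covariates` lists the expanded
#'   covariate column names; `categorical` records the encodings.
#' @export
read_covariates <- function(csv_path, covariate_columns = character(),
                            site_column = "site", id_column = "subject_id") {
  if (!file.exists(csv_path)) stop("covariate file not found: ", csv_path, call. = FALSE)
  df <- read.csv(csv_path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(id_column, site_column, covariate_columns), names(df))
  if (length(missing_cols))
    stop("missing columns in ", csv_path, ": ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  names(df)[names(df) == id_column] <- "subject_id"
  names(df)[names(df) == site_column] <- "site"
  df$site <- as.character(df$site)
  df$subject_id <- as.character(df$subject_id)
  covariate_table(df, covariate_columns)
}

#' Validate an in-memory covariate table
#'
#' @param df Data frame with columns `subject_id`, `site` and the covariates.
#' @param covariate_columns Covariate column names to declare.
#' @return The validated, covariate-expanded `covariate_table`.
#' @export
covariate_table <- function(df, covariate_columns = character()) {
  stopifnot(is.data.frame(df))
  if (!all(c("subject_id", "site") %in% names(df)))
    stop("covariate table needs 'subject_id' and 'site' columns", call. = FALSE)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "),
         call. = FALSE)
  tab <- table(df$site)
  if (any(tab < 2))
    stop("every site needs >= 2 subjects; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  for (cc in covariate_columns) {
    bad <- which(is.na(df[[cc]]) | (is.character(df[[cc]]) & df[[cc]] == ""))
    if (length(bad))
      stop(sprintf("missing values in covariate '%s' (rows %s)", cc,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  categorical <- list()
  expanded <- character()
  for (cc in covariate_columns) {
    v <- df[[cc]]
    if (is.character(v) || is.factor(v) || is.logical(v)) {
      v <- as.character(v)
      lev <- sort(unique(v))
      # a single observed level expands to zero indicator columns: the
      # covariate is constant and carries no information
      for (l in lev[-1]) {
        col <- paste0(cc, l)
        df[[col]] <- as.numeric(v == l)
        expanded <- c(expanded, col)
      }
      categorical[[cc]] <- list(levels = lev, reference = lev[1])
      df[[cc]] <- NULL
    } else {
      if (any(!is.finite(v)))
        stop(sprintf("non-finite values in covariate '%s'", cc), call. = FALSE)
      expanded <- c(expanded, cc)
    }
  }
  structure(df, class = c("covariate_table", "data.frame"),
            covariates = expanded, categorical = categorical)
}
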