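#' Save a harmonization model to a directory
#'
#' Layout: `metadata.json` plus one float32 NIfTI per (target site, order)
#' scaling map, a validity mask per target, and — for GLM models — one
#' NIfTI per design column and order plus residual-variance maps.
#'
#' @param model A `harmonization_model`.
#' @param directory Output directory (created if needed).
#' @return Invisibly, `directory`.
#' @export
save_model <- function(model, directory) {
  stopifnot(inherits(model, "harmonization_model"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    version = model$version, method = model$method,
    reference = model$reference, targets = model$targets,
    orders = model$orders, bvalue = model$bvalue,
    grid = model$grid, clip = model$clip,
    covariates = model$covariates,
    centering = as.list(model$centering),
    spec = list(max_order = model$spec$max_order, lambda = model$spec$lambda,
                regularizer = model$spec$regularizer),
    sites_safe = as.list(setNames(sanitize(c(model$reference, model$targets)),
                                  c(model$reference, model$targets))),
    columns = if (!is.null(model$glm)) model$glm$columns else NULL,
    eps = lapply(model$scaling, function(s) s$eps)
  )
  jsonlite::write_json(meta, file.path(directory, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (tgt in model$targets) {
    sm <- model$scaling[[tgt]]
    safe <- sanitize(tgt)
    for (l in model$orders)
      write_map(sm$theta[[paste0("L", l)]],
                file.path(directory, sprintf("scaling_%s_L%d.nii.gz", safe, l)))
    write_map(array(as.numeric(sm$valid), dim(sm$valid)),
              file.path(directory, sprintf("valid_%s.nii.gz", safe)))
  }
  if (!is.null(model$glm)) {
    for (j in seq_along(model$glm$columns)) {
      safe <- sanitize(model$glm$columns[j])
      for (l in model$orders)
        write_map(slice4(model$glm$betas[[paste0("L", l)]], j),
                  file.path(directory, sprintf("beta_%s_L%d.nii.gz", safe, l)))
    }
    for (l in model$orders)
      write_map(model$glm$resvar[[paste0("L", l)]],
                file.path(directory, sprintf("resvar_L%d.nii.gz", l)))
    write_map(array(as.numeric(model$glm$mask), dim(model$glm$mask)),
              file.path(directory, "glm_mask.nii.gz"))
  }
  invisible(directory)
}

sanitize <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

write_map <- function(arr, path) {
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), path)
}

read_map <- function(path) {
  if (!file.exists(path)) stop("model file missing: ", path, call. = FALSE)
  as.array(RNifti::readNifti(path))
}

#' Load a harmonization model saved by [save_model()]
#'
#' @param directory Model directory.
#' @return A `harmonization_model`; maps round-trip within float32
#'   precision, metadata exactly.
#' @export
load_model <- function(directory) {
  meta_path <- file.path(directory, "metadata.json")
  if (!file.exists(meta_path))
    stop("not a model directory (no metadata.json): ", directory, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$version) || !startsWith(meta$version, "rishglm"))
    stop("unrecognized model metadata in ", meta_path, call. = FALSE)
  orders <- as.integer(meta$orders)
  spec <- sh_basis_spec(meta$spec$max_order, meta$spec$lambda, meta$spec$regularizer)
  targets <- as.character(meta$targets)
  scaling <- lapply(targets, function(tgt) {
    safe <- sanitize(tgt)
    theta <- lapply(orders, function(l)
      read_map(file.path(directory, sprintf("scaling_%s_L%d.nii.gz", safe, l))))
    names(theta) <- paste0("L", orders)
    valid <- read_map(file.path(directory, sprintf("valid_%s.nii.gz", safe))) > 0.5
    structure(list(theta = theta, valid = valid, orders = orders,
                   reference = meta$reference, target = tgt,
                   clip = as.numeric(meta$clip),
                   eps = as.numeric(meta$eps[[tgt]]),
                   n_invalid = sum(!valid)),
              class = "scaling_maps")
  })
  names(scaling) <- targets
  glm_fit <- NULL
  if (identical(meta$method, "glm") && !is.null(meta$columns)) {
    columns <- as.character(meta$columns)
    dims <- as.integer(meta$grid)
    betas <- resvar <- list()
    for (l in orders) {
      barr <- array(0, c(dims, length(columns)))
      for (j in seq_along(columns))
        barr[, , , j] <- read_map(file.path(directory,
          sprintf("beta_%s_L%d.nii.gz", sanitize(columns[j]), l)))
      betas[[paste0("L", l)]] <- barr
      resvar[[paste0("L", l)]] <- read_map(file.path(directory,
        sprintf("resvar_L%d.nii.gz", l)))
    }
    centering <- unlist(meta$centering)
    if (is.null(centering)) centering <- setNames(numeric(0), character(0))
    glm_fit <- structure(list(
      betas = betas, resvar = resvar, columns = columns,
      site_columns = c(meta$reference, targets),
      covariate_columns = setdiff(columns, c(meta$reference, targets)),
      reference = meta$reference, centering = centering,
      orders = orders,
      mask = read_map(file.path(directory, "glm_mask.nii.gz")) > 0.5),
      class = "glm_maps")
  }
  structure(list(reference = meta$reference, targets = targets,
                 orders = orders, bvalue = as.numeric(meta$bvalue),
                 method = meta$method, spec = spec, scaling = scaling,
                 glm = glm_fit,
                 covariates = as.character(meta$covariates %||% character()),
                 centering = if (!is.null(glm_fit)) glm_fit$centering else NULL,
                 grid = as.integer(meta$grid), clip = as.numeric(meta$clip),
                 version = meta$version),
            class = "harmonization_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
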