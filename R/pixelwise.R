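#' Voxelwise IVIM parameter maps
#'
#' Applies a per-voxel estimator to every in-mask voxel of a 4D
#' diffusion-weighted volume and returns 3D parameter maps. Two estimators
#' are available: `"segmented"` (conventional segmented bi-exponential
#' fit, maps `pf_i`, `d_slow`, `d_fast`) and `"yi"` (the shifted-start
#' log-odds estimator, maps `d_slow`, `d_fast_yi`, `f_fast`, `f_tot`,
#' `f_vfast`, `r_squared`). Out-of-mask voxels are `NA`; every map is
#' accompanied by a `qc` map (1 = pass, 0 = fail, `NA` = outside mask).
#'
#' @param volume 4D numeric array (or `niftiImage`) with the diffusion
#'   dimension last, matching the scheme length.
#' @param scheme Acquisition-scheme tibble describing the 4th axis.
#' @param mask 3D array; voxels with value > 0.5 are fitted.
#' @param method `"segmented"` or `"yi"`.
#' @param b_start Fit-starting b-value for the segmented method.
#' @param b_grid Grid of starting b-values for the `"yi"` method.
#' @param threshold High-b threshold (default 60).
#'
#' @return A named list of 3D arrays (one per parameter, plus `qc`).
#' @export
pixelwise_map <- function(volume, scheme, mask,
                          method = c("segmented", "yi"), b_start = 0,
                          b_grid = c(2, 4, 7, 10, 15, 20), threshold = 60) {
  method <- match.arg(method)
  check_scheme(scheme)
  arr <- as.array(volume)
  if (length(dim(arr)) != 4) {
    stop("pixelwise_map: volume must be 4D", call. = FALSE)
  }
  if (dim(arr)[4] != nrow(scheme)) {
    stop("pixelwise_map: 4th axis does not match the scheme", call. = FALSE)
  }
  mask <- conform_mask(as.array(mask) > 0.5, dim(arr)[1:3])
  if (!all(dim(mask) == dim(arr)[1:3])) {
    stop("pixelwise_map: mask does not match the spatial dimensions",
         call. = FALSE)
  }
  par_names <- if (method == "segmented") {
    c("pf_i", "d_slow", "d_fast")
  } else {
    c("d_slow", "d_fast_yi", "f_fast", "f_tot", "f_vfast", "r_squared")
  }
  dims <- dim(arr)[1:3]
  maps <- c(stats::setNames(
    replicate(length(par_names), array(NA_real_, dims), simplify = FALSE),
    par_names), list(qc = array(NA_real_, dims)))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(maps)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    sig <- arr[i, j, k, ]
    vals <- rep(NA_real_, length(par_names))
    ok <- 0
    if (all(is.finite(sig)) && all(sig > 0)) {
      decay <- decay_signal(scheme, sig)
      if (method == "segmented") {
        fit <- tryCatch(segmented_fit(decay, b_start, threshold),
                        error = function(e) NULL)
        if (!is.null(fit)) {
          vals <- c(fit$pf_i, fit$d_slow, fit$d_fast)
          ok <- as.numeric(fit$converged)
        }
      } else {
        fit <- tryCatch(yi_pipeline(decay, b_grid = b_grid,
                                    threshold = threshold),
                        error = function(e) NULL)
        if (!is.null(fit) && !is.null(fit$params)) {
          vals <- c(fit$regression$d_slow, fit$params$d_fast_yi,
                    fit$params$f_fast, fit$params$f_tot, fit$params$f_vfast,
                    fit$regression$r_squared)
          ok <- as.numeric(fit$qc$pass)
        }
      }
    }
    for (p in seq_along(par_names)) maps[[p]][i, j, k] <- vals[p]
    maps$qc[i, j, k] <- ok
  }
  maps
}

#' Write parameter maps as NIfTI volumes
#'
#' Writes each 3D map produced by [pixelwise_map()] as
#' `<dir>/<name>.nii.gz`, inheriting the spatial header of the reference
#' image so the maps overlay the input geometry without resampling.
#'
#' @param maps Named list of 3D arrays.
#' @param reference The input `niftiImage` (or a path readable by
#'   [RNifti::readNifti()]) supplying the spatial header.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_param_maps <- function(maps, reference, dir) {
  if (is.character(reference)) reference <- RNifti::readNifti(reference)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(maps), function(nm) {
    img <- RNifti::asNifti(maps[[nm]], reference = reference)
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(img, p)
    p
  }, character(1))
  invisible(paths)
}

# Pad trailing singleton spatial dimensions a NIfTI reader may have dropped.
conform_mask <- function(mask, dims) {
  dm <- dim(mask)
  if (is.null(dm)) dm <- length(mask)
  while (length(dm) < length(dims) &&
         all(utils::tail(dims, length(dims) - length(dm)) == 1)) {
    dm <- c(dm, 1L)
  }
  dim(mask) <- dm
  mask
}
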