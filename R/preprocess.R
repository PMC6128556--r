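## Volume preprocessing: smoothing, factor-2 downsampling, masking /
## vectorization, global-mean scaling and voxelwise age residualization.
## The pipeline order is fixed (smooth -> downsample -> vectorize ->
## scale -> residualize) and enforced through the feature-matrix stage tag.

## 1-D Gaussian convolution matrix with replicate (nearest) boundary.
## Taps are truncated at 3 sigma and renormalised to sum 1, so constant
## signals are preserved exactly and no mass is lost to truncation.
.gauss_conv_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  taps <- stats::dnorm(seq(-r, r), sd = sigma)
  taps <- taps / sum(taps)
  cm <- matrix(0, n, n)
  off <- seq(-r, r)
  for (i in seq_len(n)) {
    src <- pmin(pmax(i + off, 1L), n)
    for (t in seq_along(src)) cm[i, src[t]] <- cm[i, src[t]] + taps[t]
  }
  cm
}

.apply_along_axis <- function(x, axis, cm) {
  d <- dim(x)
  perm <- c(axis, setdiff(1:3, axis))
  y <- aperm(x, perm)
  dy <- dim(y)
  dim(y) <- c(dy[1], dy[2] * dy[3])
  y <- cm %*% y
  dim(y) <- dy
  aperm(y, order(perm))
}

#' Smooth a 3-D volume with a Gaussian kernel
#'
#' Separable Gaussian filter with per-axis standard deviation
#' \code{sigma_voxels = (fwhm_mm / voxel_size_mm) / (2 sqrt(2 ln 2))}.
#' The boundary is handled by replicating the nearest voxel, so a
#' constant volume is reproduced exactly; away from the boundary the
#' total sum of voxel values is preserved.
#'
#' @param x 3-D numeric array of voxel values.
#' @param fwhm_mm Full width at half maximum of the kernel, in mm
#'   (\code{0} is the identity).
#' @param voxel_size_mm Voxel edge lengths in mm (length 1 or 3).
#' @return A smoothed array of the same dimensions.
#' @export
gaussian_smooth <- function(x, fwhm_mm, voxel_size_mm = c(1, 1, 1)) {
  if (length(dim(x)) != 3) stop("x must be a 3-D array")
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  voxel_size_mm <- rep_len(voxel_size_mm, 3)
  if (any(voxel_size_mm <= 0)) stop("voxel_size_mm must be positive")
  if (fwhm_mm == 0) return(x)
  sigmas <- (fwhm_mm / voxel_size_mm) / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    x <- .apply_along_axis(x, ax, .gauss_conv_matrix(dim(x)[ax], sigmas[ax]))
  }
  x
}

#' Downsample a volume by a factor of two
#'
#' Each output voxel is the arithmetic mean of its 2x2x2 input block.
#' Axes with odd length lose their trailing slice (floor division), which
#' is what maps a 91x109x91 grid onto 45x54x45. The voxel size doubles.
#'
#' @param x 3-D numeric array; every dimension must be at least 2.
#' @return The block-averaged array with dimensions \code{dim(x) \%/\% 2}.
#' @export
downsample_by_two <- function(x) {
  d <- dim(x)
  if (length(d) != 3) stop("x must be a 3-D array")
  if (any(d < 2)) stop("every dimension must be at least 2")
  nd <- d %/% 2L
  x <- x[seq_len(2 * nd[1]), seq_len(2 * nd[2]), seq_len(2 * nd[3]), drop = FALSE]
  dim(x) <- c(2L, nd[1], 2L, nd[2], 2L, nd[3])
  y <- aperm(x, c(1, 3, 5, 2, 4, 6))
  dim(y) <- c(8L, prod(nd))
  out <- colMeans(y)
  dim(out) <- nd
  out
}

## Downsample a logical mask: a 2x2x2 block stays in the mask when at
## least half its input voxels are in.
.downsample_mask <- function(mask) {
  downsample_by_two(mask * 1) >= 0.5
}

#' Vectorize the in-mask voxels of a volume
#'
#' Extracts the in-mask voxels of \code{x} as a single row vector in a
#' fixed raster order (first array axis fastest, i.e. R's column-major
#' order; voxel coordinates are 1-based). The accompanying
#' \code{voxel_index} maps each column back to its (i, j, k) grid
#' coordinate, so weight vectors can be painted back onto the brain.
#'
#' @param x 3-D numeric array.
#' @param mask Logical array of the same dimensions, with at least one
#'   \code{TRUE} voxel.
#' @return A list with \code{values} (numeric vector) and
#'   \code{voxel_index} (integer matrix with columns i, j, k).
#' @seealso \code{\link{devectorize}}
#' @export
vectorize_volume <- function(x, mask) {
  if (!identical(dim(x), dim(mask))) stop("mask dimensions must match volume")
  mask <- as.logical(mask)
  dim(mask) <- dim(x)
  if (!any(mask)) stop("mask is empty")
  list(values = x[mask], voxel_index = which(mask, arr.ind = TRUE))
}

#' Paint a feature vector back onto the 3-D grid
#'
#' Inverse of \code{\link{vectorize_volume}}: in-mask voxels receive the
#' vector values, all other voxels are set to 0.
#'
#' @param values Numeric vector, one value per in-mask voxel.
#' @param voxel_index Integer matrix of (i, j, k) coordinates (1-based).
#' @param grid_dims Integer triple giving the grid dimensions.
#' @return A 3-D array.
#' @export
devectorize <- function(values, voxel_index, grid_dims) {
  voxel_index <- as.matrix(voxel_index)
  if (length(values) != nrow(voxel_index)) {
    stop("length of values must match the number of indexed voxels")
  }
  out <- array(0, dim = grid_dims)
  out[voxel_index] <- values
  out
}

#' Feature matrix container
#'
#' Bundles the subjects-by-voxels value matrix with the voxel index, the
#' subject order and a processing-stage tag. The stage tag enforces the
#' fixed pipeline order raw -> scaled -> residualized.
#'
#' @param values Numeric matrix, subjects in rows, in-mask voxels in
#'   columns.
#' @param voxel_index Integer matrix mapping columns to (i, j, k).
#' @param subject_ids Character vector of subject labels.
#' @param stage One of \code{"raw"}, \code{"scaled"},
#'   \code{"residualized"}.
#' @param grid_dims Dimensions of the (downsampled) grid the voxel index
#'   refers to.
#' @return An object of class \code{"feature_matrix"}.
#' @export
feature_matrix <- function(values, voxel_index, subject_ids,
                           stage = c("raw", "scaled", "residualized"),
                           grid_dims) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  voxel_index <- as.matrix(voxel_index)
  if (ncol(values) != nrow(voxel_index)) {
    stop("number of columns must equal the number of indexed voxels")
  }
  if (nrow(values) != length(subject_ids)) {
    stop("number of rows must equal the number of subjects")
  }
  structure(list(values = values, voxel_index = voxel_index,
                 subject_ids = as.character(subject_ids), stage = stage,
                 grid_dims = as.integer(grid_dims)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d subjects x %d in-mask voxels (stage: %s)\n",
              nrow(x$values), ncol(x$values), x$stage))
  cat(sprintf("  grid: %s\n", paste(x$grid_dims, collapse = " x ")))
  invisible(x)
}

#' Scale each subject's features by their global mean
#'
#' Divides every row (one subject's in-mask voxel values) by its mean,
#' removing inter-subject differences in overall uptake. After scaling
#' each row has mean exactly 1, so the operation is idempotent.
#'
#' @param fm A \code{"feature_matrix"} at stage \code{"raw"} (or
#'   \code{"scaled"}, in which case it is a no-op up to rounding), or a
#'   bare numeric vector (one row).
#' @return The scaled object, stage \code{"scaled"}.
#' @export
global_mean_scale <- function(fm) {
  if (is.numeric(fm) && is.null(dim(fm))) {
    m <- mean(fm)
    if (!is.finite(m) || m <= 0) stop("row mean must be positive")
    return(fm / m)
  }
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$stage == "residualized") {
    stop("cannot global-mean scale residualized features; scale before residualizing")
  }
  means <- rowMeans(fm$values)
  if (any(!is.finite(means)) || any(means <= 0)) {
    bad <- which(!is.finite(means) | means <= 0)[1]
    stop(sprintf("subject %s has non-positive global mean (corrupt volume?)",
                 fm$subject_ids[bad]))
  }
  fm$values <- fm$values / means
  fm$stage <- "scaled"
  fm
}

## Per-column OLS of values on (intercept, age); returns residuals and,
## optionally, the 2 x p coefficient matrix for applying the fit to
## held-out subjects.
.age_residuals <- function(values, ages, return_coef = FALSE) {
  if (length(unique(ages)) < 3) {
    stop("ages must contain at least 3 distinct values")
  }
  dm <- cbind(1, ages)
  qr_dm <- qr(dm)
  res <- qr.resid(qr_dm, values)
  if (!return_coef) return(res)
  list(residuals = res, coef = qr.coef(qr_dm, values))
}

#' Remove the voxelwise linear age effect
#'
#' For every voxel column, fits ordinary least squares of the scaled
#' uptake values on (intercept, age) across subjects and replaces the
#' column by its residuals. Age is known to influence global and regional
#' brain metabolism, so the GP is trained on these residuals rather than
#' the raw scaled values. Each residual column sums to zero and is
#' orthogonal to the centred age vector; the operation is idempotent.
#'
#' By default the regression is fit once on the full sample. For a
#' leakage-free variant refit within each cross-validation fold, see the
#' \code{fold_safe} argument of \code{\link{loocv}}.
#'
#' @param fm A \code{"feature_matrix"} at stage \code{"scaled"} (or
#'   \code{"residualized"}, in which case the result is unchanged).
#' @param ages Numeric vector of subject ages, in subject order, with at
#'   least 3 distinct values.
#' @return The residualized object, stage \code{"residualized"}.
#' @export
residualize_age <- function(fm, ages) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$stage == "raw") {
    stop("features must be global-mean scaled before age residualization")
  }
  if (length(ages) != nrow(fm$values)) {
    stop("length of ages must match the number of subjects")
  }
  fm$values <- .age_residuals(fm$values, ages)
  fm$stage <- "residualized"
  fm
}

#' Preprocess a set of volumes into the analysis feature matrix
#'
#' Runs the fixed preprocessing pipeline: Gaussian smoothing (12 mm FWHM
#' by default), factor-2 block downsampling of volumes and mask,
#' masking/vectorization, global-mean scaling and (optionally) voxelwise
#' age residualization.
#'
#' @param volumes 4-D numeric array (x, y, z, subject) or a list of 3-D
#'   arrays, one per subject.
#' @param mask Logical 3-D array at the input resolution.
#' @param ages Subject ages; required unless \code{residualize = FALSE}.
#' @param voxel_size_mm Voxel edge lengths of the input volumes, in mm.
#' @param fwhm_mm Smoothing kernel FWHM in mm.
#' @param downsample Apply factor-2 block downsampling.
#' @param residualize Remove the voxelwise linear age effect. Set to
#'   \code{FALSE} to obtain stage-\code{"scaled"} features for fold-safe
#'   cross-validation.
#' @param subject_ids Optional subject labels.
#' @return A list with the \code{"feature_matrix"} (\code{features}), the
#'   analysis-resolution \code{mask}, and its \code{voxel_size_mm}.
#' @export
preprocess_cohort <- function(volumes, mask, ages = NULL,
                              voxel_size_mm = c(1, 1, 1), fwhm_mm = 12,
                              downsample = TRUE, residualize = TRUE,
                              subject_ids = NULL) {
  if (is.list(volumes)) {
    volumes <- array(unlist(volumes, use.names = FALSE),
                     dim = c(dim(volumes[[1]]), length(volumes)))
  }
  if (length(dim(volumes)) != 4) stop("volumes must be a 4-D array or list of 3-D arrays")
  n <- dim(volumes)[4]
  if (is.null(subject_ids)) subject_ids <- sprintf("sub-%02d", seq_len(n))
  voxel_size_mm <- rep_len(voxel_size_mm, 3)

  proc <- vector("list", n)
  for (i in seq_len(n)) {
    v <- gaussian_smooth(volumes[, , , i], fwhm_mm, voxel_size_mm)
    if (downsample) v <- downsample_by_two(v)
    proc[[i]] <- v
  }
  out_mask <- if (downsample) .downsample_mask(mask) else
    array(as.logical(mask), dim = dim(mask))
  out_vox <- if (downsample) 2 * voxel_size_mm else voxel_size_mm

  first <- vectorize_volume(proc[[1]], out_mask)
  values <- matrix(0, n, length(first$values))
  values[1, ] <- first$values
  for (i in seq_len(n)[-1]) {
    values[i, ] <- vectorize_volume(proc[[i]], out_mask)$values
  }
  fm <- feature_matrix(values, first$voxel_index, subject_ids,
                       stage = "raw", grid_dims = dim(out_mask))
  fm <- global_mean_scale(fm)
  if (residualize) {
    if (is.null(ages)) stop("ages are required for age residualization")
    fm <- residualize_age(fm, ages)
  }
  list(features = fm, mask = out_mask, voxel_size_mm = out_vox)
}
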