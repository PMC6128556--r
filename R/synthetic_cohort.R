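## Synthetic-cohort generator. Emulates a small FDG-PET cohort (defaults:
## 16 subjects, ages 8-44, 17 test scores): each subject's uptake volume
## carries a baseline level, a smooth spatially varying linear age
## effect, a signed spatial pattern coupled to a latent cognitive factor,
## and smoothed Gaussian noise; the test scores load on the same latent
## factor with measurement noise. Volumes are generated already aligned
## to a common grid, so no registration step exists anywhere downstream.

#' Ellipsoidal voxel mask
#'
#' A voxel (1-based integer coordinates) is included when
#' \eqn{\sum_a ((x_a - c_a)/r_a)^2 \le 1}. Radii larger than the grid are
#' allowed and simply yield a full mask.
#'
#' @param grid_dims Integer triple of grid dimensions.
#' @param center Ellipsoid centre (may be fractional).
#' @param radii Positive semi-axes, in voxels.
#' @return A logical 3-D array; guaranteed non-empty.
#' @export
make_ellipsoid_mask <- function(grid_dims, center, radii) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3, length(center) == 3, length(radii) == 3)
  if (any(radii <= 0)) stop("radii must be positive")
  di <- ((seq_len(grid_dims[1]) - center[1]) / radii[1])^2
  dj <- ((seq_len(grid_dims[2]) - center[2]) / radii[2])^2
  dk <- ((seq_len(grid_dims[3]) - center[3]) / radii[3])^2
  mask <- outer(outer(di, dj, `+`), dk, `+`) <= 1
  if (!any(mask)) stop("ellipsoid contains no voxels; enlarge the radii")
  mask
}

#' Configuration of a synthetic cohort
#'
#' Collects every knob of the generator with validated defaults that
#' describe the emulated study condition: 16 subjects aged 8-44, a
#' 24 x 28 x 24 grid of 8 mm voxels (a scaled-down analogue of a
#' 91 x 109 x 91 grid of 2 mm voxels), 17 test scores loading 0.8 on a
#' single latent cognitive factor, a two-lobe signed metabolic pattern
#' (one positive, one negative ellipsoid) coupled to that factor, a
#' smooth spatial age effect, and 12 mm FWHM smoothing.
#'
#' @param n_subjects Number of subjects (at least 3).
#' @param grid_dims Volume dimensions.
#' @param voxel_size_mm Voxel edge lengths in mm.
#' @param age_range Uniform age range in years.
#' @param n_measures Number of neuropsychological measures.
#' @param loadings Coupling of the latent factor(s) to each measure, in
#'   [-1, 1]: a vector (one factor) or a matrix with up to 3 columns.
#' @param score_noise_sd Measurement noise SD of each score.
#' @param baseline_level Baseline uptake (arbitrary units).
#' @param age_slope_sd Spatial SD of the voxelwise linear age slope
#'   (units per year).
#' @param signal_beta Uptake change per unit of the latent factor inside
#'   the pattern (same arbitrary units as the baseline); 0 produces a
#'   null cohort.
#' @param pattern_rois List of ROIs, each a list with \code{center},
#'   \code{radii}, \code{sign} (+1 or -1) and optional \code{factor}
#'   index. \code{NULL} gives the two-lobe default; \code{list()} gives a
#'   null pattern.
#' @param volume_noise_sd Voxel noise SD before smoothing.
#' @param smooth_fwhm_mm Smoothing applied by the generator, in mm.
#' @param seed Integer seed fixing the whole cohort.
#' @return An object of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_subjects = 16,
                          grid_dims = c(24, 28, 24),
                          voxel_size_mm = c(8, 8, 8),
                          age_range = c(8, 44),
                          n_measures = 17,
                          loadings = rep(0.8, n_measures),
                          score_noise_sd = 0.6,
                          baseline_level = 100,
                          age_slope_sd = 0.2,
                          signal_beta = 8,
                          pattern_rois = NULL,
                          volume_noise_sd = 10,
                          smooth_fwhm_mm = 12,
                          seed = 1) {
  grid_dims <- as.integer(grid_dims)
  if (n_subjects < 3) stop("n_subjects must be at least 3")
  if (any(c(score_noise_sd, volume_noise_sd, age_slope_sd) <= 0)) {
    stop("all noise/slope SDs must be positive")
  }
  if (baseline_level <= 0) stop("baseline_level must be positive")
  if (signal_beta < 0) stop("signal_beta must be non-negative")
  if (smooth_fwhm_mm < 0) stop("smooth_fwhm_mm must be non-negative")
  if (age_range[2] <= age_range[1]) stop("age_range must be increasing")
  loadings <- as.matrix(loadings)
  if (nrow(loadings) != n_measures) {
    stop("loadings must have one row per measure")
  }
  if (ncol(loadings) > 3) stop("at most 3 latent factors are supported")
  if (any(abs(loadings) > 1)) stop("loadings must lie in [-1, 1]")

  if (is.null(pattern_rois)) {
    pattern_rois <- list(
      list(center = c(8, 10, 12), radii = c(3, 3, 3), sign = +1, factor = 1),
      list(center = c(17, 19, 13), radii = c(3, 3, 3), sign = -1, factor = 1))
  }
  signs_by_factor <- list()
  for (roi in pattern_rois) {
    if (!all(c("center", "radii", "sign") %in% names(roi))) {
      stop("each ROI needs center, radii and sign")
    }
    if (!roi$sign %in% c(-1, 1)) stop("ROI sign must be +1 or -1")
    if (any(roi$radii <= 0)) stop("ROI radii must be positive")
    if (any(roi$center - roi$radii < 1) || any(roi$center + roi$radii > grid_dims)) {
      stop("ROI ellipsoid does not fit inside the grid")
    }
    f <- as.character(roi$factor %||% 1)
    signs_by_factor[[f]] <- c(signs_by_factor[[f]], roi$sign)
  }
  for (f in names(signs_by_factor)) {
    s <- signs_by_factor[[f]]
    if (length(s) >= 2 && (all(s > 0) || all(s < 0))) {
      stop("with 2 or more ROIs per factor, both a positive and a negative ROI are required")
    }
  }

  structure(list(n_subjects = as.integer(n_subjects), grid_dims = grid_dims,
                 voxel_size_mm = rep_len(voxel_size_mm, 3),
                 age_range = age_range, n_measures = as.integer(n_measures),
                 loadings = loadings, score_noise_sd = score_noise_sd,
                 baseline_level = baseline_level, age_slope_sd = age_slope_sd,
                 signal_beta = signal_beta, pattern_rois = pattern_rois,
                 volume_noise_sd = volume_noise_sd,
                 smooth_fwhm_mm = smooth_fwhm_mm, seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: %d subjects, grid %s, %d measures\n",
              x$n_subjects, paste(x$grid_dims, collapse = "x"), x$n_measures))
  cat(sprintf("  ages %g-%g, signal_beta %g, %d pattern ROI(s), seed %d\n",
              x$age_range[1], x$age_range[2], x$signal_beta,
              length(x$pattern_rois), x$seed))
  invisible(x)
}

## Brain mask of a synthetic cohort: an ellipsoid centred on the grid
## with semi-axes 0.45 of each dimension (roughly the brain/bounding-box
## ratio of a real template).
.brain_mask <- function(grid_dims) {
  make_ellipsoid_mask(grid_dims, (grid_dims + 1) / 2, 0.45 * grid_dims)
}

#' Plant the true spatial pattern of a cohort
#'
#' Builds the signed ground-truth pattern: +1 or -1 inside each ROI
#' ellipsoid, 0 elsewhere, per latent factor. Overlapping ROIs of the
#' same factor with conflicting signs are rejected. Deterministic given
#' the configuration.
#'
#' @param config A \code{"cohort_config"}.
#' @return An object of class \code{"true_pattern"}: \code{volume} (the
#'   signed pattern of factor 1), \code{volumes} (list, one per factor)
#'   and \code{mask} (the cohort brain mask).
#' @export
plant_pattern <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_factors <- ncol(config$loadings)
  vols <- lapply(seq_len(n_factors), function(f) array(0, config$grid_dims))
  for (roi in config$pattern_rois) {
    f <- roi$factor %||% 1
    if (f > n_factors) stop("ROI refers to a factor beyond the loadings matrix")
    m <- make_ellipsoid_mask(config$grid_dims, roi$center, roi$radii)
    clash <- m & (vols[[f]] != 0) & (vols[[f]] != roi$sign)
    if (any(clash)) stop("overlapping ROIs with conflicting signs")
    vols[[f]][m] <- roi$sign
  }
  structure(list(volume = vols[[1]], volumes = vols,
                 mask = .brain_mask(config$grid_dims)),
            class = "true_pattern")
}

#' Simulate a synthetic FDG-PET cohort
#'
#' Generates, from one seed, the complete inputs of the analysis: one
#' uptake volume per subject, the neuropsychological score table, a
#' demographics table (age, sex, education), the planted ground-truth
#' pattern and the latent factor values.
#'
#' For subject i with age \eqn{a_i} and latent factor \eqn{g_i \sim N(0,1)}:
#' \itemize{
#'   \item score_ij = loadings_j g_i + N(0, score_noise_sd^2)
#'   \item uptake_iv = baseline + s_v (a_i - mean age) +
#'     signal_beta g_i P_v + N(0, volume_noise_sd^2), then smoothed with
#'     \code{smooth_fwhm_mm}, where \eqn{s_v} is a smooth spatial slope
#'     field with SD \code{age_slope_sd} and \eqn{P_v} the planted
#'     pattern.
#' }
#' Uptake values are floored at a small positive epsilon (with a warning
#' if flooring occurs). Identical configurations (including the seed)
#' yield bit-identical cohorts.
#'
#' @param config A \code{"cohort_config"}.
#' @return An object of class \code{"synthetic_cohort"}: \code{volumes}
#'   (4-D array, subject last), \code{scores}, \code{demographics} (data
#'   frames keyed by \code{subject_id}), \code{pattern}, \code{mask},
#'   \code{g} (n x factors matrix) and the \code{config}.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  n_factors <- ncol(config$loadings)
  dims <- config$grid_dims
  subject_ids <- sprintf("sub-%02d", seq_len(n))

  ages <- stats::runif(n, config$age_range[1], config$age_range[2])
  g <- matrix(stats::rnorm(n * n_factors), n, n_factors)
  scores <- g %*% t(config$loadings) +
    matrix(stats::rnorm(n * config$n_measures, sd = config$score_noise_sd),
           n, config$n_measures)
  measure_names <- if (config$n_measures == nrow(default_battery())) {
    default_battery()$measure
  } else sprintf("M%02d", seq_len(config$n_measures))
  colnames(scores) <- measure_names

  sex <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "M", "F")
  education <- pmin(20, pmax(0, round(0.45 * ages + stats::rnorm(n, sd = 1.5), 1)))

  ## smooth spatial field of voxelwise age slopes, rescaled to the
  ## configured SD
  slope <- gaussian_smooth(array(stats::rnorm(prod(dims)), dims),
                           config$smooth_fwhm_mm, config$voxel_size_mm)
  slope <- slope / stats::sd(slope) * config$age_slope_sd

  pattern <- plant_pattern(config)
  age_centered <- ages - mean(ages)

  volumes <- array(0, c(dims, n))
  clipped <- 0L
  eps <- 1e-6
  for (i in seq_len(n)) {
    v <- array(config$baseline_level, dims) + slope * age_centered[i]
    for (f in seq_len(n_factors)) {
      v <- v + config$signal_beta * g[i, f] * pattern$volumes[[f]]
    }
    v <- v + array(stats::rnorm(prod(dims), sd = config$volume_noise_sd), dims)
    v <- gaussian_smooth(v, config$smooth_fwhm_mm, config$voxel_size_mm)
    below <- v < eps
    if (any(below)) {
      clipped <- clipped + sum(below)
      v[below] <- eps
    }
    volumes[, , , i] <- v
  }
  if (clipped > 0) {
    warning(sprintf("%d voxel value(s) floored at %g to keep uptake positive",
                    clipped, eps))
  }

  structure(list(
    volumes = volumes,
    scores = data.frame(subject_id = subject_ids, scores,
                        stringsAsFactors = FALSE),
    demographics = data.frame(subject_id = subject_ids, age = ages,
                              sex = sex, education = education,
                              stringsAsFactors = FALSE),
    pattern = pattern, mask = pattern$mask, g = g,
    subject_ids = subject_ids, config = config),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, grid %s, %d measures (seed %d)\n",
              x$config$n_subjects, paste(x$config$grid_dims, collapse = "x"),
              x$config$n_measures, x$config$seed))
  cat(sprintf("  ages %.1f-%.1f, signal_beta %g\n",
              min(x$demographics$age), max(x$demographics$age),
              x$config$signal_beta))
  invisible(x)
}

.write_nifti <- function(arr, path, voxel_size_mm) {
  img <- RNifti::asNifti(arr * 1)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Writes one NIfTI volume per subject (\code{sub-XX.nii.gz}), the brain
#' mask and planted pattern as NIfTI, \code{scores.csv},
#' \code{demographics.csv}, and \code{truth.json} (latent factors plus a
#' configuration echo).
#'
#' @param cohort A \code{"synthetic_cohort"}.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- cohort$config$voxel_size_mm
  for (i in seq_along(cohort$subject_ids)) {
    .write_nifti(cohort$volumes[, , , i],
                 file.path(dir, paste0(cohort$subject_ids[i], ".nii.gz")), vs)
  }
  .write_nifti(cohort$mask, file.path(dir, "mask.nii.gz"), vs)
  .write_nifti(cohort$pattern$volume, file.path(dir, "pattern.nii.gz"), vs)
  utils::write.csv(cohort$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$demographics, file.path(dir, "demographics.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  cfg$loadings <- as.vector(cfg$loadings)
  jsonlite::write_json(
    list(g = as.vector(cohort$g), config = unclass(cfg)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by \code{\link{write_cohort}}
#'
#' Subject volumes are matched to table rows by the \code{subject_id}
#' parsed from the file names (\code{sub-<ID>.nii.gz}); a mismatch
#' between volumes and tables is an error.
#'
#' @param dir Directory containing the cohort files.
#' @return A list with \code{volumes} (4-D array), \code{mask},
#'   \code{scores}, \code{demographics}, \code{subject_ids} and
#'   \code{voxel_size_mm}.
#' @export
read_cohort <- function(dir) {
  vol_files <- sort(list.files(dir, pattern = "^sub-.*\\.nii(\\.gz)?$",
                               full.names = TRUE))
  if (!length(vol_files)) stop("no subject volumes (sub-*.nii.gz) found in ", dir)
  ids <- sub("\\.nii(\\.gz)?$", "", basename(vol_files))
  scores <- utils::read.csv(file.path(dir, "scores.csv"),
                            stringsAsFactors = FALSE)
  demographics <- utils::read.csv(file.path(dir, "demographics.csv"),
                                  stringsAsFactors = FALSE)
  if (!identical(ids, scores$subject_id) ||
      !identical(ids, demographics$subject_id)) {
    stop("subject_id mismatch between volume files and tables")
  }
  imgs <- lapply(vol_files, RNifti::readNifti)
  volumes <- array(0, c(dim(imgs[[1]]), length(imgs)))
  for (i in seq_along(imgs)) volumes[, , , i] <- imgs[[i]]
  mask_img <- RNifti::readNifti(file.path(dir, "mask.nii.gz"))
  list(volumes = volumes, mask = array(mask_img > 0.5, dim(mask_img)),
       scores = scores, demographics = demographics, subject_ids = ids,
       voxel_size_mm = RNifti::pixdim(mask_img)[1:3])
}
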