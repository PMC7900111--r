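#' Phantom generator configuration
#'
#' Describes a synthetic multisequence brain phantom: four co-registered
#' contrasts over a smooth two-tissue background inside an ellipsoidal brain
#' mask, with ellipsoidal enhancing metastases (the ground truth) and
#' curvilinear vessel-like bright confounders that are visible only on
#' sequences without flow suppression.
#'
#' The default sequence roles mimic a standard metastasis protocol:
#' \describe{
#'   \item{`t1_bravo`}{post-contrast T1 gradient echo: lesions enhance,
#'     vessels bright (no flow suppression).}
#'   \item{`t1_cube_post`}{post-contrast T1 fast spin echo: lesions enhance,
#'     vessels suppressed.}
#'   \item{`t1_cube_pre`}{pre-contrast T1 fast spin echo: no enhancement,
#'     vessels suppressed.}
#'   \item{`flair`}{T2 FLAIR: mild lesion signal, vessels visible.}
#' }
#' Because vessels are bright on some sequences and suppressed on others, a
#' model can only tell lesion from vessel by combining sequences — the same
#' ambiguity that produces false positives "in and near" vessels on clinical
#' data.
#'
#' @param grid_shape Integer length-3, array dimensions (voxels).
#' @param voxel_spacing Numeric length-3, mm per voxel.
#' @param sequence_names Character, the S sequence labels.
#' @param lesion_count_range Integer length-2 `(lo, hi)`, lesions per subject;
#'   `lo >= 1` (every subject carries at least one metastasis).
#' @param lesion_radius_range Numeric length-2, ellipsoid semi-axis range (mm).
#' @param lesion_contrast Numeric length-S, lesion signal offset per sequence.
#' @param vessel_count Number of vessel tubes.
#' @param vessel_contrast Numeric length-S, vessel signal offset per sequence.
#' @param vessel_radius_mm Vessel tube radius (mm).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed RNG seed; the whole phantom is a deterministic function of the
#'   configuration.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(48L, 48L, 16L),
                           voxel_spacing = c(1, 1, 1),
                           sequence_names = c("t1_bravo", "t1_cube_post",
                                              "t1_cube_pre", "flair"),
                           lesion_count_range = c(1L, 3L),
                           lesion_radius_range = c(2, 5),
                           lesion_contrast = c(3, 3, 0, 1),
                           vessel_count = 3L,
                           vessel_contrast = c(3, 0, 0, 2),
                           vessel_radius_mm = 0.8,
                           noise_sd = 0.3,
                           seed = 1L) {
  S <- length(sequence_names)
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_spacing = as.numeric(voxel_spacing),
              sequence_names = sequence_names,
              lesion_count_range = as.integer(lesion_count_range),
              lesion_radius_range = as.numeric(lesion_radius_range),
              lesion_contrast = as.numeric(lesion_contrast),
              vessel_count = as.integer(vessel_count),
              vessel_contrast = as.numeric(vessel_contrast),
              vessel_radius_mm = as.numeric(vessel_radius_mm),
              noise_sd = as.numeric(noise_sd),
              seed = as.integer(seed))
  if (length(cfg$grid_shape) != 3 || any(cfg$grid_shape < 1))
    abort("grid_shape must be 3 positive integers")
  if (length(cfg$voxel_spacing) != 3 || any(cfg$voxel_spacing <= 0))
    abort("voxel_spacing must be 3 positive reals")
  if (length(cfg$lesion_count_range) != 2 || cfg$lesion_count_range[1] < 1 ||
      diff(cfg$lesion_count_range) < 0)
    abort("lesion_count_range must be an integer interval with lower bound >= 1")
  if (length(cfg$lesion_radius_range) != 2 || any(cfg$lesion_radius_range <= 0) ||
      diff(cfg$lesion_radius_range) < 0)
    abort("lesion_radius_range must be a positive interval (mm)")
  if (length(cfg$lesion_contrast) != S || length(cfg$vessel_contrast) != S)
    abort("lesion_contrast and vessel_contrast must have one entry per sequence")
  if (cfg$vessel_count < 0 || cfg$noise_sd < 0)
    abort("vessel_count and noise_sd must be nonnegative")
  structure(cfg, class = "phantom_config")
}

## Rasterize an axis-aligned ellipsoid; semi-axes in voxels, center in voxels.
## Returns linear indices of voxels inside it.
rasterize_ellipsoid <- function(shape, center, semi_axes) {
  lo <- pmax(1L, floor(center - semi_axes))
  hi <- pmin(shape, ceiling(center + semi_axes))
  if (any(lo > hi)) return(integer(0))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  inside <- ((g$x - center[1]) / semi_axes[1])^2 +
            ((g$y - center[2]) / semi_axes[2])^2 +
            ((g$z - center[3]) / semi_axes[3])^2 <= 1
  g <- g[inside, , drop = FALSE]
  (g$z - 1L) * shape[1] * shape[2] + (g$y - 1L) * shape[1] + g$x
}

#' Generate a synthetic multisequence phantom
#'
#' Builds one subject: a smooth two-tissue background inside an ellipsoidal
#' brain mask, plus per-sequence lesion and vessel signal offsets and additive
#' Gaussian noise. Lesions are axis-aligned ellipsoids with semi-axes drawn
#' from `lesion_radius_range`, placed fully inside the brain mask; their union
#' is the ground truth. Vessels are curvilinear tubes that never contribute to
#' the ground truth.
#'
#' The generator is a deterministic function of the configuration (including
#' its seed): the same config yields bit-identical studies.
#'
#' @param config A [phantom_config()].
#' @return A [multisequence_study()].
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  shp <- config$grid_shape
  sp <- config$voxel_spacing
  S <- length(config$sequence_names)

  ## ellipsoidal brain mask inscribed in the grid
  ctr <- (shp + 1) / 2
  semi <- 0.46 * shp
  brain_idx <- rasterize_ellipsoid(shp, ctr, semi)
  brain <- array(0L, shp); brain[brain_idx] <- 1L

  ## two smooth tissue classes from low-pass-filtered noise
  field <- gaussian_smooth_3d(array(stats::rnorm(prod(shp)), shp), sigma = 3)
  tissue_b <- field > stats::median(field[brain_idx])
  background <- array(1.0, shp)
  background[tissue_b] <- 1.5

  ## lesions: ellipsoids drawn inside the mask; bounded placement retries
  n_lesions <- if (diff(config$lesion_count_range) == 0) config$lesion_count_range[1]
               else sample(config$lesion_count_range[1]:config$lesion_count_range[2], 1)
  gt <- array(0L, shp)
  rr <- config$lesion_radius_range
  for (i in seq_len(n_lesions)) {
    placed <- FALSE
    for (try in 1:200) {
      semi_mm <- stats::runif(3, rr[1], rr[2])
      semi_vox <- semi_mm / sp
      if (any(1 + semi_vox >= shp - semi_vox)) next  # lesion larger than grid
      c_vox <- stats::runif(3, 1 + semi_vox, shp - semi_vox)
      idx <- rasterize_ellipsoid(shp, c_vox, semi_vox)
      ## the whole rasterized lesion must lie inside the brain mask
      if (length(idx) == 0 || any(brain[idx] == 0L)) next
      gt[idx] <- 1L
      placed <- TRUE
      break
    }
    if (!placed)
      abort("phantom placement failure: grid too small for the requested lesions")
  }

  ## vessels: curvilinear tubes (smoothly wandering random walks), excluded
  ## from the ground truth
  vessel <- array(0L, shp)
  r_vox <- config$vessel_radius_mm / sp
  for (v in seq_len(config$vessel_count)) {
    pos <- stats::runif(3, 0.25, 0.75) * shp
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    for (step in seq_len(4L * max(shp))) {
      if (any(pos < 1) || any(pos > shp)) break
      vessel[rasterize_ellipsoid(shp, pos, pmax(r_vox, 0.5))] <- 1L
      dir <- dir + 0.35 * stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      pos <- pos + dir
    }
  }
  vessel[gt == 1L] <- 0L   # vessels never contribute to ground truth
  vessel[brain == 0L] <- 0L

  vols <- vector("list", S)
  names(vols) <- config$sequence_names
  for (s in seq_len(S)) {
    vol <- background +
      config$lesion_contrast[s] * gt +
      config$vessel_contrast[s] * vessel
    if (config$noise_sd > 0)
      vol <- vol + stats::rnorm(prod(shp), sd = config$noise_sd)
    vol[brain == 0L] <- 0
    vols[[s]] <- vol
  }

  study <- multisequence_study(vols, sp, gt, brain, pattern = NULL)
  study$config <- unclass(config)
  study
}

#' Zero out unavailable sequences of a study
#'
#' Simulates an imaging site that did not acquire some of the training
#' sequences: the volumes of unavailable sequences are replaced by all-zero
#' arrays and the availability pattern is recorded on the study.
#'
#' @param study A [multisequence_study()].
#' @param pattern An [availability_pattern()] (or bit string) over the study's
#'   sequences; at least one sequence must remain available.
#' @return The degraded study.
#' @export
degrade_study <- function(study, pattern) {
  stopifnot(inherits(study, "multisequence_study"))
  if (is.character(pattern) || is.logical(pattern))
    pattern <- availability_pattern(pattern)
  if (length(pattern$available) != n_sequences(study))
    abort("pattern length must equal the study's number of sequences")
  for (s in which(!pattern$available))
    study$volumes[[s]] <- array(0, dim(study$volumes[[s]]))
  study$pattern <- pattern
  study
}
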