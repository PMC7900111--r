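#' Write a study to NIfTI files
#'
#' Writes one `.nii.gz` per sequence plus `ground_truth.nii.gz` and
#' `brain_mask.nii.gz`, with the voxel spacing in the NIfTI headers, and a
#' JSON sidecar (`study.json`) recording sequence names, the availability
#' pattern and, for phantoms, the generating configuration and seed.
#'
#' @param study A [multisequence_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "multisequence_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  as_nifti <- function(arr) {
    img <- RNifti::asNifti(arr)
    RNifti::`pixdim<-`(img, study$voxel_spacing)
  }
  paths <- list()
  for (s in seq_along(study$volumes)) {
    nm <- study$sequence_names[s]
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(as_nifti(study$volumes[[s]]), p)
    paths[[nm]] <- p
  }
  paths$ground_truth <- file.path(dir, "ground_truth.nii.gz")
  RNifti::writeNifti(as_nifti(study$ground_truth), paths$ground_truth)
  paths$brain_mask <- file.path(dir, "brain_mask.nii.gz")
  RNifti::writeNifti(as_nifti(study$brain_mask), paths$brain_mask)
  sidecar <- list(sequence_names = study$sequence_names,
                  voxel_spacing = study$voxel_spacing,
                  available = pattern_to_string(study$pattern))
  if (!is.null(study$config)) sidecar$config <- study$config
  jsonlite::write_json(sidecar, file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- attr(img, "pixdim")[1:3]
  list(values = array(as.numeric(img), dim(img)), spacing = as.numeric(spacing))
}

#' Read a study from NIfTI files
#'
#' Reads per-sequence volumes, ground truth and brain mask. Sequences declared
#' unavailable in `pattern` are not read: they are zero-filled, matching the
#' zero-imputation convention of the input-dropout model. A missing file for
#' an *available* sequence is an error, as is any disagreement in shape or (up
#' to `tol`) in voxel spacing — volumes must be co-registered upstream.
#'
#' @param paths Named character vector/list of per-sequence file paths, in
#'   sequence order. Entries for unavailable sequences may be `NA`.
#' @param gt_path,mask_path Paths of the ground-truth and brain-mask NIfTIs.
#' @param pattern Optional [availability_pattern()] or bit string; default all
#'   available.
#' @param tol Relative tolerance for spacing agreement.
#' @return A [multisequence_study()].
#' @export
read_study <- function(paths, gt_path, mask_path, pattern = NULL, tol = 1e-3) {
  paths <- as.list(paths)
  S <- length(paths)
  if (is.null(pattern)) pattern <- availability_pattern(rep(TRUE, S))
  if (is.character(pattern) || is.logical(pattern))
    pattern <- availability_pattern(pattern)
  if (length(pattern$available) != S)
    abort("pattern length must equal the number of sequence paths")
  vols <- vector("list", S)
  names(vols) <- names(paths) %||% paste0("seq", seq_len(S))
  spacing <- NULL; shp <- NULL
  check <- function(v, what) {
    if (is.null(shp)) { shp <<- dim(v$values); spacing <<- v$spacing }
    if (!identical(dim(v$values), shp))
      abort(sprintf("%s shape differs from the first volume", what))
    if (any(abs(v$spacing - spacing) > tol * spacing))
      abort(sprintf("%s voxel spacing differs beyond tolerance", what))
  }
  for (s in seq_len(S)) {
    if (!pattern$available[s]) next
    p <- paths[[s]]
    if (is.null(p) || is.na(p) || !file.exists(p))
      abort(sprintf("missing file for available sequence '%s'", names(vols)[s]))
    v <- read_volume(p)
    check(v, names(vols)[s])
    vols[[s]] <- v$values
  }
  if (!file.exists(gt_path)) abort("ground-truth file not found")
  if (!file.exists(mask_path)) abort("brain-mask file not found")
  gt <- read_volume(gt_path); check(gt, "ground_truth")
  bm <- read_volume(mask_path); check(bm, "brain_mask")
  for (s in which(!pattern$available)) vols[[s]] <- array(0, shp)
  multisequence_study(vols, spacing, gt$values, bm$values, pattern = pattern)
}

#' Z-score a study's available sequences within the brain mask
#'
#' Each available sequence is standardised to mean 0 and standard deviation 1
#' over brain-mask voxels (non-brain voxels are transformed with the same
#' affine map). Unavailable (all-zero) sequences are left untouched, so after
#' normalisation the zeros imputed for missing sequences sit at the masked
#' background mean. The operation is idempotent.
#'
#' @param study A [multisequence_study()].
#' @return The normalised study.
#' @export
normalize_study <- function(study) {
  stopifnot(inherits(study, "multisequence_study"))
  msk <- study$brain_mask == 1L
  if (!any(msk)) abort("brain mask is empty")
  for (s in seq_along(study$volumes)) {
    if (!study$pattern$available[s]) next
    v <- study$volumes[[s]]
    mu <- mean(v[msk])
    sdv <- stats::sd(v[msk])
    if (!is.finite(sdv) || sdv == 0)
      abort(sprintf("sequence '%s' has zero variance within the brain mask",
                    study$sequence_names[s]))
    study$volumes[[s]] <- (v - mu) / sdv
  }
  study
}

#' Extract a 2.5D slab stack centred on a slice
#'
#' Builds the network input for axial slice `z`: for each of the S sequences,
#' the `k = 2*half_width + 1` contiguous slices centred on `z`, concatenated
#' channel-wise so channels `[(s-1)*k + 1, s*k]` hold sequence `s`'s slices in
#' ascending slice order (for S = 4 sequences and k = 5 this is the 20-channel
#' input tensor). At the volume boundary, out-of-range slices are
#' edge-replicated rather than zero-filled, so boundary padding can never be
#' mistaken for a dropped sequence.
#'
#' @param study A [multisequence_study()].
#' @param z Centre slice index (1-based, along the third axis).
#' @param half_width Slab half-width; `k = 2*half_width + 1` slices per
#'   sequence (default 2, i.e. k = 5).
#' @return Object of class `slab_stack` with fields `values` (H x W x S*k
#'   array), `center_index`, `n_sequences`, `slab_width` and the study's
#'   availability `pattern`.
#' @export
extract_slab <- function(study, z, half_width = 2L) {
  stopifnot(inherits(study, "multisequence_study"))
  shp <- dim(study)
  z <- as.integer(z)
  if (z < 1L || z > shp[3]) abort("slice index out of range")
  half_width <- as.integer(half_width)
  k <- 2L * half_width + 1L
  S <- n_sequences(study)
  vals <- array(0, c(shp[1], shp[2], S * k))
  zs <- pmin(pmax(z + seq(-half_width, half_width), 1L), shp[3])
  for (s in seq_len(S)) {
    vol <- study$volumes[[s]]
    for (j in seq_len(k))
      vals[, , (s - 1L) * k + j] <- vol[, , zs[j]]
  }
  structure(list(values = vals, center_index = z, n_sequences = S,
                 slab_width = k, slab_half_width = half_width,
                 pattern = study$pattern),
            class = "slab_stack")
}

#' Write a cohort manifest
#'
#' A manifest CSV lists, per subject, the study directory and its availability
#' pattern; it is the handle the training, prediction and evaluation commands
#' use to address a cohort on disk.
#'
#' @param dirs Character vector of study directories (each as written by
#'   [write_study()]).
#' @param path Output CSV path.
#' @param available Bit-string availability pattern applied when reading
#'   (default: the pattern stored in each study's sidecar).
#' @return Invisibly, the manifest data frame.
#' @export
write_manifest <- function(dirs, path, available = NULL) {
  rows <- lapply(dirs, function(d) {
    sc <- jsonlite::read_json(file.path(d, "study.json"), simplifyVector = TRUE)
    data.frame(subject = basename(d), dir = d,
               available = available %||% sc$available,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

## availability bit strings must never be type-sniffed into integers
read_manifest_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(available = "character"))
}

#' Read one subject of a manifest
#'
#' @param manifest Manifest data frame or CSV path.
#' @param i Row index.
#' @param available Optional bit-string overriding the manifest's pattern
#'   (e.g. to evaluate a site missing a sequence).
#' @return A [multisequence_study()].
#' @export
read_manifest_study <- function(manifest, i, available = NULL) {
  if (is.character(manifest)) manifest <- read_manifest_csv(manifest)
  row <- manifest[i, ]
  row$available <- as.character(row$available)
  sc <- jsonlite::read_json(file.path(row$dir, "study.json"), simplifyVector = TRUE)
  paths <- stats::setNames(file.path(row$dir, paste0(sc$sequence_names, ".nii.gz")),
                           sc$sequence_names)
  pat <- available %||% row$available
  read_study(paths, file.path(row$dir, "ground_truth.nii.gz"),
             file.path(row$dir, "brain_mask.nii.gz"), pattern = pat)
}
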