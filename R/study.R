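#' Construct a multisequence study
#'
#' A study holds one subject's co-registered 3D volumes (one per MRI pulse
#' sequence), the voxel spacing, a binary lesion ground-truth mask and a binary
#' brain mask. All arrays must share a single shape, and every ground-truth
#' voxel must lie inside the brain mask.
#'
#' @param volumes Named list of 3D numeric arrays, one per sequence, identical
#'   dimensions. Names are the sequence labels.
#' @param voxel_spacing Numeric length-3, voxel edge lengths in mm.
#' @param ground_truth 3D binary (0/1 or logical) array, same shape.
#' @param brain_mask 3D binary array, same shape.
#' @param pattern Optional [availability_pattern()]; defaults to all available.
#' @return An object of class `multisequence_study`.
#' @seealso [generate_phantom()], [read_study()], [degrade_study()]
#' @export
multisequence_study <- function(volumes, voxel_spacing, ground_truth, brain_mask,
                                pattern = NULL) {
  if (!is.list(volumes) || length(volumes) < 1)
    abort("`volumes` must be a non-empty list of 3D arrays")
  if (is.null(names(volumes)) || anyNA(names(volumes)) || any(names(volumes) == ""))
    names(volumes) <- paste0("seq", seq_along(volumes))
  shp <- dim(volumes[[1]])
  if (length(shp) != 3) abort("volumes must be 3D arrays")
  for (v in volumes)
    if (!identical(dim(v), shp)) abort("all volumes must share one shape")
  if (!identical(dim(ground_truth), shp))
    abort("ground_truth shape differs from volume shape")
  if (!identical(dim(brain_mask), shp))
    abort("brain_mask shape differs from volume shape")
  if (!is.numeric(voxel_spacing) || length(voxel_spacing) != 3 || any(voxel_spacing <= 0))
    abort("voxel_spacing must be 3 positive reals (mm)")
  gt <- array(as.integer(ground_truth != 0), shp)
  bm <- array(as.integer(brain_mask != 0), shp)
  if (any(gt == 1L & bm == 0L))
    abort("every ground-truth voxel must lie inside the brain mask")
  if (is.null(pattern)) pattern <- availability_pattern(rep(TRUE, length(volumes)))
  if (length(pattern$available) != length(volumes))
    abort("availability pattern length must equal the number of sequences")
  structure(list(
    volumes = volumes,
    sequence_names = names(volumes),
    voxel_spacing = as.numeric(voxel_spacing),
    ground_truth = gt,
    brain_mask = bm,
    pattern = pattern
  ), class = "multisequence_study")
}

#' @export
print.multisequence_study <- function(x, ...) {
  shp <- dim(x$volumes[[1]])
  cat("Multisequence study\n")
  cat("  sequences :", paste(x$sequence_names, collapse = ", "), "\n")
  cat("  shape     :", paste(shp, collapse = " x "),
      " spacing:", paste(signif(x$voxel_spacing, 3), collapse = " x "), "mm\n")
  cat("  available :", pattern_to_string(x$pattern), "\n")
  cat("  lesion vox:", sum(x$ground_truth),
      " brain vox:", sum(x$brain_mask), "\n")
  invisible(x)
}

#' @export
dim.multisequence_study <- function(x) dim(x$volumes[[1]])

n_sequences <- function(study) length(study$volumes)
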