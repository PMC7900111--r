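#' Predict a whole-volume probability map
#'
#' Applies the model slice by slice: for each axial slice, a 2.5D slab is
#' extracted, the declared availability pattern is applied exactly as in
#' training (unavailable sequences zeroed, survivors upweighted by `1/(1-p)`),
#' and the network's centre-slice probabilities are written into the output
#' volume. Declaring a sequence unavailable is bit-identical to zeroing its
#' volume first and declaring it unavailable — missing data never needs
#' re-training, only a different pattern flag.
#'
#' @param model A trained `seg_model`.
#' @param study A [multisequence_study()]; normalised internally.
#' @param pattern Availability pattern (object or bit string); defaults to the
#'   study's own pattern.
#' @param slab_half_width 2.5D half-width; by default inferred from the
#'   model's channel count (`in_channels / S` slices per sequence).
#' @return Object of class `probability_map`: `values` (3D array in (0,1)),
#'   `voxel_spacing`, `pattern`.
#' @export
predict_volume <- function(model, study, pattern = NULL, slab_half_width = NULL) {
  stopifnot(inherits(model, "seg_model"), inherits(study, "multisequence_study"))
  if (is.character(pattern) || is.logical(pattern))
    pattern <- availability_pattern(pattern)
  pattern <- pattern %||% study$pattern
  S <- n_sequences(study)
  if (length(pattern$available) != S)
    abort("pattern length must equal the study's number of sequences")
  if (is.null(slab_half_width)) {
    k <- model$config$in_channels %/% S
    if (k * S != model$config$in_channels || k %% 2L != 1L)
      abort(sprintf("cannot infer slab width: model has %d channels for %d sequences",
                    model$config$in_channels, S))
    slab_half_width <- (k - 1L) %/% 2L
  }
  k <- 2L * as.integer(slab_half_width) + 1L
  if (model$config$in_channels != S * k)
    abort(sprintf("model expects %d input channels, study yields %d",
                  model$config$in_channels, S * k))
  ## declared-unavailable sequences are zero-filled before normalisation so
  ## the study matches what a site missing them would supply
  study <- degrade_study(study, pattern)
  study <- normalize_study(study)
  shp <- dim(study)
  ctx <- make_conv_context(shp[1], shp[2], 1L, c(1L, model$config$dilation_rates))
  out <- array(0, shp)
  HW <- shp[1] * shp[2]
  for (z in seq_len(shp[3])) {
    slab <- extract_slab(study, z, slab_half_width)
    slab <- apply_input_dropout(slab, pattern)
    X <- matrix(slab$values, HW, S * k)
    fwd <- network_forward(model, X, ctx, keep_cache = FALSE)
    out[, , z] <- fwd$p
  }
  structure(list(values = out, voxel_spacing = study$voxel_spacing,
                 pattern = pattern),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat("Probability map", paste(dim(x$values), collapse = " x "),
      "| pattern", pattern_to_string(x$pattern),
      sprintf("| range [%.3g, %.3g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Threshold a probability map
#'
#' A voxel is included iff its probability is greater than or equal to the
#' threshold (closed lower bound). Raising the threshold can therefore never
#' add a positive voxel.
#'
#' @param map A `probability_map` (or bare numeric array).
#' @param threshold Probability threshold in `[0, 1]`.
#' @return 3D integer (0/1) array.
#' @export
binarize <- function(map, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1)
    abort("threshold must be a single value in [0, 1]")
  vals <- if (inherits(map, "probability_map")) map$values else map
  array(as.integer(vals >= threshold), dim(vals))
}

#' Write a probability map (and optionally its binary mask) as NIfTI
#'
#' @param map A `probability_map`.
#' @param path Output `.nii.gz` path for the probability map.
#' @param threshold Optional; if given, also writes `<path>` with suffix
#'   `_mask` holding [binarize()] at this threshold.
#' @return Invisibly, the path(s) written.
#' @export
write_probability_map <- function(map, path, threshold = NULL) {
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- map$voxel_spacing
  RNifti::writeNifti(img, path)
  out <- path
  if (!is.null(threshold)) {
    mpath <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
    msk <- RNifti::asNifti(binarize(map, threshold))
    RNifti::pixdim(msk) <- map$voxel_spacing
    RNifti::writeNifti(msk, mpath)
    out <- c(out, mpath)
  }
  invisible(out)
}
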