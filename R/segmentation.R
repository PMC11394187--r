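# Segmentation providers.
#
# 2D-per-slice stent detection is pluggable: clinical deployments feed masks
# from a trained network through `import_mask()`, while `threshold_segment()`
# is a Hounsfield-window baseline that lets the whole 3D pipeline run without
# any model. Stents and stones share overlapping attenuation, so a threshold
# alone over-segments by design — separating the stent from bright clutter is
# the job of the 3D connected-domain filtering downstream.

#' Threshold-based stent segmentation baseline
#'
#' @param volume A [ct_volume()].
#' @param hu_low,hu_high Inclusive Hounsfield window; `hu_low < hu_high`.
#'   The default 300--3000 HU brackets typical stent and stone attenuation.
#' @return A [binary_mask()] on the volume grid, true where
#'   `hu_low <= HU <= hu_high`.
#' @export
threshold_segment <- function(volume, hu_low = 300, hu_high = 3000) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!(hu_low < hu_high)) stop("hu_low must be strictly below hu_high")
  fg <- volume$voxels >= hu_low & volume$voxels <= hu_high
  binary_mask(fg, spacing = volume$spacing, origin = volume$origin)
}

#' Import a stent mask produced by an external segmentation model
#'
#' Thin wrapper over [read_mask()]: reads a NIfTI 0/1 volume and verifies that
#' its grid matches the reference CT volume.
#'
#' @param path NIfTI mask path.
#' @param reference The [ct_volume()] the mask belongs to.
#' @return A [binary_mask()].
#' @export
import_mask <- function(path, reference) read_mask(path, reference)

# Resolve a provider spec (from the pipeline config) to a mask.
resolve_segmentation <- function(volume, config) {
  provider <- config$segmentation$provider
  if (provider == "threshold") {
    threshold_segment(volume, config$segmentation$hu_low,
                      config$segmentation$hu_high)
  } else if (provider == "external") {
    if (is.null(config$segmentation$mask_path))
      stop("segmentation.provider = 'external' requires segmentation.mask_path")
    import_mask(config$segmentation$mask_path, volume)
  } else {
    stop("unknown segmentation provider '", provider, "'")
  }
}
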