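#' @useDynLib stentcheck, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---------------------------------------------------------------------------
# Domain containers
# ---------------------------------------------------------------------------

#' Construct a CT volume
#'
#' A `ct_volume` is the package-wide carrier for 3D CT data: a scalar array in
#' Hounsfield units on a rectilinear grid with physical voxel spacing and
#' origin. Voxel indices are 0-based in world-coordinate formulas; the centre
#' of voxel `(i, j, k)` is at `origin + c(i, j, k) * spacing` (mm). Axis order
#' of the array is `(x, y, z)`.
#'
#' @param voxels 3D numeric array of attenuation values (HU).
#' @param spacing Numeric length-3, mm per voxel along (x, y, z); all > 0.
#' @param origin Numeric length-3, world position (mm) of voxel (0,0,0).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive finite values (mm)")
  if (length(origin) != 3 || any(!is.finite(origin)))
    stop("origin must be three finite values (mm)")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' Construct a binary mask on the grid of a CT volume
#'
#' @param voxels 3D logical array (same shape as its source volume).
#' @param spacing,origin Grid geometry, as in [ct_volume()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  storage.mode(voxels) <- "logical"
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "binary_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("CT volume:", paste(dim(x$voxels), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = " x "),
      "mm\n  HU range:", paste(signif(range(x$voxels), 4), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("Binary mask:", paste(dim(x$voxels), collapse = " x "),
      "voxels,", sum(x$voxels), "foreground\n")
  invisible(x)
}

# Grid comparison used by every consumer of (volume, mask) pairs.
same_grid <- function(a, b, tol = 1e-3) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

describe_grid <- function(x) {
  sprintf("dim [%s], spacing [%s] mm, origin [%s] mm",
          paste(dim(x$voxels), collapse = ", "),
          paste(signif(x$spacing, 6), collapse = ", "),
          paste(signif(x$origin, 6), collapse = ", "))
}

# World coordinates (mm) of 0-based voxel indices (n x 3 matrix in, n x 3 out).
index_to_world <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(sweep(ijk, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

world_to_index <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(sweep(xyz, 2, grid$origin, "-"), 2, grid$spacing, "/")
}

# ---------------------------------------------------------------------------
# Volume I/O
# ---------------------------------------------------------------------------

#' Read a CT volume from NIfTI or a DICOM series directory
#'
#' NIfTI voxel spacing is taken from `pixdim`; DICOM slices are sorted by
#' position along the slice axis and values are rescaled to HU via the rescale
#' slope/intercept when present. Missing spacing information is an error:
#' 1 mm is never silently assumed.
#'
#' @param path Path to a `.nii`/`.nii.gz` file or a DICOM series directory.
#' @param format `"nifti"` or `"dicom_dir"`; `"auto"` guesses from `path`.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom_dir")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_dir" else "nifti"
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 3)
      stop("expected a 3D NIfTI volume, got ", length(dim(img)), " dimensions")
    pd <- RNifti::pixdim(img)
    if (length(pd) < 3 || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
      stop("NIfTI header carries no usable voxel spacing (pixdim); refusing to assume 1 mm")
    # World origin is pinned to voxel (0,0,0): downstream geometry only needs a
    # consistent rectilinear affine, not scanner-table coordinates.
    ct_volume(unclass(as.array(img)), spacing = pd[1:3], origin = c(0, 0, 0))
  } else {
    read_dicom_series(path)
  }
}

#' Write a CT volume as NIfTI
#'
#' @param volume A [ct_volume()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write a binary mask as NIfTI (uint8, 0/1)
#'
#' @param mask A [binary_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  arr <- array(as.integer(mask$voxels), dim = dim(mask$voxels))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a binary mask and check it against a reference grid
#'
#' @param path NIfTI path holding a 0/1 volume.
#' @param reference A [ct_volume()] whose grid the mask must match
#'   (spacing within 1e-3 mm, identical shape).
#' @return A [binary_mask()] on the reference grid.
#' @export
read_mask <- function(path, reference) {
  stopifnot(inherits(reference, "ct_volume"))
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)[1:3]
  arr <- unclass(as.array(img)) != 0
  cand <- list(voxels = arr, spacing = pd, origin = reference$origin)
  if (!identical(dim(arr), dim(reference$voxels)) ||
      any(abs(pd - reference$spacing) > 1e-3))
    stop("mask grid does not match reference grid:\n  mask:      ",
         describe_grid(cand), "\n  reference: ", describe_grid(reference))
  binary_mask(arr, spacing = reference$spacing, origin = reference$origin)
}

# ---------------------------------------------------------------------------
# Case reports
# ---------------------------------------------------------------------------

#' Construct a per-case report
#'
#' @param case_id Character identifier.
#' @param verdict One of `"negative"`, `"residual_stone"`, `"encrustation"`,
#'   `"indeterminate"`.
#' @param segments List of anomaly segments (each a list with `start`, `end`,
#'   `class`, `mean_area`, `max_area`; 1-based section indices).
#' @param provenance Named list recording the segmentation source and the
#'   parameters used (serialized verbatim into the JSON report).
#' @return An object of class `case_report`.
#' @export
case_report <- function(case_id, verdict, segments = list(),
                        provenance = list()) {
  verdict <- match.arg(verdict,
                       c("negative", "residual_stone", "encrustation",
                         "indeterminate"))
  if (verdict == "negative" && length(segments) > 0)
    stop("a negative verdict must carry no anomaly segments")
  if (verdict %in% c("residual_stone", "encrustation") && length(segments) == 0)
    stop("verdict '", verdict, "' requires at least one anomaly segment")
  structure(list(case_id = as.character(case_id), verdict = verdict,
                 segments = segments, provenance = provenance),
            class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat("Case", x$case_id, "- verdict:", x$verdict, "\n")
  for (s in x$segments)
    cat(sprintf("  segment [%d, %d] class=%s max normalized area=%.2f\n",
                s$start, s$end, s$class, s$max_area))
  invisible(x)
}

report_schema_version <- "1.0"

#' Write a case report as JSON
#'
#' Produces a stable, deterministic document (fixed key order, schema version
#' field) so that re-writing a re-read report is byte-identical.
#'
#' @param report A [case_report()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "case_report"))
  doc <- list(schema_version = report_schema_version,
              case_id = report$case_id,
              verdict = report$verdict,
              segments = lapply(report$segments, function(s)
                s[order(names(s))]),
              provenance = report$provenance)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2, digits = NA,
                           null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a case report written by [write_report()]
#'
#' @param path JSON path.
#' @return A [case_report()].
#' @export
read_report <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$schema_version))
    stop("not a stentcheck case report: missing schema_version")
  case_report(doc$case_id, doc$verdict,
              segments = lapply(doc$segments, function(s) s[order(names(s))]),
              provenance = doc$provenance)
}
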