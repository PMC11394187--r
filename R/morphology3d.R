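# 3D connected-domain analysis.
#
# The stent is the one structure in the thresholded foreground that is long,
# thin and connected from kidney to bladder; loose stone fragments and bone
# are compact. Labeling is the classic two-pass raster scan: a first scan
# assigns provisional labels from already-visited neighbours and records label
# equivalences in a union-find table, a second scan resolves every voxel to
# its equivalence-class minimum.

#' Label 3D connected components (two-pass scan)
#'
#' @param mask A [binary_mask()] (may be empty).
#' @param adjacency Voxel neighbourhood system: 6 (faces), 18 (faces+edges) or
#'   26 (faces+edges+corners). Default 26: a thin tilted tube often connects
#'   only diagonally between slices.
#' @return A `labeled_volume`: list with `labels` (integer array, 0 =
#'   background, components numbered consecutively 1..n), `n_components`,
#'   `adjacency`, and the mask grid (`spacing`, `origin`).
#' @export
label_components <- function(mask, adjacency = 26) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!adjacency %in% c(6, 18, 26))
    stop("adjacency must be 6, 18 or 26")
  res <- .ccl_two_pass(as.logical(mask$voxels), dim(mask$voxels),
                       as.integer(adjacency))
  labels <- array(res$labels, dim = dim(mask$voxels))
  structure(list(labels = labels, n_components = res$n_components,
                 adjacency = adjacency, spacing = mask$spacing,
                 origin = mask$origin),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat("Labeled volume:", x$n_components, "components, adjacency",
      x$adjacency, "\n")
  invisible(x)
}

#' Per-component geometric statistics
#'
#' @param labeled A `labeled_volume` from [label_components()].
#' @param volume Optional [ct_volume()] on the same grid (grid check only).
#' @return A data.frame with one row per label: `label`, `voxel_count`,
#'   `volume_mm3`, index bounding box (`x0,x1,y0,y1,z0,z1`, 1-based), centroid
#'   (mm), physical extents per axis (mm) and `elongation` =
#'   z-extent / max(x-extent, y-extent).
#' @export
component_stats <- function(labeled, volume = NULL) {
  stopifnot(inherits(labeled, "labeled_volume"))
  if (!is.null(volume) && !same_grid(labeled, volume))
    stop("labeled volume and CT volume are on different grids:\n  labels:  ",
         describe_grid(labeled), "\n  volume:  ", describe_grid(volume))
  sp <- labeled$spacing
  vx <- prod(sp)
  n <- labeled$n_components
  if (n == 0)
    return(data.frame(label = integer(0), voxel_count = integer(0),
                      volume_mm3 = numeric(0), x0 = integer(0), x1 = integer(0),
                      y0 = integer(0), y1 = integer(0), z0 = integer(0),
                      z1 = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), centroid_z = numeric(0),
                      x_extent = numeric(0), y_extent = numeric(0),
                      z_extent = numeric(0), elongation = numeric(0)))
  idx <- which(labeled$labels > 0, arr.ind = TRUE)
  lab <- labeled$labels[labeled$labels > 0]
  cnt <- tabulate(lab, nbins = n)
  agg <- function(v, f) as.numeric(tapply(v, lab, f))
  x0 <- agg(idx[, 1], min); x1 <- agg(idx[, 1], max)
  y0 <- agg(idx[, 2], min); y1 <- agg(idx[, 2], max)
  z0 <- agg(idx[, 3], min); z1 <- agg(idx[, 3], max)
  ext <- cbind((x1 - x0 + 1) * sp[1], (y1 - y0 + 1) * sp[2],
               (z1 - z0 + 1) * sp[3])
  # centroid of voxel centres, world mm (0-based index convention)
  cx <- labeled$origin[1] + (agg(idx[, 1], mean) - 1) * sp[1]
  cy <- labeled$origin[2] + (agg(idx[, 2], mean) - 1) * sp[2]
  cz <- labeled$origin[3] + (agg(idx[, 3], mean) - 1) * sp[3]
  data.frame(label = seq_len(n), voxel_count = cnt, volume_mm3 = cnt * vx,
             x0 = as.integer(x0), x1 = as.integer(x1),
             y0 = as.integer(y0), y1 = as.integer(y1),
             z0 = as.integer(z0), z1 = as.integer(z1),
             centroid_x = cx, centroid_y = cy, centroid_z = cz,
             x_extent = ext[, 1], y_extent = ext[, 2], z_extent = ext[, 3],
             elongation = ext[, 3] / pmax(ext[, 1], ext[, 2]))
}

#' Bridge short axial gaps in a tubular mask
#'
#' A weak 2D segmentation can lose a few consecutive slices of the stent.
#' For every pair of components whose z-ranges are separated by at most
#' `max_gap_slices` empty slices and whose flanking-slice centroids lie within
#' `centroid_mm` in-plane, interpolated disks (centres linearly interpolated,
#' radius the mean of the flanking per-slice equivalent radii) are inserted
#' across the gap. Output is a superset of the input; the operation is
#' idempotent.
#'
#' @param mask A [binary_mask()].
#' @param max_gap_slices Maximum bridgeable gap, in slices (>= 0).
#' @param centroid_mm Maximum in-plane centroid distance between the flanking
#'   slices (mm).
#' @param adjacency Neighbourhood for the component analysis.
#' @return A [binary_mask()].
#' @export
fill_gaps <- function(mask, max_gap_slices = 5, centroid_mm = 10,
                      adjacency = 26) {
  stopifnot(inherits(mask, "binary_mask"), max_gap_slices >= 0)
  if (max_gap_slices == 0) return(mask)
  lv <- label_components(mask, adjacency)
  if (lv$n_components < 2) return(mask)
  st <- component_stats(lv)
  sp <- mask$spacing
  vox <- mask$voxels
  dims <- dim(vox)

  slice_disk_stats <- function(label, z) {
    sl <- lv$labels[, , z] == label
    ij <- which(sl, arr.ind = TRUE)
    if (nrow(ij) == 0) return(NULL)
    list(cx = mean(ij[, 1]), cy = mean(ij[, 2]),
         r_mm = sqrt(nrow(ij) * sp[1] * sp[2] / pi))
  }

  ord <- order(st$z0)
  st <- st[ord, ]
  for (a in seq_len(nrow(st) - 1)) {
    for (b in (a + 1):nrow(st)) {
      gap <- st$z0[b] - st$z1[a] - 1
      if (gap < 1 || gap > max_gap_slices) next
      lo <- slice_disk_stats(st$label[a], st$z1[a])
      hi <- slice_disk_stats(st$label[b], st$z0[b])
      if (is.null(lo) || is.null(hi)) next
      d_mm <- sqrt(((hi$cx - lo$cx) * sp[1])^2 + ((hi$cy - lo$cy) * sp[2])^2)
      if (d_mm > centroid_mm) next
      r <- max((lo$r_mm + hi$r_mm) / 2, max(sp[1], sp[2]))
      xs <- (seq_len(dims[1]) - 1) * sp[1]
      ys <- (seq_len(dims[2]) - 1) * sp[2]
      for (g in seq_len(gap)) {
        f <- g / (gap + 1)
        cx <- ((1 - f) * lo$cx + f * hi$cx - 1) * sp[1]
        cy <- ((1 - f) * lo$cy + f * hi$cy - 1) * sp[2]
        disk <- outer((xs - cx)^2, (ys - cy)^2, "+") <= r^2
        z <- st$z1[a] + g
        vox[, , z] <- vox[, , z] | disk
      }
    }
  }
  binary_mask(vox, spacing = mask$spacing, origin = mask$origin)
}

#' Isolate the stent component by connected-domain filtering
#'
#' Among components that are long enough (`min_z_extent_mm`) and thin enough
#' (`min_elongation`), the one with the greatest z-extent is returned; ties
#' break on larger voxel count, then smaller label. A double-J stent spans
#' kidney to bladder, so loose fragments and compact bone blobs fail both
#' filters and are discarded wholesale.
#'
#' @param stats Component table from [component_stats()].
#' @param labeled The matching `labeled_volume`.
#' @param min_z_extent_mm Minimum physical z-extent (default 100 mm).
#' @param min_elongation Minimum z-extent / max in-plane extent (default 3).
#' @return A [binary_mask()] containing exactly the selected component.
#' @export
select_stent_component <- function(stats, labeled, min_z_extent_mm = 100,
                                   min_elongation = 3) {
  stopifnot(inherits(labeled, "labeled_volume"))
  if (nrow(stats) == 0)
    stop(errorCondition("mask is empty: no components to select",
                        class = c("stentcheck_empty_mask", "error", "condition")))
  ok <- stats$z_extent >= min_z_extent_mm & stats$elongation >= min_elongation
  if (!any(ok))
    stop(errorCondition(
      sprintf(paste0("no stent found: none of the %d components passes ",
                     "z_extent >= %g mm and elongation >= %g"),
              nrow(stats), min_z_extent_mm, min_elongation),
      class = c("stentcheck_no_stent", "error", "condition")))
  cand <- stats[ok, ]
  cand <- cand[order(-cand$z_extent, -cand$voxel_count, cand$label), ]
  pick <- cand$label[1]
  binary_mask(labeled$labels == pick, spacing = labeled$spacing,
              origin = labeled$origin)
}
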