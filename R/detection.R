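# Polar radius profiling and anomaly classification.
#
# A clean stent section is a near-circle: its polar radius profile is flat.
# A residual stone touching the stent bulges the profile hugely over one
# contiguous stretch of sections; encrustation grows as many small
# intermittent thickenings along the whole stent. The classifier encodes
# exactly that contrast on the elevated-section run structure.

#' Default detection thresholds
#'
#' The qualitative rules (one large contiguous excursion = residual stone,
#' many small intermittent excursions = encrustation) need numeric handles;
#' these defaults are recorded in every report for provenance.
#'
#' @param elevation_delta Relative radius increase over baseline that marks a
#'   bin elevated (0.15 = +15%).
#' @param stone_run_fraction Minimum longest-run length as a fraction of the
#'   section count for the residual-stone branch.
#' @param stone_magnitude Minimum max relative elevation for residual stone.
#' @param encrust_min_runs Minimum number of elevated runs for encrustation.
#' @param encrust_run_max_fraction Maximum single-run length (fraction of
#'   sections) for the encrustation branch.
#' @param n_bins Angular bins of the polar transform.
#' @return A named list of class `detection_thresholds`.
#' @export
detection_thresholds <- function(elevation_delta = 0.15,
                                 stone_run_fraction = 0.08,
                                 stone_magnitude = 0.5,
                                 encrust_min_runs = 3,
                                 encrust_run_max_fraction = 0.05,
                                 n_bins = 64) {
  stopifnot(elevation_delta > 0, stone_run_fraction > 0,
            stone_run_fraction <= 1, stone_magnitude > 0,
            encrust_min_runs >= 1, encrust_run_max_fraction > 0,
            encrust_run_max_fraction <= 1, n_bins >= 8)
  structure(list(elevation_delta = elevation_delta,
                 stone_run_fraction = stone_run_fraction,
                 stone_magnitude = stone_magnitude,
                 encrust_min_runs = encrust_min_runs,
                 encrust_run_max_fraction = encrust_run_max_fraction,
                 n_bins = as.integer(n_bins)),
            class = "detection_thresholds")
}

#' Polar radius profile of a cross-section
#'
#' The patch foreground is reduced to radius-versus-angle: for each of
#' `n_bins` uniform angular bins over [0, 2*pi), the radius is the distance
#' (mm) from the foreground centroid to the outermost foreground pixel whose
#' angle falls in the bin. Empty bins get radius 0 and are flagged. Centering
#' on the centroid makes the profile translation-invariant; rotating the
#' section cyclically shifts the profile.
#'
#' @param section A `cross_section` with a mask patch.
#' @param n_bins Number of angular bins.
#' @return A `radius_profile`: `angles` (bin centres, rad), `radius` (mm),
#'   `empty` (logical per bin), `section_index`.
#' @export
polar_transform <- function(section, n_bins = 64) {
  stopifnot(inherits(section, "cross_section"))
  patch <- section$patch
  fg <- which(patch >= 0.5, arr.ind = TRUE)
  if (nrow(fg) == 0)
    stop(errorCondition("empty cross-section: no foreground pixels",
                        class = c("stentcheck_empty_section", "error",
                                  "condition")))
  px <- section$pixel_mm
  cx <- mean(fg[, 1]); cy <- mean(fg[, 2])
  dx <- (fg[, 1] - cx) * px
  dy <- (fg[, 2] - cy) * px
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx) %% (2 * pi)
  bin <- pmin(floor(ang / (2 * pi / n_bins)) + 1, n_bins)
  radius <- rep(0, n_bins)
  agg <- tapply(r, bin, max)
  radius[as.integer(names(agg))] <- agg
  empty <- !(seq_len(n_bins) %in% bin)
  structure(list(angles = (seq_len(n_bins) - 0.5) * 2 * pi / n_bins,
                 radius = radius, empty = empty,
                 section_index = section$index),
            class = "radius_profile")
}

# Circular median filter over angular bins. Voxel-scale rim aliasing shows up
# as 1-2 bin blips in the outermost-pixel radius; a short median filter
# removes them while leaving real bumps (tens of degrees wide) intact. Empty
# bins are excluded from each window.
smooth_profile <- function(radius, empty, window = 3) {
  n <- length(radius)
  h <- (window - 1) %/% 2
  r <- radius
  r[empty] <- NA
  out <- vapply(seq_len(n), function(i) {
    w <- ((i - h - 1):(i + h - 1)) %% n + 1
    v <- r[w]
    if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)
  }, numeric(1))
  out
}

#' Elevation features across a sequence of radius profiles
#'
#' The baseline radius is the median over all bins of the non-anomalous
#' sections (falling back to the global median when every section is flagged).
#' Each profile is first smoothed with a short circular median filter (3 bins,
#' about 17 degrees at 64 bins) to suppress voxel-scale rim aliasing. A bin is
#' elevated when its smoothed radius exceeds `baseline * (1 +
#' elevation_delta)`; a section is elevated when any of its bins is; runs are
#' maximal stretches of consecutive elevated section indices. Single-section
#' runs whose peak elevation stays below the residual-stone magnitude are
#' discretization noise (an excursion shorter than the section spacing with
#' near-threshold amplitude) and are excluded from the run statistics.
#'
#' @param profiles List of `radius_profile`, ordered along the stent.
#' @param thresholds A [detection_thresholds()].
#' @param anomalous_idx Optional 1-based indices of sections already flagged
#'   by the area rule; these are excluded from the baseline.
#' @return A `profile_features` list: `baseline_mm`, per-section
#'   `elevated_fraction`, `elevated` flags, `runs` (data.frame start/end/len),
#'   `longest_run`, `n_runs`, `max_relative_elevation`, `n_sections`.
#' @export
profile_features <- function(profiles, thresholds = detection_thresholds(),
                             anomalous_idx = integer(0)) {
  stopifnot(length(profiles) >= 1)
  smoothed <- lapply(profiles, function(p)
    smooth_profile(p$radius, p$empty))
  sec_idx <- vapply(profiles, function(p) p$section_index, numeric(1))
  clean <- !(sec_idx %in% anomalous_idx)
  pool <- unlist(smoothed[clean])
  pool <- pool[!is.na(pool)]
  if (length(pool) == 0) pool <- unlist(smoothed)
  baseline <- stats::median(pool, na.rm = TRUE)
  if (!is.finite(baseline) || baseline <= 0)
    stop("cannot establish a baseline radius (no usable bins)")
  cut <- baseline * (1 + thresholds$elevation_delta)
  elev_frac <- vapply(smoothed, function(r) {
    ok <- !is.na(r)
    if (!any(ok)) return(0)
    mean(r[ok] > cut)
  }, numeric(1))
  elevated <- elev_frac > 0
  rel <- vapply(smoothed, function(r) {
    ok <- !is.na(r)
    if (!any(ok)) return(0)
    max(r[ok] / baseline - 1)
  }, numeric(1))
  runs <- rle(elevated)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  rdf <- data.frame(start = starts[runs$values], end = ends[runs$values],
                    len = runs$lengths[runs$values])
  if (nrow(rdf)) {
    run_rel <- vapply(seq_len(nrow(rdf)), function(k)
      max(rel[rdf$start[k]:rdf$end[k]]), numeric(1))
    noise <- rdf$len == 1 & run_rel < thresholds$stone_magnitude
    for (k in which(noise)) elevated[rdf$start[k]] <- FALSE
    rdf <- rdf[!noise, , drop = FALSE]
  }
  structure(list(baseline_mm = baseline,
                 elevated_fraction = elev_frac,
                 elevated = elevated,
                 runs = rdf,
                 longest_run = if (nrow(rdf)) max(rdf$len) else 0L,
                 n_runs = nrow(rdf),
                 max_relative_elevation = if (any(elevated)) max(rel[elevated]) else 0,
                 n_sections = length(profiles)),
            class = "profile_features")
}

#' Classify the elevation pattern of a case
#'
#' Decision rule: no elevated section is clean. One (or two) contiguous runs
#' that are long (`>= stone_run_fraction` of sections) and strong
#' (`max_relative_elevation >= stone_magnitude`) mean a residual stone in
#' contact with the stent. Several short intermittent runs
#' (`>= encrust_min_runs`, each `<= encrust_run_max_fraction` of sections)
#' match the growth pattern of encrustation. Patterns that fit neither branch
#' default to encrustation: the costly clinical error is attempting outpatient
#' removal of an encrusted stent, so ambiguity flags for review.
#'
#' @param features A `profile_features`.
#' @param thresholds A [detection_thresholds()].
#' @return `"clean"`, `"residual_stone"` or `"encrustation"`.
#' @export
classify_anomaly <- function(features, thresholds = detection_thresholds()) {
  stopifnot(inherits(features, "profile_features"))
  n <- features$n_sections
  if (features$n_runs == 0) return("clean")
  if (features$longest_run / n >= thresholds$stone_run_fraction &&
      features$max_relative_elevation >= thresholds$stone_magnitude &&
      features$n_runs <= 2)
    return("residual_stone")
  if (features$n_runs >= thresholds$encrust_min_runs &&
      all(features$runs$len / n <= thresholds$encrust_run_max_fraction))
    return("encrustation")
  "encrustation"
}

#' Aggregate per-segment classes into a case verdict
#'
#' Encrustation (the positive finding) dominates: if any segment classifies
#' as encrustation the verdict is `"encrustation"`; otherwise any residual
#' stone gives `"residual_stone"`; with no segments the case is
#' `"negative"`.
#'
#' @param segments Anomaly segments (from [detect_area_anomalies()]).
#' @param per_segment_class Character vector, one class per segment.
#' @param case_id Identifier for the report.
#' @param provenance Provenance list stored in the report.
#' @return A [case_report()].
#' @export
decide_case <- function(segments, per_segment_class, case_id = "case",
                        provenance = list()) {
  stopifnot(length(segments) == length(per_segment_class))
  keep <- per_segment_class != "clean"
  segments <- segments[keep]
  per_segment_class <- per_segment_class[keep]
  verdict <- if (length(segments) == 0) "negative"
  else if (any(per_segment_class == "encrustation")) "encrustation"
  else "residual_stone"
  segs <- mapply(function(s, cls) {
    s$class <- cls
    s
  }, segments, per_segment_class, SIMPLIFY = FALSE)
  case_report(case_id, verdict, segments = segs, provenance = provenance)
}
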