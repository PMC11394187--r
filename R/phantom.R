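# Synthetic CT phantoms with exact ground truth.
#
# The generator renders a bright curved tube (the stent) of known analytic
# centerline and radius into an anisotropic HU grid, optionally decorated
# with the three stent morphologies seen clinically: intermittent radial
# bumps fused to the wall (encrustation), a single compact sphere touching
# the wall (residual stone), scattered bright blobs away from the tube
# (loose fragments) and a large compact bone-like distractor. Gaussian HU
# noise is added last. The same spec and seed always render the same volume.

#' Construct a phantom specification
#'
#' @param dim Grid shape (voxels), length 3.
#' @param spacing Voxel spacing (mm), length 3; anisotropic by default to
#'   exercise physical-unit handling.
#' @param family Centerline family: `"straight"`, `"tilted"`, `"helix"` or
#'   `"piecewise_j"`.
#' @param tube_radius_mm Stent outer radius (mm).
#' @param tilt_deg Tilt from vertical for the `"tilted"` family (degrees).
#' @param helix_radius_mm,helix_turns,helix_phase Helix geometry.
#' @param z_margin_mm Axial clearance between tube ends and volume faces.
#' @param tube_hu,background_hu,stone_hu,bone_hu HU palette. Stent and stone
#'   attenuation deliberately overlap so thresholding alone cannot separate
#'   them.
#' @param noise_sd Gaussian HU noise standard deviation.
#' @param encrustations List of bumps, each
#'   `list(arc_pos, angle, width, height_mm, length_mm)`: arc position as a
#'   fraction of arc length, angular centre/width (rad) around the local
#'   frame, radial height and along-arc length (mm).
#' @param residual_stone `NULL` or `list(arc_pos, radius_mm, offset_mm,
#'   angle)`; `offset_mm = 0` means touching the wall.
#' @param loose_stones `list(count, radius_range)` scattered blobs not
#'   touching the tube.
#' @param bone Logical: add a compact bright ellipsoid distractor.
#' @param gap `NULL` or `list(arc_pos, n_slices)`: z-slices of the tube
#'   blanked out to emulate a segmentation dropout.
#' @param seed Integer; fully determines the rendered volume.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dim = c(96, 96, 120), spacing = c(0.7, 0.7, 1.25),
                         family = c("helix", "straight", "tilted",
                                    "piecewise_j"),
                         tube_radius_mm = 2.5, tilt_deg = 15,
                         helix_radius_mm = 10, helix_turns = 1,
                         helix_phase = 0, z_margin_mm = 8,
                         tube_hu = 900, background_hu = 20, stone_hu = 700,
                         bone_hu = 1100, noise_sd = 15,
                         encrustations = list(), residual_stone = NULL,
                         loose_stones = list(count = 0,
                                             radius_range = c(2, 4)),
                         bone = FALSE, gap = NULL, seed = 1) {
  family <- match.arg(family)
  spec <- list(dim = as.integer(dim), spacing = as.numeric(spacing),
               family = family, tube_radius_mm = tube_radius_mm,
               tilt_deg = tilt_deg, helix_radius_mm = helix_radius_mm,
               helix_turns = helix_turns, helix_phase = helix_phase,
               z_margin_mm = z_margin_mm, tube_hu = tube_hu,
               background_hu = background_hu, stone_hu = stone_hu,
               bone_hu = bone_hu, noise_sd = noise_sd,
               encrustations = encrustations, residual_stone = residual_stone,
               loose_stones = loose_stones, bone = bone, gap = gap,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (length(spec$dim) != 3 || any(spec$dim < 8))
    stop("phantom grid must be 3D with at least 8 voxels per axis")
  if (any(spec$spacing <= 0)) stop("phantom spacing must be positive")
  if (spec$tube_radius_mm <= 0) stop("tube radius must be positive")
  for (b in spec$encrustations) {
    if (b$height_mm <= 0)
      stop("encrustation bump radial height must be positive")
    if (b$arc_pos < 0 || b$arc_pos > 1)
      stop("encrustation arc position must lie in [0, 1]")
  }
  rs <- spec$residual_stone
  if (!is.null(rs)) {
    if (rs$offset_mm < 0) stop("residual stone offset must be >= 0")
    if (rs$radius_mm <= 0) stop("residual stone radius must be positive")
    # centre distance with the half-voxel contact interpenetration
    d <- spec$tube_radius_mm + rs$offset_mm + rs$radius_mm -
      0.5 * max(spec$spacing)
    if (d <= spec$tube_radius_mm)
      stop("residual stone centre would sit inside the tube; ",
           "increase its radius or offset")
  }
  if (spec$loose_stones$count < 0) stop("loose stone count must be >= 0")
  invisible(spec)
}

# Analytic centerline of a spec: function t in [0,1] -> mm point.
phantom_centerline_fun <- function(spec) {
  ext <- (spec$dim - 1) * spec$spacing
  cx <- ext[1] / 2; cy <- ext[2] / 2
  z0 <- spec$z_margin_mm; z1 <- ext[3] - spec$z_margin_mm
  switch(spec$family,
    straight = function(t) cbind(cx, cy, z0 + t * (z1 - z0)),
    tilted = function(t) {
      dz <- z1 - z0
      dx <- dz * tan(spec$tilt_deg * pi / 180)
      cbind(cx - dx / 2 + t * dx, cy, z0 + t * dz)
    },
    helix = function(t) {
      ang <- spec$helix_phase + 2 * pi * spec$helix_turns * t
      cbind(cx + spec$helix_radius_mm * cos(ang),
            cy + spec$helix_radius_mm * sin(ang),
            z0 + t * (z1 - z0))
    },
    piecewise_j = function(t) {
      # vertical limb (t in [0, 0.75]) blending into a circular hook at the
      # superior end, tangent-continuous at the join
      rho <- spec$helix_radius_mm
      tb <- 0.75
      zj <- z1 - rho
      straight_len <- zj - z0
      hook_angle <- pi * 0.75
      out <- matrix(0, length(t), 3)
      lower <- t <= tb
      out[lower, ] <- cbind(cx - rho / 2, cy,
                            z0 + (t[lower] / tb) * straight_len)
      a <- (t[!lower] - tb) / (1 - tb) * hook_angle
      out[!lower, ] <- cbind(cx - rho / 2 + rho * (1 - cos(a)), cy,
                             zj + rho * sin(a))
      out
    })
}

# Dense arc-length-uniform samples of the centerline with tangents and local
# frames (same deterministic basis rule as the re-slicer).
sample_centerline <- function(spec, step_mm = 0.5) {
  f <- phantom_centerline_fun(spec)
  tt <- seq(0, 1, length.out = 4096)
  p <- f(tt)
  s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  total <- s[length(s)]
  target <- seq(0, total, by = step_mm)
  if (target[length(target)] < total) target <- c(target, total)
  ts <- stats::approx(s, tt, xout = target, ties = "ordered")$y
  pts <- f(ts)
  eps <- 1e-4
  tang <- (f(pmin(ts + eps, 1)) - f(pmax(ts - eps, 0)))
  tang <- tang / sqrt(rowSums(tang^2))
  list(t = ts, s = target, frac = target / total, points = pts,
       tangents = tang, total = total)
}

# 1-based linear indices of voxels within `radius` mm of `center` mm.
ball_voxels <- function(dim, spacing, center, radius) {
  lo <- pmax(floor((center - radius) / spacing), 0)
  hi <- pmin(ceiling((center + radius) / spacing), dim - 1)
  if (any(hi < lo)) return(integer(0))
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  g <- expand.grid(i = ii, j = jj, k = kk)
  d2 <- (g$i * spacing[1] - center[1])^2 + (g$j * spacing[2] - center[2])^2 +
    (g$k * spacing[3] - center[3])^2
  keep <- d2 <= radius^2
  (1 + g$i + dim[1] * (g$j + dim[2] * g$k))[keep]
}

#' Render a phantom volume and its ground truth
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (a [ct_volume()]) and `truth`: analytic
#'   centerline samples (`centerline_mm`), pairwise-disjoint class masks
#'   (`tube`, `encrustation`, `residual_stone`, `loose_stones`, `bone` as
#'   logical arrays), `label` (`"negative"`, `"residual_stone"` or
#'   `"encrustation"`), and `anomaly_intervals` (arc fractions).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  dm <- spec$dim; sp <- spec$spacing
  nvox <- prod(dm)
  cl <- sample_centerline(spec, step_mm = min(sp) / 2)
  rt <- spec$tube_radius_mm

  # --- tube ---
  tube_idx <- integer(0)
  acc <- vector("list", nrow(cl$points))
  for (k in seq_len(nrow(cl$points)))
    acc[[k]] <- ball_voxels(dm, sp, cl$points[k, ], rt)
  tube_idx <- unique(unlist(acc))
  tube <- logical(nvox); tube[tube_idx] <- TRUE

  slab_half <- 0.75 * max(min(sp) / 2 * 2, max(sp))
  frame_for <- function(k) section_basis(cl$tangents[k, ])

  # --- encrustation bumps ---
  enc <- logical(nvox)
  intervals <- list()
  for (b in spec$encrustations) {
    half_arc <- b$length_mm / 2 / cl$total
    intervals[[length(intervals) + 1]] <-
      c(max(0, b$arc_pos - half_arc), min(1, b$arc_pos + half_arc))
    ks <- which(abs(cl$frac - b$arc_pos) <= half_arc)
    for (k in ks) {
      fr <- frame_for(k)
      cand <- ball_voxels(dm, sp, cl$points[k, ], rt + b$height_mm)
      if (length(cand) == 0) next
      ai <- arrayInd(cand, dm) - 1
      d <- sweep(sweep(ai, 2, sp, "*"), 2, cl$points[k, ], "-")
      axial <- d %*% fr$t
      ok <- abs(axial) <= slab_half
      rho2 <- rowSums(d^2) - axial^2
      ang <- atan2(d %*% fr$v, d %*% fr$u) %% (2 * pi)
      dif <- abs(((ang - b$angle + pi) %% (2 * pi)) - pi)
      ok <- ok & dif <= b$width / 2 & rho2 <= (rt + b$height_mm)^2
      enc[cand[ok]] <- TRUE
    }
  }
  enc <- enc & !tube

  # --- residual stone ---
  stone <- logical(nvox)
  rs <- spec$residual_stone
  if (!is.null(rs)) {
    k <- which.min(abs(cl$frac - rs$arc_pos))
    fr <- frame_for(k)
    centre_dist <- rt + rs$offset_mm + rs$radius_mm - 0.5 * max(sp)
    centre <- cl$points[k, ] + centre_dist *
      (cos(rs$angle) * fr$u + sin(rs$angle) * fr$v)
    stone[ball_voxels(dm, sp, centre, rs$radius_mm)] <- TRUE
    stone <- stone & !tube & !enc
    half_arc <- rs$radius_mm / cl$total
    intervals[[length(intervals) + 1]] <-
      c(max(0, rs$arc_pos - half_arc), min(1, rs$arc_pos + half_arc))
  }

  # --- seeded placement of distractors + noise ---
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(spec$seed)

  ext <- (dm - 1) * sp
  bone_mask <- logical(nvox)
  bone_centre <- NULL
  if (isTRUE(spec$bone)) {
    bone_centre <- c(0.17 * ext[1], 0.8 * ext[2], 0.5 * ext[3])
    semi <- c(8, 6, 25)
    lo <- pmax(floor((bone_centre - semi) / sp), 0)
    hi <- pmin(ceiling((bone_centre + semi) / sp), dm - 1)
    g <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
    q <- ((g$i * sp[1] - bone_centre[1]) / semi[1])^2 +
      ((g$j * sp[2] - bone_centre[2]) / semi[2])^2 +
      ((g$k * sp[3] - bone_centre[3]) / semi[3])^2
    bone_mask[(1 + g$i + dm[1] * (g$j + dm[2] * g$k))[q <= 1]] <- TRUE
  }

  loose <- logical(nvox)
  n_loose <- spec$loose_stones$count
  if (n_loose > 0) {
    rr <- spec$loose_stones$radius_range
    placed <- matrix(numeric(0), ncol = 4) # x, y, z, r
    tries <- 0
    while (nrow(placed) < n_loose && tries < 2000) {
      tries <- tries + 1
      r <- stats::runif(1, rr[1], rr[2])
      pos <- c(stats::runif(1, r + 2, ext[1] - r - 2),
               stats::runif(1, r + 2, ext[2] - r - 2),
               stats::runif(1, 0.18 * ext[3], 0.82 * ext[3]))
      dmin <- min(sqrt(colSums((t(cl$points) - pos)^2)))
      if (dmin < rt + r + 3) next
      if (!is.null(bone_centre) &&
          sqrt(sum((pos - bone_centre)^2)) < 25 + r + 2) next
      if (nrow(placed) > 0) {
        dp <- sqrt(colSums((t(placed[, 1:3, drop = FALSE]) - pos)^2))
        if (any(dp < placed[, 4] + r + 2)) next
      }
      placed <- rbind(placed, c(pos, r))
    }
    for (i in seq_len(nrow(placed)))
      loose[ball_voxels(dm, sp, placed[i, 1:3], placed[i, 4])] <- TRUE
    loose <- loose & !tube & !enc & !stone
  }
  bone_mask <- bone_mask & !tube & !enc & !stone & !loose

  # --- optional axial gap in the tube ---
  if (!is.null(spec$gap)) {
    kz <- which.min(abs(cl$frac - spec$gap$arc_pos))
    z_mid <- round(cl$points[kz, 3] / sp[3])       # 0-based slice index
    zs <- z_mid + seq_len(spec$gap$n_slices) - 1 -
      floor((spec$gap$n_slices - 1) / 2)
    zs <- zs[zs >= 0 & zs < dm[3]]
    tube_arr <- array(tube, dim = dm)
    tube_arr[, , zs + 1] <- FALSE
    tube <- as.vector(tube_arr)
  }

  # --- assemble HU volume, noise last ---
  hu <- rep(spec$background_hu, nvox)
  hu[bone_mask] <- spec$bone_hu
  hu[loose] <- spec$stone_hu
  hu[stone] <- spec$stone_hu
  hu[enc] <- spec$stone_hu
  hu[tube] <- spec$tube_hu
  hu <- hu + stats::rnorm(nvox, 0, spec$noise_sd)

  label <- if (length(spec$encrustations) > 0) "encrustation"
  else if (!is.null(rs)) "residual_stone" else "negative"

  fine <- sample_centerline(spec, step_mm = 1)
  list(volume = ct_volume(array(hu, dim = dm), spacing = sp),
       truth = list(centerline_mm = fine$points,
                    arc_frac = fine$frac,
                    arc_length_mm = fine$total,
                    tube = array(tube, dim = dm),
                    encrustation = array(enc, dim = dm),
                    residual_stone = array(stone, dim = dm),
                    loose_stones = array(loose, dim = dm),
                    bone = array(bone_mask, dim = dm),
                    label = label,
                    anomaly_intervals = intervals,
                    spec = spec))
}

#' Named reproducible phantom presets
#'
#' `"clean"`: bare helical stent. `"encrusted"`: 4--7 short intermittent
#' wall bumps. `"residual"`: one large sphere touching the wall.
#' `"distractors"`: clean stent plus 5 loose fragments and a bone blob.
#' `"gapped"`: clean stent with a 3-slice segmentation dropout. Feature
#' positions, angles and sizes vary deterministically with `seed`.
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(name = c("clean", "encrusted", "residual",
                                    "distractors", "gapped"), seed = 1) {
  name <- match.arg(name)
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed * 7919 + match(name, c("clean", "encrusted", "residual",
                                       "distractors", "gapped")))
  phase <- stats::runif(1, 0, 2 * pi)
  base <- list(family = "helix", helix_phase = phase, seed = seed)
  args <- switch(name,
    clean = base,
    encrusted = {
      n <- sample(4:7, 1)
      # stratified arc positions with jitter: bumps stay well separated so
      # each produces its own elevated run
      pos <- seq(0.15, 0.85, length.out = n) + stats::runif(n, -0.02, 0.02)
      bumps <- lapply(seq_len(n), function(i)
        list(arc_pos = pos[i], angle = stats::runif(1, 0, 2 * pi),
             width = stats::runif(1, 80, 120) * pi / 180,
             height_mm = stats::runif(1, 1.6, 2.5),
             length_mm = stats::runif(1, 3, 5)))
      c(base, list(encrustations = bumps))
    },
    residual = c(base, list(residual_stone = list(
      arc_pos = stats::runif(1, 0.25, 0.75),
      radius_mm = stats::runif(1, 6.5, 7.5),
      offset_mm = 0,
      angle = stats::runif(1, 0, 2 * pi)))),
    distractors = c(base, list(loose_stones = list(count = 5,
                                                   radius_range = c(2, 4)),
                               bone = TRUE)),
    gapped = c(base, list(gap = list(arc_pos = 0.5, n_slices = 3))))
  do.call(phantom_spec, args)
}
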