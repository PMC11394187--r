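test_that("a one-voxel-wide line is its own skeleton", {
  vox <- array(FALSE, c(6, 6, 44))
  vox[3, 3, 3:42] <- TRUE
  m <- binary_mask(vox, spacing = c(1, 1, 1))
  sk <- thin_to_skeleton(m)
  expect_identical(sk$voxels, vox)
})

test_that("a solid cylinder thins to a single path along its axis", {
  m <- cylinder_mask(c(11, 11, 46), c(1, 1, 1), radius_mm = 3,
                     length_mm = 40)
  sk <- thin_to_skeleton(m)
  expect_true(all(sk$voxels[!m$voxels] == FALSE))   # skeleton subset of mask
  expect_equal(label_components(sk, 26)$n_components, 1)
  idx <- which(sk$voxels, arr.ind = TRUE)
  # axis of the cylinder is x = 6, y = 6 (1-based): within 1.5 voxels
  axis_dist <- sqrt((idx[, 1] - 6)^2 + (idx[, 2] - 6)^2)
  expect_lt(max(axis_dist), 1.5)
  # simple path: orderable without pruning
  cl <- order_skeleton(sk, prune_len = 0)
  expect_equal(nrow(cl$points), sum(sk$voxels))
})

test_that("a solid sphere thins to a few voxels near its centroid", {
  m <- cylinder_mask(c(15, 15, 15), c(1, 1, 1), radius_mm = 5,
                     length_mm = 0.1)  # not used; build sphere directly
  g <- expand.grid(i = 0:14, j = 0:14, k = 0:14)
  vox <- array((g$i - 7)^2 + (g$j - 7)^2 + (g$k - 7)^2 <= 25, c(15, 15, 15))
  sphere <- binary_mask(vox, spacing = c(1, 1, 1))
  sk <- thin_to_skeleton(sphere)
  expect_equal(label_components(sk, 26)$n_components, 1)
  expect_lte(sum(sk$voxels), 10)
  idx <- which(sk$voxels, arr.ind = TRUE)
  # every remaining voxel stays inside the sphere; their centroid is central
  expect_true(all(rowSums(sweep(idx, 2, c(8, 8, 8))^2) <= 25))
  expect_lt(sqrt(sum((colMeans(idx) - c(8, 8, 8))^2)), 3)
})

test_that("thinning preserves component count and is a fixed point", {
  set.seed(31)
  for (nm in c("clean", "residual")) {
    ph <- render_phantom(phantom_preset(nm, 3))
    m <- threshold_segment(ph$volume)
    lv <- label_components(m, 26)
    stent <- select_stent_component(component_stats(lv), lv)
    sk <- thin_to_skeleton(stent)
    expect_equal(label_components(sk, 26)$n_components,
                 label_components(stent, 26)$n_components)
    expect_true(all(stent$voxels[sk$voxels]))
    again <- thin_to_skeleton(sk)
    expect_identical(again$voxels, sk$voxels)
  }
})

test_that("skeleton ordering covers simple paths end to end", {
  vox <- array(FALSE, c(6, 6, 44))
  vox[3, 3, 3:42] <- TRUE
  cl <- order_skeleton(binary_mask(vox, spacing = c(1, 1, 1)), 0)
  expect_equal(nrow(cl$points), 40)
  expect_true(all(diff(cl$points[, 3]) < 0))  # superior end first
  d <- diff(cl$points)
  expect_true(all(sqrt(rowSums(d^2)) <= 2 * sqrt(3)))

  # L-shaped path: both arms covered, corner possibly cut diagonally
  vox <- array(FALSE, c(20, 6, 20))
  vox[3, 3, 3:15] <- TRUE
  vox[3:15, 3, 15] <- TRUE
  cl <- order_skeleton(binary_mask(vox, spacing = c(1, 1, 1)), 1)
  expect_gte(nrow(cl$points), 24)
  expect_lte(nrow(cl$points), 25)
  # ends of the path are the two arm tips
  tips <- cl$voxels[c(1, nrow(cl$voxels)), ]
  expect_setequal(paste(tips[, 1], tips[, 3]), c("3 3", "15 15"))
})

test_that("short spurs are pruned; deep branches raise a counted error", {
  vox <- array(FALSE, c(20, 8, 40))
  vox[4, 4, 3:38] <- TRUE
  vox[5:6, 4, 20] <- TRUE          # 2-voxel spur
  m <- binary_mask(vox, spacing = c(1, 1, 1))
  cl <- order_skeleton(m, prune_len = 3)
  expect_equal(nrow(cl$points), 36)

  vox[5:12, 4, 20] <- TRUE         # 8-voxel branch
  expect_error(order_skeleton(binary_mask(vox, spacing = c(1, 1, 1)),
                              prune_len = 3),
               "3 endpoints",
               class = "stentcheck_branched_skeleton")
})

test_that("spline fit reproduces straight lines exactly", {
  pts <- cbind(seq(0, 10, length.out = 30), seq(0, 5, length.out = 30),
               seq(40, 0, length.out = 30))
  cl <- structure(list(points = pts, voxels = NULL,
                       spacing = c(1, 1, 1), origin = c(0, 0, 0)),
                  class = "centerline")
  for (sm in list(0, "auto")) {
    cu <- fit_curve(cl, smoothing = sm)
    tt <- seq(0, 1, length.out = 17)
    p <- cu$eval(tt)
    # collinear: distance to the line through the endpoints
    dir <- c(10, 5, -40) / sqrt(sum(c(10, 5, -40)^2))
    rel <- sweep(p, 2, p[1, ])
    offaxis <- rel - (rel %*% dir) %*% t(dir)
    expect_lt(max(abs(offaxis)), 1e-6)
    d <- cu$deriv(tt)
    cs <- (d / sqrt(rowSums(d^2))) %*% dir
    expect_true(all(cs > 0.999))
  }
})

test_that("interpolating fit passes through every input point", {
  set.seed(32)
  tt <- seq(0, 1, length.out = 25)
  pts <- cbind(10 * cos(2 * pi * tt), 10 * sin(2 * pi * tt), 100 * tt)
  cl <- structure(list(points = pts, voxels = NULL, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)), class = "centerline")
  cu <- fit_curve(cl, smoothing = 0)
  chord <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  fitted <- cu$eval(chord / chord[length(chord)])
  expect_lt(max(abs(fitted - pts)), 1e-6)
})

test_that("fitted helix tangents match the analytic derivative within 5 degrees", {
  n <- 60
  tt <- seq(0, 1, length.out = n)
  R <- 10; H <- 100; turns <- 1.5
  pts <- cbind(R * cos(2 * pi * turns * tt), R * sin(2 * pi * turns * tt),
               H * tt)
  cl <- structure(list(points = pts, voxels = NULL, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)), class = "centerline")
  cu <- fit_curve(cl, smoothing = 0)
  chord <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  tq <- chord / chord[n]
  d <- cu$deriv(tq[5:(n - 4)])
  d <- d / sqrt(rowSums(d^2))
  analytic <- cbind(-R * 2 * pi * turns * sin(2 * pi * turns * tt),
                    R * 2 * pi * turns * cos(2 * pi * turns * tt),
                    H)[5:(n - 4), ]
  analytic <- analytic / sqrt(rowSums(analytic^2))
  angles <- acos(pmin(1, rowSums(d * analytic))) * 180 / pi
  expect_lt(max(angles), 5)
})

test_that("too few points refuse to fit", {
  cl <- structure(list(points = rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
                       voxels = NULL, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)), class = "centerline")
  expect_error(fit_curve(cl, smoothing = 0), "at least 4")
})

straight_curve <- function(z0, z1, x = 0, y = 0) {
  structure(list(
    eval = function(t) cbind(x, y, z0 + t * (z1 - z0)),
    deriv = function(t) cbind(0 * t, 0 * t, rep(z1 - z0, length(t))),
    t = NULL, n_points = 2), class = "fitted_curve")
}

test_that("perpendicular sections of a cylinder recover the analytic area", {
  sp <- c(0.7, 0.7, 1.25)
  m <- cylinder_mask(c(40, 40, 48), sp, radius_mm = 5)
  ctr <- (c(40, 40, 48) - 1) * sp / 2
  cu <- straight_curve(4, (48 - 1) * sp[3] - 4, x = ctr[1], y = ctr[2])
  secs <- extract_sections(m, cu, n_sections = 20, patch_extent_mm = 16,
                           pixel_mm = 0.25, end_margin_mm = 4)
  areas <- vapply(secs, function(s) s$area_mm2, numeric(1))
  expect_true(all(abs(areas - pi * 25) / (pi * 25) < 0.05))
})

test_that("perpendicular re-slicing undoes the tilt that distorts axial slices", {
  sp <- c(0.7, 0.7, 0.7)
  dims <- c(60, 40, 60)
  m <- cylinder_mask(dims, sp, radius_mm = 5, axis = c(1, 0, 1) / sqrt(2))
  ctr <- (dims - 1) * sp / 2
  # perpendicular sections: normal along the true axis
  ax <- c(1, 0, 1) / sqrt(2)
  cu <- structure(list(
    eval = function(t) cbind(ctr[1] + (t - 0.5) * 30 * ax[1], ctr[2],
                             ctr[3] + (t - 0.5) * 30 * ax[3]),
    deriv = function(t) matrix(rep(30 * ax, each = length(t)), ncol = 3),
    t = NULL, n_points = 2), class = "fitted_curve")
  secs <- extract_sections(m, cu, n_sections = 9, patch_extent_mm = 16,
                           pixel_mm = 0.25, end_margin_mm = 2)
  perp <- vapply(secs, function(s) s$area_mm2, numeric(1))
  expect_true(all(abs(perp - pi * 25) / (pi * 25) < 0.05))

  # axial (z) slice through the middle: ellipse area pi*a*b, b = r/cos(45 deg)
  mid <- round(dims[3] / 2)
  axial_area <- sum(m$voxels[, , mid]) * sp[1] * sp[2]
  expected <- pi * 25 / cos(pi / 4)
  expect_lt(abs(axial_area - expected) / expected, 0.05)
})

test_that("perpendicular section area is invariant to cylinder orientation", {
  set.seed(33)
  sp <- c(0.7, 0.7, 0.7)
  dims <- c(56, 56, 56)
  ctr <- (dims - 1) * sp / 2
  for (k in 1:10) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    m <- cylinder_mask(dims, sp, radius_mm = 5, axis = ax)
    cu <- structure(list(
      eval = function(t) cbind(ctr[1] + (t - 0.5) * 24 * ax[1],
                               ctr[2] + (t - 0.5) * 24 * ax[2],
                               ctr[3] + (t - 0.5) * 24 * ax[3]),
      deriv = function(t) matrix(rep(24 * ax, each = length(t)), ncol = 3),
      t = NULL, n_points = 2), class = "fitted_curve")
    secs <- extract_sections(m, cu, n_sections = 5, patch_extent_mm = 16,
                             pixel_mm = 0.25, end_margin_mm = 2)
    areas <- vapply(secs, function(s) s$area_mm2, numeric(1))
    expect_true(all(abs(areas - pi * 25) / (pi * 25) < 0.05),
                label = sprintf("orientation %d", k))
  }
})

test_that("sections of an empty mask have zero area", {
  m <- binary_mask(array(FALSE, c(20, 20, 20)), spacing = c(1, 1, 1))
  cu <- straight_curve(2, 18, x = 9.5, y = 9.5)
  secs <- extract_sections(m, cu, n_sections = 5, patch_extent_mm = 10,
                           pixel_mm = 0.5)
  expect_true(all(vapply(secs, function(s) s$area_mm2, numeric(1)) == 0))
})

test_that("section basis is orthonormal with the tangent as normal", {
  ph <- render_phantom(phantom_preset("clean", 4))
  m <- threshold_segment(ph$volume)
  lv <- label_components(m, 26)
  stent <- select_stent_component(component_stats(lv), lv)
  cu <- fit_curve(order_skeleton(thin_to_skeleton(stent), 10))
  secs <- extract_sections(stent, cu, n_sections = 12)
  for (s in secs[c(1, 6, 12)]) {
    expect_equal(sum(s$normal^2), 1, tolerance = 1e-8)
    expect_equal(sum(s$u^2), 1, tolerance = 1e-8)
    expect_equal(sum(s$v^2), 1, tolerance = 1e-8)
    expect_lt(abs(sum(s$normal * s$u)), 1e-8)
    expect_lt(abs(sum(s$normal * s$v)), 1e-8)
    expect_lt(abs(sum(s$u * s$v)), 1e-8)
  }
})

fake_sections <- function(areas) {
  lapply(seq_along(areas), function(i)
    structure(list(index = i, area_mm2 = areas[i], patch = NULL,
                   pixel_mm = 0.25), class = "cross_section"))
}

test_that("area anomaly rule finds the boundary in the sorted sequence", {
  expect_equal(detect_area_anomalies(fake_sections(rep(20, 50)), 0.3), list())

  a <- rep(1, 100); a[41:50] <- 1.8
  segs <- detect_area_anomalies(fake_sections(a * 30), 0.3)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$start, 41)
  expect_equal(segs[[1]]$end, 50)
  expect_equal(segs[[1]]$max_area, 1.8, tolerance = 1e-9)

  b <- rep(1, 100); b[11:15] <- 1.7; b[61:70] <- 1.9
  segs <- detect_area_anomalies(fake_sections(b * 12), 0.3)
  expect_length(segs, 2)
  expect_equal(segs[[1]]$start, 11); expect_equal(segs[[1]]$end, 15)
  expect_equal(segs[[2]]$start, 61); expect_equal(segs[[2]]$end, 70)
})

test_that("area anomaly rule is scale-invariant and one-sided", {
  a <- rep(1, 80); a[31:38] <- 1.9
  s1 <- detect_area_anomalies(fake_sections(a), 0.3)
  s2 <- detect_area_anomalies(fake_sections(a * 1000), 0.3)
  expect_equal(s1, s2)

  # a low-area dip must not flag the rest of the stent as anomalous
  dip <- rep(1, 80); dip[1:3] <- 0.5
  expect_equal(detect_area_anomalies(fake_sections(dip * 40), 0.3), list())
})
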