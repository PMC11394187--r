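test_that("a centred disk has a constant polar radius profile", {
  # 10 px disk at 0.25 mm: every populated bin within one pixel of 2.5 mm
  sec <- disk_section(n = 101, pixel_mm = 0.25, radius_px = 10)
  p <- polar_transform(sec, n_bins = 64)
  expect_true(all(abs(p$radius[!p$empty] - 2.5) <= 0.25))
  # finer sampling fills every bin
  fine <- disk_section(n = 101, pixel_mm = 0.0625, radius_px = 40)
  pf <- polar_transform(fine, n_bins = 64)
  expect_false(any(pf$empty))
  expect_true(all(abs(pf$radius - 2.5) <= 0.0625 * 2))
})

test_that("the outer boundary governs: annulus profile equals disk profile", {
  n <- 101; ctr <- c(51, 51)
  g <- expand.grid(i = 1:n, j = 1:n)
  d2 <- (g$i - ctr[1])^2 + (g$j - ctr[2])^2
  ring <- matrix(as.numeric(d2 <= 100 & d2 >= 36), n, n)
  disk <- matrix(as.numeric(d2 <= 100), n, n)
  mk <- function(patch) structure(
    list(index = 1, patch = patch, pixel_mm = 0.25),
    class = "cross_section")
  pr <- polar_transform(mk(ring), 64)
  pd <- polar_transform(mk(disk), 64)
  expect_equal(pr$radius, pd$radius, tolerance = 1e-12)
})

test_that("a fused bump elevates only bins inside its angular window", {
  n <- 121; ctr <- c(61, 61)
  g <- expand.grid(i = 1:n, j = 1:n)
  disk <- (g$i - ctr[1])^2 + (g$j - ctr[2])^2 <= 100
  # bump disk radius 4 px centred 9 px away at angle 0
  bump <- (g$i - (ctr[1] + 9))^2 + (g$j - ctr[2])^2 <= 16
  patch <- matrix(as.numeric(disk | bump), n, n)
  sec <- structure(list(index = 1, patch = patch, pixel_mm = 0.25),
                   class = "cross_section")
  p <- polar_transform(sec, n_bins = 64)
  base <- polar_transform(disk_section(n = n, radius_px = 10,
                                       centre = ctr), 64)
  # analytic half-angle of the bump seen from the disk centre, plus slack for
  # the centroid shift the bump itself causes
  half <- asin(4 / 9) + 0.35
  inside <- abs(((p$angles + pi) %% (2 * pi)) - pi) <= half
  expect_true(any(p$radius[inside] > 2.5 + 0.25))
  ok <- !inside & !p$empty & !base$empty
  expect_true(all(abs(p$radius[ok] - base$radius[ok]) <= 0.3))
})

test_that("polar profiles are rotation-equivariant within one bin", {
  n <- 121; ctr <- c(61, 61)
  n_bins <- 64
  mkbump <- function(theta) {
    g <- expand.grid(i = 1:n, j = 1:n)
    disk <- (g$i - ctr[1])^2 + (g$j - ctr[2])^2 <= 144
    bump <- (g$i - (ctr[1] + 11 * cos(theta)))^2 +
      (g$j - (ctr[2] + 11 * sin(theta)))^2 <= 16
    structure(list(index = 1, patch = matrix(as.numeric(disk | bump), n, n),
                   pixel_mm = 0.25), class = "cross_section")
  }
  p0 <- polar_transform(mkbump(0), n_bins)
  shift_bins <- 16                       # 90 degrees
  p90 <- polar_transform(mkbump(pi / 2), n_bins)
  rolled <- c(p0$radius[(n_bins - shift_bins + 1):n_bins],
              p0$radius[1:(n_bins - shift_bins)])
  expect_lt(max(abs(p90$radius - rolled)), 2 * 0.25 + 1e-9)
})

test_that("polar profiles are translation-invariant (centroid centring)", {
  a <- polar_transform(disk_section(n = 121, radius_px = 10,
                                    centre = c(61, 61)), 64)
  b <- polar_transform(disk_section(n = 121, radius_px = 10,
                                    centre = c(41, 75)), 64)
  expect_lt(max(abs(a$radius - b$radius)), 0.25 + 1e-9)
})

test_that("an empty section is an error distinct from an all-zero profile", {
  sec <- structure(list(index = 1, patch = matrix(0, 11, 11),
                        pixel_mm = 0.25), class = "cross_section")
  expect_error(polar_transform(sec, 64), class = "stentcheck_empty_section")
})

test_that("profile features summarise elevation runs correctly", {
  thr <- detection_thresholds()
  clean <- profile_set(100, integer(0))
  f <- profile_features(clean, thr)
  expect_equal(f$n_runs, 0)
  expect_equal(sum(f$elevated), 0)
  expect_equal(f$baseline_mm, 2.5)

  one_run <- profile_set(100, 40:49, factor = 1.8)
  f1 <- profile_features(one_run, thr)
  expect_equal(f1$n_runs, 1)
  expect_equal(f1$longest_run, 10)
  expect_equal(f1$max_relative_elevation, 0.8, tolerance = 1e-9)

  scattered <- profile_set(100, c(10, 22, 37, 51, 70), factor = 1.8)
  f2 <- profile_features(scattered, thr)
  expect_equal(f2$n_runs, 5)
  expect_equal(f2$longest_run, 1)
})

test_that("single-section near-threshold blips are treated as noise", {
  thr <- detection_thresholds()
  blip <- profile_set(100, 55, factor = 1.2)   # 20% for one section only
  f <- profile_features(blip, thr)
  expect_equal(f$n_runs, 0)
  expect_equal(classify_anomaly(f, thr), "clean")
})

test_that("anomalous sections are excluded from the baseline", {
  thr <- detection_thresholds()
  profs <- profile_set(50, 10:30, factor = 1.6)  # elevation in 21 of 50
  f_excl <- profile_features(profs, thr, anomalous_idx = 10:30)
  expect_equal(f_excl$baseline_mm, 2.5)
})

test_that("classification separates the three morphologies", {
  thr <- detection_thresholds()
  expect_equal(classify_anomaly(profile_features(profile_set(100, integer(0)),
                                                 thr), thr), "clean")
  # one contiguous run covering 12% with 80% elevation -> residual stone
  stone <- profile_features(profile_set(100, 45:56, factor = 1.8), thr)
  expect_equal(classify_anomaly(stone, thr), "residual_stone")
  # six scattered runs of 1-3 sections at 25% elevation -> encrustation
  idx <- c(10, 11, 25, 26, 27, 40, 55, 56, 70, 71, 85, 86, 87)
  enc <- profile_features(profile_set(150, idx, factor = 1.25), thr)
  expect_equal(classify_anomaly(enc, thr), "encrustation")
})

test_that("raising elevation_delta never converts clean to non-clean", {
  set.seed(41)
  for (rep in 1:20) {
    idx <- sample(100, sample(0:12, 1))
    factor <- runif(1, 1.1, 2)
    profs <- profile_set(100, idx, factor = factor)
    lo <- detection_thresholds(elevation_delta = 0.15)
    hi <- detection_thresholds(elevation_delta = 0.4)
    cls_lo <- classify_anomaly(profile_features(profs, lo), lo)
    cls_hi <- classify_anomaly(profile_features(profs, hi), hi)
    if (cls_lo == "clean") expect_equal(cls_hi, "clean")
  }
})

test_that("case verdicts follow the stated precedence", {
  expect_equal(decide_case(list(), character(0))$verdict, "negative")

  seg <- function(s, e) list(start = s, end = e, mean_area = 1.5,
                             max_area = 1.8)
  both <- decide_case(list(seg(10, 14), seg(60, 69)),
                      c("residual_stone", "encrustation"))
  expect_equal(both$verdict, "encrustation")

  stone_only <- decide_case(list(seg(10, 14)), "residual_stone")
  expect_equal(stone_only$verdict, "residual_stone")
  expect_length(stone_only$segments, 1)
  expect_equal(stone_only$segments[[1]]$class, "residual_stone")
})
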