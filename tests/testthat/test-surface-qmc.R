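test_that("the 4-D Sobol generator reproduces the canonical sequence", {
  # reference values of the unscrambled Joe-Kuo sequence (dimensions 1-4)
  expect_equal(sobol_points(7, skip = 1), matrix(c(
    0.500, 0.500, 0.500, 0.500,
    0.750, 0.250, 0.250, 0.250,
    0.250, 0.750, 0.750, 0.750,
    0.375, 0.375, 0.625, 0.875,
    0.875, 0.875, 0.125, 0.375,
    0.625, 0.125, 0.875, 0.625,
    0.125, 0.625, 0.375, 0.125), 7, 4, byrow = TRUE))
  expect_equal(sobol_points(4, skip = 1000), matrix(c(
    0.2197265625, 0.0966796875, 0.5185546875, 0.6767578125,
    0.7197265625, 0.5966796875, 0.0185546875, 0.1767578125,
    0.9697265625, 0.3466796875, 0.7685546875, 0.9267578125,
    0.4697265625, 0.8466796875, 0.2685546875, 0.4267578125),
    4, 4, byrow = TRUE))
  expect_identical(sobol_points(100, skip = 17), sobol_points(100, skip = 17))
  # a skipped subsequence continues the base sequence
  expect_equal(sobol_points(50, skip = 31)[1, ], sobol_points(40, skip = 1)[31, ])
})

test_that("the enclosing ball strictly contains the flap", {
  g <- array(FALSE, c(5, 5, 5))
  g[3, 3, 3] <- TRUE
  single <- voxel_mask(g)
  b1 <- enclosing_ball(single, margin_factor = 1.2)
  expect_equal(b1$radius_mm, 1.2 * sqrt(3) / 2, tolerance = 1e-10)
  flap <- crop_mask(split50()$true_flap)
  b <- enclosing_ball(flap)
  d <- sqrt(rowSums(sweep(mask_coordinates(flap), 2, b$center_mm)^2))
  expect_true(all(d < b$radius_mm))
  expect_equal(b$surface_area_cm2, 4 * pi * b$radius_mm^2 / 100)
})

test_that("chords realize the kinematic line measure on the ball", {
  b <- structure(list(center_mm = c(1, 2, 3), radius_mm = 60,
                      surface_area_cm2 = 4 * pi * 3600 / 100),
                 class = "enclosing_ball")
  ch <- generate_chords(b, 20000)
  r0 <- sqrt(rowSums(sweep(ch$p0, 2, b$center_mm)^2))
  r1 <- sqrt(rowSums(sweep(ch$p1, 2, b$center_mm)^2))
  expect_lt(max(abs(c(r0, r1) - 60)), 1e-6 * 60)
  # every chord meets the ball: exactly 2 surface points each
  expect_identical(nrow(ch$p0) + nrow(ch$p1), 40000L)
  # low-discrepancy directions average out
  expect_lt(sqrt(sum(colMeans(ch$directions)^2)), 0.02)
  ch2 <- generate_chords(b, 20000)
  expect_identical(ch, ch2)
})

test_that("crossing counts match simple geometric cases", {
  ball <- fixture("ball15", function() ball_mask(15, n = 40))
  ctr <- mask_centroid(ball)
  diam <- list(p0 = matrix(ctr - c(30, 0, 0), 1), p1 = matrix(ctr + c(30, 0, 0), 1))
  expect_identical(count_crossings(ball, diam), 2L)
  miss <- list(p0 = matrix(c(0, 0, 0), 1), p1 = matrix(c(1, 1, 1), 1))
  expect_identical(count_crossings(ball, miss), 0L)
  n <- 40
  ax <- (seq_len(n) - 1) - (n - 1) / 2
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  sh <- voxel_mask(array(r2 <= 225 & r2 >= 100, c(n, n, n)))
  expect_identical(count_crossings(sh, diam), 4L)
})

test_that("the Crofton estimate recovers the sphere area", {
  est <- qmc_area(ball30(), n_lines = 20000)
  expect_rel_error(est$metadata$total_area_cm2, 4 * pi * 9, 0.03)
  expect_identical(est$metadata$n_b, 40000L)
  expect_identical(est$metadata$n %% 2L, 0L)
})

test_that("the estimator is scale equivariant", {
  m1 <- ball_mask(10, n = 28, spacing = 1)
  m2 <- m1
  m2$spacing <- m1$spacing * 2
  e1 <- qmc_area(m1, 5000)
  e2 <- qmc_area(m2, 5000)
  expect_equal(e2$area_cm2, 4 * e1$area_cm2, tolerance = 1e-10)
})

test_that("halving overestimates the outer area of small thick patches", {
  spec <- shell50_spec()
  rp <- remove_patch(shell50(), spec, patch_spec(0, 0.35, 1.0, 1.6))
  est <- qmc_area(crop_mask(rp$true_flap), 20000)
  expect_gt(est$area_cm2, rp$true_outer_area_cm2)
})

test_that("a chord set that misses the flap yields zero with a warning", {
  g <- array(FALSE, c(5, 5, 5))
  g[3, 3, 3] <- TRUE
  expect_warning(est <- qmc_area(voxel_mask(g), n_lines = 1,
                                 margin_factor = 50), "no chord")
  expect_identical(est$area_cm2, 0)
})
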