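test_that("spherical cap and ellipse base formulas reproduce reference values", {
  # cap: flat disk, hemisphere, generic; ellipse: circle, degenerate, generic
  expect_equal(spherical_cap_area(100, 0), 78.53982, tolerance = 1e-6)
  expect_equal(spherical_cap_area(100, 50), 157.0796, tolerance = 1e-6)
  expect_equal(spherical_cap_area(120, 30), pi * (3600 + 900) / 100)
  expect_equal(ellipse_base_area(100, 100), 78.53982, tolerance = 1e-6)
  expect_equal(ellipse_base_area(0, 120), 0)
  expect_equal(ellipse_base_area(150, 120), pi / 4 * 150 * 120 / 100)
  expect_error(spherical_cap_area(-1, 2), "non-negative")
  expect_error(ellipse_base_area(10, -2), "non-negative")
})

test_that("dome patch area matches closed forms and adaptive quadrature", {
  expect_equal(dome_patch_outer_area(dome_patch(50, pi, 0, pi)),
               4 * pi * 25, tolerance = 1e-10)
  expect_equal(dome_patch_outer_area(dome_patch(50, pi, 0, pi / 2)),
               2 * pi * 25, tolerance = 1e-10)
  # independent oracle: 2-D quadrature of the surface element R^2 sin(polar)
  skip_if_not_installed("pracma")
  p <- dome_patch(50, 0.5, 0.8, 1.8)
  q <- pracma::integral2(function(az, pol) 50^2 * sin(pol),
                         -0.5, 0.5, 0.8, 1.8, reltol = 1e-10)$Q / 100
  expect_equal(dome_patch_outer_area(p), q, tolerance = 1e-6)
})

test_that("dome patch area is monotone in azimuthal and polar extent", {
  thetas <- seq(0.2, 2.8, length.out = 8)
  areas <- vapply(thetas, function(th)
    dome_patch_outer_area(dome_patch(60, th, 0.6, 1.9)), numeric(1))
  expect_true(all(diff(areas) > 0))
  his <- seq(0.9, 2.9, length.out = 8)
  areas <- vapply(his, function(hi)
    dome_patch_outer_area(dome_patch(60, 1, 0.6, hi)), numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("chord lengths match a brute-force extremal search on the patch", {
  p <- dome_patch(50, 0.5, 0.8, 1.8)
  cl <- chord_lengths(p)
  # brute force A: densely sample each polar ring of the patch and take the
  # maximal in-plane pairwise distance over rings
  pol <- seq(0.8, 1.8, length.out = 400)
  az <- seq(-0.5, 0.5, length.out = 400)
  ring_max <- vapply(pol, function(pp) {
    x <- 50 * sin(pp) * cos(az)
    y <- 50 * sin(pp) * sin(az)
    max(dist(cbind(x, y)))
  }, numeric(1))
  expect_equal(cl$A_mm, max(ring_max), tolerance = 1e-4)
  # C is the axial extent of the patch, C' the great-circle chord
  zs <- 50 * cos(pol)
  expect_equal(cl$C_mm, max(zs) - min(zs), tolerance = 1e-10)
  expect_equal(cl$C_prime_mm, 2 * 50 * sin(0.5), tolerance = 1e-10)
})

test_that("chord length edge cases and ordering invariants hold", {
  tiny <- chord_lengths(dome_patch(40, 0.7, 1.0, 1.0001))
  expect_lt(tiny$C_mm, 0.01)
  expect_lt(tiny$C_prime_mm, 0.01)
  full <- chord_lengths(dome_patch(40, 0.7, 0, pi))
  expect_equal(full$C_mm, 80, tolerance = 1e-10)
  expect_equal(full$C_prime_mm, 80, tolerance = 1e-10)
  # C <= C' <= 2R over a sweep
  set.seed(7)
  for (i in 1:40) {
    lo <- runif(1, 0, 2.5)
    cl <- chord_lengths(dome_patch(60, runif(1, 0.1, 3.1), lo,
                                   runif(1, lo + 0.05, pi)))
    expect_lte(cl$C_mm, cl$C_prime_mm + 1e-12)
    expect_lte(cl$C_prime_mm, 120 + 1e-12)
  }
})

test_that("A x C approximates the patch area within 15% for moderate patches", {
  # for equatorial patches the ratio A*C / S equals sin(theta)/theta exactly,
  # so the 15% band holds precisely for theta <= 0.95 rad
  for (theta in c(0.4, 0.7, 0.95)) {
    for (extent in c(0.4, 0.8, 1.2)) {
      p <- dome_patch(75, theta, (pi - extent) / 2, (pi + extent) / 2)
      cl <- chord_lengths(p)
      s_ac <- cl$A_mm * cl$C_mm / 100
      expect_rel_error(s_ac, dome_patch_outer_area(p), 0.15)
    }
  }
})
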