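#' Ball enclosing a flap mask
#'
#' The Cauchy-Crofton estimator needs a reference body with known surface
#' area containing the flap.  The ball is centred at the flap bounding-box
#' centre with radius `margin_factor` times the minimal bounding radius, so
#' every flap voxel centre lies strictly inside.
#'
#' @param flap A non-empty [voxel_mask()].
#' @param margin_factor Radius safety factor (>= 1).
#' @return An `enclosing_ball`: list with `center_mm`, `radius_mm` and
#'   `surface_area_cm2` (`4 pi R^2`).
#' @export
enclosing_ball <- function(flap, margin_factor = 1.05) {
  assert_mask(flap)
  stopifnot(margin_factor >= 1)
  xyz <- mask_coordinates(flap)
  if (nrow(xyz) == 0L) stop("flap mask is empty", call. = FALSE)
  center <- (apply(xyz, 2, min) + apply(xyz, 2, max)) / 2
  r_min <- sqrt(max(rowSums(sweep(xyz, 2, center)^2)))
  if (r_min == 0) r_min <- sqrt(sum((flap$spacing / 2)^2)) # single voxel
  radius <- margin_factor * r_min
  structure(
    list(center_mm = as.numeric(center), radius_mm = radius,
         surface_area_cm2 = 4 * pi * radius^2 / 100),
    class = "enclosing_ball"
  )
}

#' Quasi-random chords of an enclosing ball
#'
#' Maps each 4-D Sobol point `(u1, u2, u3, u4)` to a line meeting the ball:
#' the direction comes from the area-preserving sphere map
#' (`z = 2 u1 - 1`, azimuth `2 pi u2`), and the line offset from the centre
#' is a point in the perpendicular disk of radius `R`, at radius `R sqrt(u3)`
#' and angle `2 pi u4`.  This is the invariant kinematic measure on lines
#' meeting the ball, the measure under which Crofton crossing counts are
#' unbiased.  Every line hits the ball, so a set of `n` chords contributes
#' exactly `2 n` line-ball surface intersections.
#'
#' @param ball An [enclosing_ball()].
#' @param n_lines Number of chords (>= 1).
#' @param skip Sobol start index (see [sobol_points()]).
#' @return A `chord_set`: list with `p0`, `p1` (n x 3 matrices of chord
#'   endpoints on the ball surface, mm), `directions`, `n_lines`, `skip`,
#'   `ball`.
#' @export
generate_chords <- function(ball, n_lines, skip = 1L) {
  stopifnot(inherits(ball, "enclosing_ball"), n_lines >= 1)
  u <- sobol_points(n_lines, skip)
  z <- 2 * u[, 1] - 1
  s <- sqrt(pmax(0, 1 - z^2))
  phi <- 2 * pi * u[, 2]
  w <- cbind(s * cos(phi), s * sin(phi), z)         # chord direction
  # orthonormal frame (e1, e2) perpendicular to w; seed axis = least aligned
  seed <- diag(3)[max.col(-abs(w), ties.method = "first"), , drop = FALSE]
  e1 <- cbind(w[, 2] * seed[, 3] - w[, 3] * seed[, 2],
              w[, 3] * seed[, 1] - w[, 1] * seed[, 3],
              w[, 1] * seed[, 2] - w[, 2] * seed[, 1])
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(w[, 2] * e1[, 3] - w[, 3] * e1[, 2],
              w[, 3] * e1[, 1] - w[, 1] * e1[, 3],
              w[, 1] * e1[, 2] - w[, 2] * e1[, 1])
  R <- ball$radius_mm
  rho <- R * sqrt(u[, 3])
  psi <- 2 * pi * u[, 4]
  q <- matrix(ball$center_mm, n_lines, 3, byrow = TRUE) +
    rho * cos(psi) * e1 + rho * sin(psi) * e2
  half <- sqrt(pmax(0, R^2 - rho^2))
  structure(
    list(p0 = q - half * w, p1 = q + half * w, directions = w,
         n_lines = as.integer(n_lines), skip = as.integer(skip), ball = ball),
    class = "chord_set"
  )
}

#' @export
print.chord_set <- function(x, ...) {
  cat(sprintf("<chord_set> %d chords of a %.1f mm ball (skip %d)\n",
              x$n_lines, x$ball$radius_mm, x$skip))
  invisible(x)
}

#' Count flap surface crossings along chords
#'
#' Marches each chord at a step of at most `min(spacing) / 2` and counts the
#' crossings of the flap surface, taken -- exactly as in the mesh estimator
#' -- as the level-0.5 isosurface of the Gaussian-smoothed occupancy field,
#' sampled by trilinear interpolation.  (Counting raw nearest-voxel binary
#' transitions instead would measure the staircase boundary, whose area
#' exceeds the smooth surface by tens of percent; see the package vignette.)
#' For a flap strictly inside the ball every chord yields an even count.
#'
#' @param flap A [voxel_mask()].
#' @param chords A chord set from [generate_chords()], or a list with
#'   matrices `p0` and `p1`.
#' @param smooth_sigma Gaussian sigma in voxels defining the sampled surface;
#'   0 uses the trilinearly interpolated binary field.
#' @param field Optional precomputed [occupancy field][extract_mesh] (an
#'   internal optimization used when many chord sets probe one flap).
#' @return Integer vector of per-chord crossing counts.
#' @export
count_crossings <- function(flap, chords, smooth_sigma = 1, field = NULL) {
  assert_mask(flap)
  p0 <- chords$p0
  p1 <- chords$p1
  stopifnot(is.matrix(p0), is.matrix(p1), ncol(p0) == 3, ncol(p1) == 3)
  of <- field %||% occupancy_field(flap, smooth_sigma)
  cpp_count_crossings_field(of$field, dim(of$field), of$spacing, of$origin,
                            p0, p1, min(of$spacing) / 2, 0.5)
}

#' Cauchy-Crofton quasi-Monte Carlo outer-area estimate
#'
#' Encloses the flap in a ball of known surface area `S_b`, casts `n_lines`
#' Sobol chords, counts the total number `n` of chord-flap surface crossings
#' and estimates the total flap surface area as `S = (n / n_b) S_b`, where
#' `n_b = 2 n_lines` is the number of chord-ball intersections.  Because the
#' flap has two principal sides, `S` is halved to give the outer-surface
#' estimate.
#'
#' @param flap A non-empty [voxel_mask()].
#' @param n_lines Number of chords.
#' @param skip Sobol start index (replicate runs use different skips).
#' @param margin_factor Passed to [enclosing_ball()].
#' @param smooth_sigma Surface definition, see [count_crossings()].
#' @return An [area_estimate()] with metadata `n`, `n_b`, `S_b_cm2`,
#'   `radius_mm`, `total_area_cm2`, `n_lines`, `skip`.  A zero crossing count
#'   yields a zero estimate with a warning.
#' @export
qmc_area <- function(flap, n_lines = 20000L, skip = 1L, margin_factor = 1.05,
                     smooth_sigma = 1) {
  ball <- enclosing_ball(flap, margin_factor)
  chords <- generate_chords(ball, n_lines, skip)
  n <- sum(count_crossings(flap, chords, smooth_sigma))
  n_b <- 2L * as.integer(n_lines)
  total <- (n / n_b) * ball$surface_area_cm2
  if (n == 0L) {
    warning("no chord crossed the flap surface; estimate is 0", call. = FALSE)
  }
  area_estimate(
    "qmc",
    total / 2,
    list(n = n, n_b = n_b, S_b_cm2 = ball$surface_area_cm2,
         radius_mm = ball$radius_mm, total_area_cm2 = total,
         n_lines = as.integer(n_lines), skip = as.integer(skip))
  )
}
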