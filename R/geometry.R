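#' Spherical cap surface area
#'
#' Classic estimate of a craniectomy surface area that models the defect as a
#' spherical cap over the bulging brain: `A = pi * ((d/2)^2 + h^2)`, where
#' `d` is the anteroposterior diameter of the defect and `h` the longest
#' perpendicular distance from `d` to the dural surface.
#'
#' @param d_mm Cap base diameter in mm (>= 0).
#' @param h_mm Cap height in mm (>= 0).
#' @return Area in cm^2.
#' @examples
#' spherical_cap_area(100, 50) # hemisphere of radius 50 mm
#' @export
spherical_cap_area <- function(d_mm, h_mm) {
  if (any(d_mm < 0) || any(h_mm < 0)) {
    stop("`d_mm` and `h_mm` must be non-negative", call. = FALSE)
  }
  pi * ((d_mm / 2)^2 + h_mm^2) / 100
}

#' Elliptical base area
#'
#' Models the craniectomy base as an ellipse with anteroposterior diameter
#' `d` and superoinferior diameter `D`: `A = (pi/4) d D`.
#'
#' @param d_mm,D_mm Ellipse axis lengths in mm (>= 0).
#' @return Area in cm^2.
#' @export
ellipse_base_area <- function(d_mm, D_mm) {
  if (any(d_mm < 0) || any(D_mm < 0)) {
    stop("`d_mm` and `D_mm` must be non-negative", call. = FALSE)
  }
  (pi / 4) * d_mm * D_mm / 100
}

#' Spherical dome patch
#'
#' The idealized skull-defect model: the skull is a sphere of radius `R` and
#' the craniectomy is the patch bounded by an azimuthal half-angle `theta`
#' (full azimuthal width `2 * theta`) and polar angles
#' `[polar_lo, polar_hi]` measured from the +z pole.
#'
#' @param R_mm Sphere (outer-table) radius in mm.
#' @param theta_rad Azimuthal half-angle in `(0, pi]`.
#' @param polar_lo_rad,polar_hi_rad Polar bounds with
#'   `0 <= polar_lo < polar_hi <= pi`.
#' @return An object of class `dome_patch`.
#' @examples
#' p <- dome_patch(50, pi, 0, pi / 2) # hemisphere on a 50 mm sphere
#' dome_patch_outer_area(p)           # 2 * pi * 5^2 = 157.08 cm^2
#' @export
dome_patch <- function(R_mm, theta_rad, polar_lo_rad, polar_hi_rad) {
  if (!is.finite(R_mm) || R_mm <= 0) stop("`R_mm` must be positive", call. = FALSE)
  if (!is.finite(theta_rad) || theta_rad <= 0 || theta_rad > pi) {
    stop("`theta_rad` must lie in (0, pi]", call. = FALSE)
  }
  if (polar_lo_rad < 0 || polar_hi_rad > pi || polar_lo_rad >= polar_hi_rad) {
    stop("polar bounds must satisfy 0 <= lo < hi <= pi", call. = FALSE)
  }
  structure(
    list(R_mm = R_mm, theta_rad = theta_rad,
         polar_lo_rad = polar_lo_rad, polar_hi_rad = polar_hi_rad),
    class = "dome_patch"
  )
}

#' @export
print.dome_patch <- function(x, ...) {
  cat(sprintf(
    "<dome_patch> R = %.1f mm, azimuth +/- %.3f rad, polar %.3f..%.3f rad (%.2f cm^2)\n",
    x$R_mm, x$theta_rad, x$polar_lo_rad, x$polar_hi_rad,
    dome_patch_outer_area(x)
  ))
  invisible(x)
}

#' Exact outer-surface area of a dome patch
#'
#' Surface integral of the spherical area element over the patch window:
#' `R^2 * (2 theta) * (cos(polar_lo) - cos(polar_hi))`.  This is the
#' ground-truth oracle against which the voxel-based estimators are tested.
#'
#' @param patch A [dome_patch()].
#' @return Area in cm^2.
#' @export
dome_patch_outer_area <- function(patch) {
  stopifnot(inherits(patch, "dome_patch"))
  patch$R_mm^2 * 2 * patch$theta_rad *
    (cos(patch$polar_lo_rad) - cos(patch$polar_hi_rad)) / 100
}

#' Characteristic chord lengths of a dome patch
#'
#' The linear measurements the AC method reads off axial slices, derived
#' analytically from the patch:
#' * `A_mm` -- the in-plane chord subtended by the azimuthal width `2 theta`
#'   at the patch's widest polar ring (the greatest axial defect length).
#'   For `theta > pi/2` the in-plane extremal distance saturates at the ring
#'   diameter, so `theta` is capped at `pi/2`.
#' * `C_mm` -- the axial height extent `R (cos(polar_lo) - cos(polar_hi))`.
#' * `C_prime_mm` -- the great-circle chord of the polar extent,
#'   `2 R sin((polar_hi - polar_lo) / 2)`, the "actual base diameter" along
#'   the superoinferior direction.
#'
#' @param patch A [dome_patch()].
#' @return Named list with `A_mm`, `C_mm`, `C_prime_mm`.
#' @export
chord_lengths <- function(patch) {
  stopifnot(inherits(patch, "dome_patch"))
  lo <- patch$polar_lo_rad
  hi <- patch$polar_hi_rad
  sin_widest <- if (lo <= pi / 2 && hi >= pi / 2) 1 else max(sin(lo), sin(hi))
  list(
    A_mm = 2 * patch$R_mm * sin_widest * sin(min(patch$theta_rad, pi / 2)),
    C_mm = patch$R_mm * (cos(lo) - cos(hi)),
    C_prime_mm = 2 * patch$R_mm * sin((hi - lo) / 2)
  )
}
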