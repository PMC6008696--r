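#' Spherical-shell skull phantom specification
#'
#' The phantom skull is a hollow spherical shell digitized on a regular grid.
#' Defaults give a 75 mm outer-table radius (adult cranial vault scale) and a
#' 5 mm calvarial thickness at 1 mm isotropic spacing.  If `grid_shape` or
#' `center_mm` are omitted they are chosen so the shell sits centred with a
#' comfortable margin.
#'
#' @param outer_radius_mm Outer-table radius (mm).
#' @param thickness_mm Shell thickness (mm); must be smaller than the radius
#'   and at least `2 * max(spacing_mm)` so the digitized shell is watertight.
#' @param spacing_mm Voxel spacing (mm), length 3; the third axis is the
#'   axial (slice) direction.
#' @param grid_shape Integer length-3 grid dimensions, or `NULL` to fit.
#' @param center_mm Sphere centre (mm), or `NULL` for the grid centre.
#' @param base_features Add two solid basal prominences (near the inferior
#'   pole, polar angle > 2.6 rad) emulating the structured skull base.  Real
#'   skulls register rigidly because cranial anatomy breaks rotational
#'   symmetry; a perfectly spherical shell does not (any rotation maps it to
#'   itself), which would make rigid registration of the phantom an
#'   ill-posed problem unlike the clinical one.  The prominences sit outside
#'   the polar range where craniectomy patches are sampled.
#' @return A `shell_spec` object.
#' @examples
#' spec <- shell_spec(outer_radius_mm = 50, thickness_mm = 5)
#' shell <- make_skull_shell(spec)
#' @export
shell_spec <- function(outer_radius_mm = 75, thickness_mm = 5,
                       spacing_mm = c(1, 1, 1), grid_shape = NULL,
                       center_mm = NULL, base_features = TRUE) {
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(spacing_mm) == 3, all(spacing_mm > 0))
  if (!is.finite(outer_radius_mm) || outer_radius_mm <= 0) {
    stop("`outer_radius_mm` must be positive", call. = FALSE)
  }
  if (thickness_mm <= 0 || thickness_mm > outer_radius_mm) {
    stop("`thickness_mm` must be in (0, outer_radius_mm]", call. = FALSE)
  }
  if (thickness_mm < 2 * max(spacing_mm)) {
    stop("`thickness_mm` must be >= 2 * max(spacing_mm) for a watertight shell",
         call. = FALSE)
  }
  if (is.null(grid_shape)) {
    # fit the shell with >= 3 voxels of margin per face at any anisotropy
    grid_shape <- ceiling(2 * outer_radius_mm / spacing_mm) + 7L
  }
  grid_shape <- as.integer(grid_shape)
  if (is.null(center_mm)) {
    center_mm <- (grid_shape - 1) / 2 * spacing_mm
  }
  # require >= 2 voxel margin between shell and grid faces
  lo_margin <- center_mm - outer_radius_mm
  hi_margin <- (grid_shape - 1) * spacing_mm - (center_mm + outer_radius_mm)
  if (any(lo_margin < 2 * spacing_mm) || any(hi_margin < 2 * spacing_mm)) {
    stop("shell exceeds grid bounds: need a >= 2-voxel margin on every face; ",
         "enlarge `grid_shape` or shrink `outer_radius_mm`", call. = FALSE)
  }
  structure(
    list(outer_radius_mm = outer_radius_mm, thickness_mm = thickness_mm,
         spacing_mm = spacing_mm, grid_shape = grid_shape,
         center_mm = center_mm, base_features = isTRUE(base_features)),
    class = "shell_spec"
  )
}

# basal prominences: position (polar, azimuth) on the mid-shell surface and
# radius, scaled to the shell size
base_feature_params <- function(spec) {
  r_mid <- spec$outer_radius_mm - spec$thickness_mm / 2
  list(
    list(polar = 2.80, azimuth = 0.6, radius = 0.20 * spec$outer_radius_mm),
    list(polar = 2.88, azimuth = 2.8, radius = 0.16 * spec$outer_radius_mm),
    r_mid = r_mid
  )
}

add_base_features <- function(grid, spec) {
  bf <- base_feature_params(spec)
  d <- dim(grid)
  for (b in bf[1:2]) {
    ctr <- spec$center_mm + bf$r_mid *
      c(sin(b$polar) * cos(b$azimuth), sin(b$polar) * sin(b$azimuth),
        cos(b$polar))
    lo <- pmax(1L, floor((ctr - b$radius) / spec$spacing_mm) + 1L - 1L)
    hi <- pmin(d, ceiling((ctr + b$radius) / spec$spacing_mm) + 1L + 1L)
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    dx2 <- ((ii - 1) * spec$spacing_mm[1] - ctr[1])^2
    dy2 <- ((jj - 1) * spec$spacing_mm[2] - ctr[2])^2
    dz2 <- ((kk - 1) * spec$spacing_mm[3] - ctr[3])^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= b$radius^2
    grid[ii, jj, kk] <- grid[ii, jj, kk] | inside
  }
  grid
}

#' Angular patch specification on the phantom shell
#'
#' The craniectomy defect is the full-thickness portion of the shell whose
#' angular coordinates (about the shell centre) fall inside an azimuthal
#' window of half-width `azimuth_halfwidth_rad` around `azimuth_center_rad`
#' and a polar band `[polar_min_rad, polar_max_rad]` (polar angle from +z).
#'
#' @param azimuth_center_rad Azimuth of the patch centre.
#' @param azimuth_halfwidth_rad Azimuthal half-angle, in `(0, pi)`.
#' @param polar_min_rad,polar_max_rad Polar bounds,
#'   `0 <= polar_min < polar_max <= pi`.
#' @return A `patch_spec` object.
#' @export
patch_spec <- function(azimuth_center_rad, azimuth_halfwidth_rad,
                       polar_min_rad, polar_max_rad) {
  if (!is.finite(azimuth_halfwidth_rad) || azimuth_halfwidth_rad <= 0 ||
      azimuth_halfwidth_rad >= pi) {
    stop("`azimuth_halfwidth_rad` must lie in (0, pi)", call. = FALSE)
  }
  if (polar_min_rad < 0 || polar_max_rad > pi || polar_min_rad >= polar_max_rad) {
    stop("polar bounds must satisfy 0 <= min < max <= pi", call. = FALSE)
  }
  structure(
    list(azimuth_center_rad = azimuth_center_rad,
         azimuth_halfwidth_rad = azimuth_halfwidth_rad,
         polar_min_rad = polar_min_rad, polar_max_rad = polar_max_rad),
    class = "patch_spec"
  )
}

#' @rdname patch_spec
#' @param patch A `patch_spec`.
#' @param R_mm Sphere radius at which to evaluate the patch.
#' @return `as_dome_patch()` returns the equivalent [dome_patch()].
#' @export
as_dome_patch <- function(patch, R_mm) {
  stopifnot(inherits(patch, "patch_spec"))
  dome_patch(R_mm, patch$azimuth_halfwidth_rad,
             patch$polar_min_rad, patch$polar_max_rad)
}

#' Digitize the phantom skull shell
#'
#' A voxel belongs to the shell iff its centre satisfies
#' `r_inner <= |x - center| <= r_outer` (centre-point sampling), which makes
#' voxel counts directly comparable to analytic shell volumes.
#'
#' @param spec A [shell_spec()].
#' @return A [voxel_mask()].
#' @export
make_skull_shell <- function(spec) {
  stopifnot(inherits(spec, "shell_spec"))
  lab <- cpp_shell_patch(spec$grid_shape, spec$spacing_mm, c(0, 0, 0),
                         spec$center_mm,
                         spec$outer_radius_mm - spec$thickness_mm,
                         spec$outer_radius_mm,
                         FALSE, 0, 0, 0, 0)
  dim(lab) <- spec$grid_shape
  g <- lab > 0L
  if (spec$base_features) g <- add_base_features(g, spec)
  voxel_mask(g, spec$spacing_mm, c(0, 0, 0))
}

#' Remove an angular patch from the shell
#'
#' Splits the digitized shell into the post-craniectomy skull and the removed
#' flap, and returns the exact outer-table area of the removed patch from the
#' analytic dome model (the ground truth for all estimator tests).
#'
#' @param shell The digitized shell from [make_skull_shell()].
#' @param shell_spec The [shell_spec()] that generated `shell`.
#' @param patch A [patch_spec()].
#' @return List with `post_mask`, `true_flap` (both [voxel_mask()] on the
#'   shell grid) and `true_outer_area_cm2`.
#' @export
remove_patch <- function(shell, shell_spec, patch) {
  assert_mask(shell)
  stopifnot(inherits(shell_spec, "shell_spec"), inherits(patch, "patch_spec"))
  lab <- cpp_shell_patch(shell_spec$grid_shape, shell_spec$spacing_mm,
                         c(0, 0, 0), shell_spec$center_mm,
                         shell_spec$outer_radius_mm - shell_spec$thickness_mm,
                         shell_spec$outer_radius_mm,
                         TRUE, patch$azimuth_center_rad,
                         patch$azimuth_halfwidth_rad,
                         patch$polar_min_rad, patch$polar_max_rad)
  dim(lab) <- shell_spec$grid_shape
  flap <- (lab == 2L) & shell$grid
  if (!any(flap)) stop("patch does not intersect the shell: empty flap", call. = FALSE)
  list(
    post_mask = voxel_mask(shell$grid & !flap, shell_spec$spacing_mm, c(0, 0, 0)),
    true_flap = voxel_mask(flap, shell_spec$spacing_mm, c(0, 0, 0)),
    true_outer_area_cm2 = dome_patch_outer_area(
      as_dome_patch(patch, shell_spec$outer_radius_mm))
  )
}

#' Apply a small rigid misalignment to a mask
#'
#' Resamples the mask under the forward rigid map (rotation about the mask
#' centroid followed by translation) with nearest-neighbour interpolation,
#' emulating patient repositioning between scans.
#'
#' @param mask A [voxel_mask()].
#' @param rotation_deg Euler angles (degrees) about the x, y, z axes, applied
#'   as `Rz %*% Ry %*% Rx`.
#' @param translation_mm Translation vector (mm).
#' @param center_mm Rotation centre; defaults to the mask centroid.
#' @return The resampled [voxel_mask()].  Errors if content is pushed out of
#'   the grid (foreground count not conserved within 5%).
#' @export
perturb_rigid <- function(mask, rotation_deg, translation_mm,
                          center_mm = NULL) {
  assert_mask(mask)
  t <- rigid_transform(rotation_deg, translation_mm,
                       center_mm %||% mask_centroid(mask))
  out <- apply_transform(mask, t)
  n0 <- mask_count(mask)
  if (abs(mask_count(out) - n0) > 0.05 * n0) {
    stop("rigid perturbation pushed mask content outside the grid",
         call. = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run `expr` under a private RNG stream, leaving the caller's stream intact
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Add salt-streak artifacts near the mask boundary
#'
#' Flips a severity-proportional fraction of boundary-adjacent voxels (both
#' surface voxels and background voxels touching the surface), a lightweight
#' stand-in for metal-streak degradation used to probe estimator robustness.
#' At most 10% of the mask volume is ever flipped.  Deterministic for a fixed
#' `seed`.
#'
#' @param mask A [voxel_mask()].
#' @param severity Scalar in `[0, 1]`; 0 returns the mask unchanged.
#' @param seed Integer seed for the flip pattern.
#' @param rate Fraction of boundary candidates flipped at `severity = 1`.
#' @return A [voxel_mask()].
#' @export
add_artifacts <- function(mask, severity, seed = 1L, rate = 0.25) {
  assert_mask(mask)
  if (!is.finite(severity) || severity < 0 || severity > 1) {
    stop("`severity` must lie in [0, 1]", call. = FALSE)
  }
  if (severity == 0) return(mask)
  g <- mask$grid
  surf <- g & !erode6(g)
  rim_out <- dilate6(g) & !g
  cand <- which(surf | rim_out)
  n_flip <- min(round(severity * rate * length(cand)),
                floor(0.1 * sum(g)))
  if (n_flip == 0) return(mask)
  flips <- with_local_seed(seed, sample(cand, n_flip))
  g[flips] <- !g[flips]
  voxel_mask(g, mask$spacing, mask$origin)
}

shift_arr <- function(g, axis, by) {
  d <- dim(g)
  out <- array(FALSE, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (by > 0) {
    idx_dst[[axis]] <- (1 + by):n
    idx_src[[axis]] <- 1:(n - by)
  } else if (by < 0) {
    idx_dst[[axis]] <- 1:(n + by)
    idx_src[[axis]] <- (1 - by):n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    g[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

erode6 <- function(g) {
  out <- g
  for (axis in 1:3) for (by in c(-1, 1)) out <- out & shift_arr(g, axis, by)
  out
}

dilate6 <- function(g) {
  out <- g
  for (axis in 1:3) for (by in c(-1, 1)) out <- out | shift_arr(g, axis, by)
  out
}

#' Cohort specification for phantom studies
#'
#' Describes a simulated craniectomy cohort: number of cases, the range of
#' true outer-surface areas (sampled uniformly, emulating the spread of a
#' clinical case series), voxel spacing, optional rigid misalignment between
#' the simulated pre- and post-operative scans, and optional artifact noise.
#'
#' @param n_cases Number of cases (>= 1).
#' @param area_range_cm2 Length-2 positive range of true flap outer areas.
#' @param seed Integer seed controlling all randomness in the cohort.
#' @param spacing_mm Voxel spacing; use `c(1, 1, 5)` for CT-like axial slices.
#' @param outer_radius_mm,thickness_mm Shell geometry; `thickness_mm = NULL`
#'   picks `max(5, 2 * max(spacing_mm))`.
#' @param misalignment `NULL` for perfectly aligned pairs, or a list with
#'   `max_rotation_deg` and `max_translation_mm` giving per-axis uniform
#'   perturbation magnitudes applied to the post-operative mask.
#' @param artifact_severity Scalar in `[0, 1]` passed to [add_artifacts()].
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_cases = 118, area_range_cm2 = c(9.46, 205.32),
                        seed = 1L, spacing_mm = c(1, 1, 1),
                        outer_radius_mm = 75, thickness_mm = NULL,
                        misalignment = NULL, artifact_severity = 0) {
  stopifnot(n_cases >= 1, length(area_range_cm2) == 2,
            all(area_range_cm2 > 0), area_range_cm2[1] < area_range_cm2[2])
  thickness_mm <- thickness_mm %||% max(5, 2 * max(spacing_mm))
  shell <- shell_spec(outer_radius_mm, thickness_mm, spacing_mm)
  max_area <- feasible_area_max_cm2(outer_radius_mm)
  if (area_range_cm2[2] > max_area) {
    stop(sprintf(
      "area range infeasible for a %.0f mm shell: feasible range is (0, %.1f] cm^2",
      outer_radius_mm, max_area), call. = FALSE)
  }
  structure(
    list(n_cases = as.integer(n_cases), area_range_cm2 = area_range_cm2,
         seed = as.integer(seed), shell_spec = shell,
         misalignment = misalignment,
         artifact_severity = artifact_severity),
    class = "cohort_spec"
  )
}

# patch shape constraints used by the cohort sampler
PATCH_MAX_POLAR_EXTENT <- 2.2
PATCH_MAX_THETA <- 2.4
PATCH_POLAR_MARGIN <- 0.08

feasible_area_max_cm2 <- function(R_mm) {
  2 * PATCH_MAX_THETA * R_mm^2 * 2 * sin(PATCH_MAX_POLAR_EXTENT / 2) / 100
}

# Solve for a patch_spec with exactly the requested outer area.  The polar
# extent is set from the target area and an aspect ratio (azimuthal width /
# polar arc length), then the azimuthal half-angle is solved exactly.
patch_for_area <- function(target_cm2, R_mm, aspect = 1,
                           polar_center = pi / 2, azimuth_center = 0) {
  target_mm2 <- target_cm2 * 100
  plen <- sqrt(target_mm2 / aspect)
  extent <- min(plen / R_mm, PATCH_MAX_POLAR_EXTENT)
  lo <- polar_center - extent / 2
  hi <- polar_center + extent / 2
  if (lo < PATCH_POLAR_MARGIN) { hi <- hi + (PATCH_POLAR_MARGIN - lo); lo <- PATCH_POLAR_MARGIN }
  if (hi > pi - PATCH_POLAR_MARGIN) { lo <- lo - (hi - (pi - PATCH_POLAR_MARGIN)); hi <- pi - PATCH_POLAR_MARGIN }
  theta <- target_mm2 / (2 * R_mm^2 * (cos(lo) - cos(hi)))
  if (!is.finite(theta) || theta <= 0 || theta > PATCH_MAX_THETA) {
    stop(sprintf("no feasible patch for %.1f cm^2 on a %.0f mm shell",
                 target_cm2, R_mm), call. = FALSE)
  }
  patch_spec(azimuth_center, theta, lo, hi)
}

#' Simulate a phantom craniectomy cohort
#'
#' Generates `n_cases` matched pre/post skull phantoms with ground-truth
#' flaps.  True outer areas are drawn uniformly over `area_range_cm2` and the
#' patch angles are solved so each case's analytic outer area equals its
#' draw exactly.  All cases share one digitized shell (the "pre" skull); the
#' per-case flap is stored cropped to its bounding box.  Use [case_masks()]
#' to materialize the full pre/post/flap volumes of a case, including any
#' misalignment and artifact noise.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of class `flap_cohort` with one row per case: `case_id`,
#'   `true_area_cm2`, the sampled `patch` (list of [patch_spec()]),
#'   `rotation_deg` / `translation_mm` (lists, the applied misalignment),
#'   `artifact_severity`, and `flap_truth` (list of cropped [voxel_mask()]).
#'   The shared shell and specs are carried in attributes `shell`,
#'   `shell_spec` and `cohort_spec`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_spec(n_cases = 3, seed = 7))
#' cohort$true_area_cm2
#' }
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  sh_spec <- spec$shell_spec
  n <- spec$n_cases
  draws <- with_local_seed(spec$seed, {
    list(
      area = runif(n, spec$area_range_cm2[1], spec$area_range_cm2[2]),
      aspect = runif(n, 0.75, 1.3),
      polar_center = runif(n, 0.95, 1.45),
      azimuth_center = runif(n, -pi, pi),
      rot = matrix(
        if (is.null(spec$misalignment)) rep(0, 3 * n) else
          runif(3 * n, -spec$misalignment$max_rotation_deg,
                spec$misalignment$max_rotation_deg), ncol = 3),
      trans = matrix(
        if (is.null(spec$misalignment)) rep(0, 3 * n) else
          runif(3 * n, -spec$misalignment$max_translation_mm,
                spec$misalignment$max_translation_mm), ncol = 3),
      art_seed = sample.int(.Machine$integer.max - 1L, n)
    )
  })
  shell <- make_skull_shell(sh_spec)

  # classify shell voxels by angle once; every case is an angular window
  idx <- which(shell$grid, arr.ind = TRUE)
  xyz <- sweep(sweep(idx - 1, 2, sh_spec$spacing_mm, `*`), 2,
               sh_spec$center_mm, `-`)
  r <- sqrt(rowSums(xyz^2))
  polar <- acos(pmin(1, pmax(-1, xyz[, 3] / r)))
  az <- atan2(xyz[, 2], xyz[, 1])
  lin <- which(shell$grid)

  cases <- vector("list", n)
  for (i in seq_len(n)) {
    patch <- patch_for_area(draws$area[i], sh_spec$outer_radius_mm,
                            draws$aspect[i], draws$polar_center[i],
                            draws$azimuth_center[i])
    daz <- (az - patch$azimuth_center_rad + pi) %% (2 * pi) - pi
    sel <- polar >= patch$polar_min_rad & polar <= patch$polar_max_rad &
      abs(daz) <= patch$azimuth_halfwidth_rad
    if (!any(sel)) stop("sampled patch missed the digitized shell", call. = FALSE)
    sub <- idx[sel, , drop = FALSE]
    lo <- pmax(apply(sub, 2, min) - 2L, 1L)
    hi <- pmin(apply(sub, 2, max) + 2L, sh_spec$grid_shape)
    g <- array(FALSE, hi - lo + 1L)
    g[cbind(sub[, 1] - lo[1] + 1L, sub[, 2] - lo[2] + 1L,
            sub[, 3] - lo[3] + 1L)] <- TRUE
    cases[[i]] <- list(
      flap = voxel_mask(g, sh_spec$spacing_mm, (lo - 1) * sh_spec$spacing_mm),
      patch = patch,
      flap_lin = lin[sel]
    )
  }

  out <- tibble::tibble(
    case_id = seq_len(n),
    true_area_cm2 = draws$area,
    patch = lapply(cases, `[[`, "patch"),
    rotation_deg = lapply(seq_len(n), function(i) draws$rot[i, ]),
    translation_mm = lapply(seq_len(n), function(i) draws$trans[i, ]),
    artifact_severity = rep(spec$artifact_severity, n),
    artifact_seed = draws$art_seed,
    flap_truth = lapply(cases, `[[`, "flap")
  )
  attr(out, "flap_lin") <- lapply(cases, `[[`, "flap_lin")
  attr(out, "shell") <- shell
  attr(out, "shell_spec") <- sh_spec
  attr(out, "cohort_spec") <- spec
  class(out) <- c("flap_cohort", class(out))
  out
}

#' Materialize the full volumes of one cohort case
#'
#' Rebuilds the full-grid pre-operative skull, the (optionally misaligned and
#' artifact-degraded) post-operative skull, and the ground-truth flap for one
#' case of a simulated cohort.
#'
#' @param cohort A `flap_cohort` from [simulate_cohort()].
#' @param case_id Case number.
#' @return List with `pre_mask`, `post_mask`, `true_flap` (full-grid
#'   [voxel_mask()]s), `true_outer_area_cm2` and `applied_transform` (a
#'   [rigid_transform()] or `NULL`).
#' @export
case_masks <- function(cohort, case_id) {
  stopifnot(inherits(cohort, "flap_cohort"))
  row <- match(case_id, cohort$case_id)
  if (is.na(row)) stop("unknown `case_id`", call. = FALSE)
  shell <- attr(cohort, "shell")
  g <- shell$grid
  g[attr(cohort, "flap_lin")[[row]]] <- FALSE
  post <- voxel_mask(g, shell$spacing, shell$origin)
  flap_full <- shell$grid & !g
  applied <- NULL
  rot <- cohort$rotation_deg[[row]]
  trans <- cohort$translation_mm[[row]]
  if (any(rot != 0) || any(trans != 0)) {
    applied <- rigid_transform(rot, trans, mask_centroid(post))
    post <- apply_transform(post, applied)
  }
  if (cohort$artifact_severity[row] > 0) {
    post <- add_artifacts(post, cohort$artifact_severity[row],
                          seed = cohort$artifact_seed[row])
  }
  list(
    pre_mask = shell,
    post_mask = post,
    true_flap = voxel_mask(flap_full, shell$spacing, shell$origin),
    true_outer_area_cm2 = cohort$true_area_cm2[row],
    applied_transform = applied
  )
}

#' Convert a mask to a pseudo-CT intensity volume
#'
#' Assigns a bone-like intensity to foreground voxels and 0 elsewhere, so the
#' segmentation stage can be exercised on phantoms.
#'
#' @param mask A [voxel_mask()].
#' @param bone_intensity Intensity of foreground voxels (HU-like scale).
#' @return A 3-D numeric array with attributes `spacing` and `origin`.
#' @export
as_pseudo_ct <- function(mask, bone_intensity = 1000) {
  assert_mask(mask)
  vol <- array(0, dim(mask$grid))
  vol[mask$grid] <- bone_intensity
  attr(vol, "spacing") <- mask$spacing
  attr(vol, "origin") <- mask$origin
  vol
}

#' Write one phantom case to disk
#'
#' Writes `pre.nii.gz`, `post.nii.gz`, `flap_truth.nii.gz` and a `case.json`
#' with the ground truth into `dir`.
#'
#' @inheritParams case_masks
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_case <- function(cohort, case_id, dir) {
  cm <- case_masks(cohort, case_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mask(cm$pre_mask, file.path(dir, "pre.nii.gz"))
  write_mask(cm$post_mask, file.path(dir, "post.nii.gz"))
  write_mask(cm$true_flap, file.path(dir, "flap_truth.nii.gz"))
  row <- match(case_id, cohort$case_id)
  truth <- list(
    case_id = case_id,
    true_outer_area_cm2 = cm$true_outer_area_cm2,
    patch = unclass(cohort$patch[[row]]),
    rotation_deg = cohort$rotation_deg[[row]],
    translation_mm = cohort$translation_mm[[row]],
    artifact_severity = cohort$artifact_severity[row]
  )
  jsonlite::write_json(truth, file.path(dir, "case.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
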