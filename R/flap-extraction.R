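#' Rigid transform
#'
#' A rigid map `y = R (x - center) + center + translation`, with `R` built
#' from Euler angles applied as `Rz %*% Ry %*% Rx` (degrees).
#'
#' @param rotation_deg Euler angles (degrees) about x, y, z.
#' @param translation_mm Translation (mm).
#' @param center_mm Rotation centre (mm).
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  rotation_deg <- as.numeric(rotation_deg)
  translation_mm <- as.numeric(translation_mm)
  center_mm <- as.numeric(center_mm)
  stopifnot(length(rotation_deg) == 3, length(translation_mm) == 3,
            length(center_mm) == 3,
            all(is.finite(c(rotation_deg, translation_mm, center_mm))))
  structure(
    list(rotation_deg = rotation_deg, translation_mm = translation_mm,
         center_mm = center_mm),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> rot (%.2f, %.2f, %.2f) deg, trans (%.2f, %.2f, %.2f) mm\n",
    x$rotation_deg[1], x$rotation_deg[2], x$rotation_deg[3],
    x$translation_mm[1], x$translation_mm[2], x$translation_mm[3]
  ))
  invisible(x)
}

rotation_matrix <- function(rotation_deg) {
  a <- rotation_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Invert a rigid transform
#' @param t A [rigid_transform()].
#' @return The inverse transform about the same centre.  Because Euler
#'   angles do not negate componentwise, the inverse is returned with the
#'   rotation matrix attached as attribute `matrix`.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  R <- t(rotation_matrix(t$rotation_deg))
  out <- rigid_transform(-t$rotation_deg, as.numeric(-R %*% t$translation_mm),
                         t$center_mm)
  attr(out, "matrix") <- R
  out
}

transform_matrix <- function(t) {
  attr(t, "matrix") %||% rotation_matrix(t$rotation_deg)
}

#' Apply a rigid transform to a mask
#'
#' Resamples the mask onto its own grid under the forward rigid map.
#' `"nearest"` interpolation takes the nearest input voxel (pure label
#' resampling); `"linear"` interpolates the binary occupancy trilinearly and
#' thresholds at 0.5, which places the resampled surface with sub-voxel
#' accuracy and roughly halves staircase noise -- the registration pipeline
#' uses it when undoing a misalignment.  The identity transform reproduces
#' the mask exactly under either scheme.
#'
#' @param mask A [voxel_mask()].
#' @param t A [rigid_transform()].
#' @param interpolation `"nearest"` or `"linear"`.
#' @return The resampled [voxel_mask()].
#' @export
apply_transform <- function(mask, t,
                            interpolation = c("nearest", "linear")) {
  assert_mask(mask)
  stopifnot(inherits(t, "rigid_transform"))
  interpolation <- match.arg(interpolation)
  fn <- if (interpolation == "nearest") cpp_resample_rigid else
    cpp_resample_rigid_linear
  g <- fn(mask$grid, dim(mask$grid), mask$spacing, mask$origin,
          transform_matrix(t), t$translation_mm, t$center_mm)
  dim(g) <- dim(mask$grid)
  voxel_mask(g, mask$spacing, mask$origin)
}

#' Threshold bone out of a CT-like volume
#'
#' Bone segmentation by global thresholding: a voxel is bone iff its
#' intensity is at least `threshold`.  On phantom pseudo-CT volumes
#' (bone = 1000, background = 0) the default threshold of 300 recovers the
#' generating mask exactly.
#'
#' @param volume 3-D numeric array; attributes `spacing` / `origin` are used
#'   when present (as produced by [as_pseudo_ct()]).
#' @param threshold Intensity threshold (HU-like units).
#' @param spacing_mm,origin_mm Geometry overrides when `volume` carries none.
#' @return A [voxel_mask()].  An all-background result triggers a warning and
#'   returns an empty mask.
#' @export
segment_bone <- function(volume, threshold = 300,
                         spacing_mm = NULL, origin_mm = NULL) {
  if (length(dim(volume)) != 3L) stop("`volume` must be a 3-D array", call. = FALSE)
  if (any(!is.finite(volume))) stop("`volume` must be finite-valued", call. = FALSE)
  spacing_mm <- spacing_mm %||% attr(volume, "spacing") %||% c(1, 1, 1)
  origin_mm <- origin_mm %||% attr(volume, "origin") %||% c(0, 0, 0)
  g <- volume >= threshold
  if (!any(g)) warning("bone segmentation is empty", call. = FALSE)
  voxel_mask(array(g, dim(volume)), spacing_mm, origin_mm)
}

#' Register one bone mask rigidly onto another
#'
#' Mask-based rigid registration by overlap maximization: the objective is
#' the mean trilinearly-interpolated fixed-mask value at the transformed
#' moving-voxel centres, optimized coarse-to-fine against progressively less
#' smoothed versions of the fixed mask (Gaussian sigma 3 mm, 1 mm, then the
#' crisp mask).  Initialization aligns centroids.  Designed to recover small
#' rigid misalignments (<= 10 degrees, <= 10 mm) between scans of the same
#' skull.
#'
#' @param fixed,moving Non-empty [voxel_mask()]s on the same grid geometry.
#' @param max_points Moving-voxel subsample size used during optimization.
#' @return A [rigid_transform()] mapping `moving` onto `fixed`, with
#'   attributes `dice` (final overlap after resampling) and `low_confidence`
#'   (`TRUE` when that Dice is below 0.5).
#' @export
register_rigid <- function(fixed, moving, max_points = 20000L) {
  assert_mask(fixed)
  assert_mask(moving)
  if (mask_count(fixed) == 0L || mask_count(moving) == 0L) {
    stop("cannot register empty masks", call. = FALSE)
  }
  pts_full <- mask_coordinates(moving)
  pts <- pts_full
  if (nrow(pts) > max_points) {
    pts <- pts[seq(1L, nrow(pts), length.out = max_points), , drop = FALSE]
  }
  center <- mask_centroid(fixed)
  t0 <- center - mask_centroid(moving)
  dims <- dim(fixed$grid)
  fgrid <- array(as.numeric(fixed$grid), dims)

  score_field <- function(field) {
    function(par) {
      -cpp_overlap_score(field, dims, fixed$spacing, fixed$origin, pts,
                         rotation_matrix(par[1:3]), par[4:6], center)
    }
  }
  smooth_field <- function(sigma_mm) {
    f <- cpp_gaussian_smooth(fgrid, dims, sigma_mm / fixed$spacing)
    dim(f) <- dims
    f
  }
  field1 <- smooth_field(1)
  f3 <- score_field(smooth_field(3))
  f1 <- score_field(field1)

  # stage 1: translation only (rotation fixed at 0), coarse to fine
  tpar <- optim(t0, function(p) f3(c(0, 0, 0, p)), method = "Nelder-Mead",
                control = list(maxit = 300))$par
  tpar <- optim(tpar, function(p) f1(c(0, 0, 0, p)), method = "Nelder-Mead",
                control = list(maxit = 300))$par

  # stage 2: dense rotation grid on the lightly smoothed field.  The skull
  # vault is close to a spherical shell, so the rotation landscape is a
  # shallow valley whose true optimum is marked mainly by the asymmetric
  # structures (skull base); the smoothed field carries that signal without
  # voxel-lattice noise.  Scored on a voxel subsample for speed.
  sub <- pts[seq(1L, nrow(pts), length.out = min(6000L, nrow(pts))), ,
             drop = FALSE]
  f1_sub <- function(par) {
    -cpp_overlap_score(field1, dims, fixed$spacing, fixed$origin, sub,
                       rotation_matrix(par[1:3]), par[4:6], center)
  }
  grid1 <- seq(-10.5, 10.5, by = 1.5)
  rots <- as.matrix(expand.grid(grid1, grid1, grid1))
  scores <- apply(rots, 1, function(r) f1_sub(c(r, tpar)))
  cand <- rbind(rots[order(scores)[1:6], , drop = FALSE], c(0, 0, 0))

  # stage 3: full 6-parameter refinement from each candidate basin, still on
  # the smoothed field (the crisp polish follows)
  refined <- lapply(seq_len(nrow(cand)), function(q) {
    optim(c(cand[q, ], tpar), f1, method = "Nelder-Mead",
          control = list(maxit = 400, reltol = 1e-8,
                         parscale = rep(0.75, 6)))[c("par", "value")]
  })
  refined <- refined[order(vapply(refined, `[[`, numeric(1), "value"))]
  # stage 4: deterministic coordinate hill-climb polish of the two best
  # basins on the crisp objective, scored with every moving voxel for the
  # sharpest localization; keep whichever polishes better
  crisp_full <- function(par) {
    -cpp_overlap_score(fgrid, dims, fixed$spacing, fixed$origin, pts_full,
                       rotation_matrix(par[1:3]), par[4:6], center)
  }
  polish <- function(par) {
    best <- crisp_full(par)
    for (step in c(0.5, 0.2, 0.08)) {
      repeat {
        improved <- FALSE
        for (q in 1:6) {
          for (dir in c(-1, 1)) {
            cand <- par
            cand[q] <- cand[q] + dir * step
            s <- crisp_full(cand)
            if (s < best - 1e-9) {
              par <- cand
              best <- s
              improved <- TRUE
            }
          }
        }
        if (!improved) break
      }
    }
    list(par = par, value = best)
  }
  finalists <- lapply(head(refined, 2), function(r) polish(r$par))
  par <- finalists[[which.min(vapply(finalists, `[[`, numeric(1),
                                     "value"))]]$par
  t <- rigid_transform(par[1:3], par[4:6], center)
  d <- dice(fixed, apply_transform(moving, t))
  attr(t, "dice") <- d
  attr(t, "low_confidence") <- d < 0.5
  if (d < 0.5) {
    warning(sprintf("registration converged with low overlap (Dice %.2f)", d),
            call. = FALSE)
  }
  t
}

#' Subtract registered post-operative bone from pre-operative bone
#'
#' The missing skull flap is `pre & !post` followed by removal of
#' 26-connected components smaller than `min_component_cm3`, which filters
#' out the thin mismatch shell left by registration and resampling noise.
#'
#' @param pre_bone Pre-operative bone [voxel_mask()].
#' @param post_bone_registered Post-operative bone mask already resampled
#'   onto the pre-operative grid.
#' @param min_component_cm3 Minimum surviving component volume.
#' @param opening Apply a one-voxel morphological opening (6-neighbourhood,
#'   intersected with the raw difference) before component filtering; removes
#'   the thin mismatch sheets left on the skull surfaces after registration
#'   and resampling while leaving the full-thickness flap body intact.
#' @return The flap [voxel_mask()].  Errors if nothing survives cleanup.
#' @export
subtract_flap <- function(pre_bone, post_bone_registered,
                          min_component_cm3 = 0.5, opening = FALSE) {
  assert_mask(pre_bone)
  assert_mask(post_bone_registered)
  if (!identical(dim(pre_bone$grid), dim(post_bone_registered$grid))) {
    stop("masks must share a grid", call. = FALSE)
  }
  g <- pre_bone$grid & !post_bone_registered$grid
  if (opening) g <- dilate6(erode6(g)) & g
  flap <- voxel_mask(g, pre_bone$spacing, pre_bone$origin)
  flap <- filter_components(flap, min_component_cm3)
  if (mask_count(flap) == 0L) {
    stop("no craniectomy detected: flap empty after cleanup", call. = FALSE)
  }
  flap
}

filter_components <- function(mask, min_component_cm3) {
  if (mask_count(mask) == 0L || min_component_cm3 <= 0) return(mask)
  lab <- label_components(mask, 26L)
  sizes <- tabulate(lab[lab > 0L], nbins = attr(lab, "n_components"))
  keep <- which(sizes * prod(mask$spacing) / 1000 >= min_component_cm3)
  mask$grid <- array(lab %in% keep, dim(mask$grid))
  mask
}

# Keep only full-thickness defect voxels: bin flap and pre-operative skull
# voxels by direction about the skull centroid and keep the bins where the
# flap's radial span covers at least `frac` of the skull's local radial
# span.  Thin mismatch sheets left by sub-voxel registration error span only
# one or two voxels radially and are dropped; the true (full-thickness) flap
# spans the whole skull thickness and survives intact.
full_thickness_clean <- function(flap_grid, pre_bone, frac = 0.5,
                                 bin_rad = 0.026) {
  ctr <- mask_centroid(pre_bone)
  span_by_bin <- function(grid) {
    idx <- which(grid, arr.ind = TRUE)
    xyz <- sweep(sweep(idx - 1, 2, pre_bone$spacing, `*`), 2,
                 pre_bone$origin, `+`)
    xyz <- sweep(xyz, 2, ctr, `-`)
    r <- sqrt(rowSums(xyz^2))
    polar <- acos(pmin(1, pmax(-1, xyz[, 3] / pmax(r, 1e-9))))
    az <- atan2(xyz[, 2], xyz[, 1])
    bin <- floor(polar / bin_rad) * 1000L + floor((az + pi) / bin_rad)
    list(bin = bin, r = r, idx = idx)
  }
  fb <- span_by_bin(flap_grid)
  pb <- span_by_bin(pre_bone$grid)
  # a genuine defect bin is a solid radial column: it spans (most of) the
  # local skull thickness AND has no internal radial gap; paired thin
  # mismatch sheets on the outer and inner tables span the thickness too but
  # leave a gap in between
  gap_tol <- 2 * max(pre_bone$spacing) + 1e-6
  f_stat <- vapply(split(fb$r, fb$bin), function(v) {
    v <- sort(v)
    c(span = v[length(v)] - v[1],
      gap = if (length(v) > 1) max(diff(v)) else 0)
  }, numeric(2))
  p_span <- vapply(split(pb$r, pb$bin), function(v) max(v) - min(v), numeric(1))
  need <- frac * pmax(p_span[match(colnames(f_stat), names(p_span))],
                      2 * min(pre_bone$spacing), na.rm = TRUE)
  keep_bins <- colnames(f_stat)[f_stat["span", ] >= need &
                                  f_stat["gap", ] <= gap_tol]
  out <- array(FALSE, dim(flap_grid))
  sel <- fb$bin %in% as.numeric(keep_bins)
  out[fb$idx[sel, , drop = FALSE]] <- TRUE
  out
}

#' End-to-end flap extraction
#'
#' Runs the full preprocessing chain on a pre/post bone-mask pair: register
#' the post-operative mask onto the pre-operative one, resample it, and
#' subtract to recover the missing skull flap.
#'
#' @inheritParams subtract_flap
#' @param post_bone Post-operative bone mask (possibly misaligned).
#' @param register Set `FALSE` to skip registration (already-aligned pairs).
#' @param full_thickness Keep only full-thickness defect voxels after
#'   subtraction (radial-span filter against the pre-operative skull);
#'   defaults to on exactly when registration runs, where sub-voxel residual
#'   misalignment otherwise leaves thin mismatch sheets on the skull
#'   surfaces.  A craniectomy defect is full-thickness by definition, so the
#'   filter does not touch the true flap.
#' @return List with `flap` ([voxel_mask()]), `transform` (the recovered
#'   [rigid_transform()] or `NULL`) and `registration_dice`.
#' @export
extract_flap <- function(pre_bone, post_bone, min_component_cm3 = 0.5,
                         register = TRUE, full_thickness = register) {
  t <- NULL
  d <- NA_real_
  post_reg <- post_bone
  if (register) {
    t <- register_rigid(pre_bone, post_bone)
    post_reg <- apply_transform(post_bone, t, interpolation = "linear")
    d <- dice(pre_bone, post_reg)
  }
  g <- pre_bone$grid & !post_reg$grid
  if (full_thickness && any(g)) g <- full_thickness_clean(g, pre_bone)
  flap <- filter_components(voxel_mask(g, pre_bone$spacing, pre_bone$origin),
                            min_component_cm3)
  if (mask_count(flap) == 0L) {
    stop("no craniectomy detected: flap empty after cleanup", call. = FALSE)
  }
  list(flap = flap, transform = t, registration_dice = d)
}
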