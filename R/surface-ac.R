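#' Greatest in-plane defect length of one axial slice
#'
#' Reads the craniectomy length the way a rater would on an axial CT slice:
#' among the slice's flap voxels, only those on the outer table are
#' considered -- operationalized as the radially outermost flap voxel per
#' angular bin about `center_xy` -- and the greatest pairwise in-plane
#' distance between them is returned.
#'
#' @param flap A [voxel_mask()].
#' @param z_index Axial slice index (1-based).
#' @param center_xy In-plane reference centre (mm) for the radial binning;
#'   defaults to the slice's own in-plane centroid.  Pass the skull centroid
#'   when measuring craniectomy defects.
#' @param bin_deg Angular bin width in degrees.
#' @return Length in cm (0 for an empty slice).
#' @export
slice_defect_length <- function(flap, z_index, center_xy = NULL, bin_deg = 2) {
  assert_mask(flap)
  d <- dim(flap$grid)
  if (z_index < 1L || z_index > d[3]) stop("invalid `z_index`", call. = FALSE)
  ij <- which(flap$grid[, , z_index], arr.ind = TRUE)
  if (nrow(ij) == 0L) return(0)
  xy <- sweep(sweep(ij - 1, 2, flap$spacing[1:2], `*`), 2, flap$origin[1:2], `+`)
  if (nrow(ij) == 1L) return(0)
  center_xy <- center_xy %||% colMeans(xy)
  dx <- xy[, 1] - center_xy[1]
  dy <- xy[, 2] - center_xy[2]
  r <- sqrt(dx^2 + dy^2)
  bin <- floor(((atan2(dy, dx) + pi) / (2 * pi)) * (360 / bin_deg))
  outer_idx <- vapply(split(seq_along(r), bin),
                      function(g) g[which.max(r[g])], integer(1))
  pts <- xy[outer_idx, , drop = FALSE]
  if (nrow(pts) < 2L) return(0)
  max(stats::dist(pts)) / 10
}

#' Craniectomy length A
#'
#' The greatest axial defect length: the maximum of [slice_defect_length()]
#' over all axial slices.
#'
#' @inheritParams slice_defect_length
#' @return List with `A_cm` and `slice_index` (argmax slice).
#' @export
craniectomy_A <- function(flap, center_xy = NULL, bin_deg = 2) {
  assert_mask(flap)
  if (mask_count(flap) == 0L) stop("flap mask is empty", call. = FALSE)
  d <- dim(flap$grid)
  flat <- flap$grid
  dim(flat) <- c(d[1] * d[2], d[3])
  zs <- which(colSums(flat) > 0)
  lens <- vapply(zs, function(z)
    slice_defect_length(flap, z, center_xy, bin_deg), numeric(1))
  list(A_cm = max(lens), slice_index = zs[which.max(lens)])
}

#' Craniectomy height C
#'
#' The number of axial slices in which a full-thickness defect is visible,
#' times the slice spacing.  With a pre-operative skull available, a slice
#' counts when at least one angular bin of the skull's slice cross-section is
#' entirely missing (every pre-operative bone voxel of the bin belongs to the
#' flap); this excludes partial-thickness drilling.  Without a pre-operative
#' mask every slice containing flap voxels counts.
#'
#' @inheritParams slice_defect_length
#' @param pre_bone Optional pre-operative skull [voxel_mask()] on the same
#'   grid.
#' @return List with `C_cm` and `n_slices`.
#' @export
craniectomy_C <- function(flap, pre_bone = NULL, bin_deg = 2) {
  assert_mask(flap)
  if (mask_count(flap) == 0L) stop("flap mask is empty", call. = FALSE)
  d <- dim(flap$grid)
  nbin <- round(360 / bin_deg)
  flat <- flap$grid
  dim(flat) <- c(d[1] * d[2], d[3])
  z_flap <- which(colSums(flat) > 0)
  if (is.null(pre_bone)) {
    n_slices <- length(z_flap)
  } else {
    assert_mask(pre_bone)
    if (!identical(dim(pre_bone$grid), d)) {
      stop("`pre_bone` must share the flap grid", call. = FALSE)
    }
    n_slices <- 0L
    for (z in z_flap) {
      fl <- flap$grid[, , z]
      ij <- which(pre_bone$grid[, , z] | fl, arr.ind = TRUE)
      xy <- sweep(sweep(ij - 1, 2, flap$spacing[1:2], `*`), 2,
                  flap$origin[1:2], `+`)
      ctr <- colMeans(xy)
      bin <- floor(((atan2(xy[, 2] - ctr[2], xy[, 1] - ctr[1]) + pi) /
                      (2 * pi)) * nbin)
      in_flap <- fl[ij]
      # a slice shows a full-thickness defect when some angular bin holds
      # flap voxels and no non-flap skull voxels
      if (length(setdiff(unique(bin[in_flap]), unique(bin[!in_flap]))) > 0) {
        n_slices <- n_slices + 1L
      }
    }
  }
  list(C_cm = n_slices * flap$spacing[3] / 10, n_slices = n_slices)
}

#' AC estimate of the craniectomy outer surface area
#'
#' The manual method automated: `S_ac = A x C`, the greatest axial defect
#' length times the craniectomy height.  When `pre_bone` is supplied its
#' centroid anchors the radial binning for `A` and its slice cross-sections
#' define full thickness for `C`.
#'
#' @inheritParams craniectomy_C
#' @param center_xy Optional precomputed in-plane skull centroid (mm),
#'   avoiding a recomputation from `pre_bone`.
#' @return An [area_estimate()] with metadata `A_cm`, `C_cm`,
#'   `slice_index_of_A` and `n_slices`.
#' @examples
#' flap <- voxel_mask(array(TRUE, c(24, 2, 4)), spacing = c(5, 5, 25))
#' ac_area(flap) # A = 11.5 cm in-plane, C = 4 x 2.5 cm
#' @export
ac_area <- function(flap, pre_bone = NULL, bin_deg = 2, center_xy = NULL) {
  if (is.null(center_xy) && !is.null(pre_bone)) {
    center_xy <- mask_centroid(pre_bone)[1:2]
  }
  A <- craniectomy_A(flap, center_xy, bin_deg)
  C <- craniectomy_C(flap, pre_bone, bin_deg)
  area_estimate(
    "ac",
    A$A_cm * C$C_cm,
    list(A_cm = A$A_cm, C_cm = C$C_cm, slice_index_of_A = A$slice_index,
         n_slices = C$n_slices)
  )
}
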