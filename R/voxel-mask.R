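#' Binary voxel masks
#'
#' A `voxel_mask` is the package's universal representation of a skull, a
#' skull flap or any other binary occupancy volume: a 3-D logical array with
#' per-axis voxel spacing (mm) and a physical origin.  Axial slices run along
#' the third array axis.  Voxel `[i, j, k]` (1-based in R) has its centre at
#' `origin + (c(i, j, k) - 1) * spacing` -- the voxel-centre convention used
#' throughout.
#'
#' @param grid 3-D `logical` (or coercible) array of voxel occupancy.
#' @param spacing Numeric length-3, voxel spacing in mm (all positive).
#' @param origin Numeric length-3, physical position (mm) of the centre of
#'   voxel `[1, 1, 1]`.
#' @return An object of class `voxel_mask`.
#' @examples
#' m <- voxel_mask(array(TRUE, c(2, 2, 2)), spacing = c(1, 1, 5))
#' mask_volume_cm3(m)
#' @export
voxel_mask <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(grid)) != 3L) {
    stop("`grid` must be a 3-D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive lengths (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be a finite 3-vector (mm)", call. = FALSE)
  }
  storage.mode(grid) <- "logical"
  grid[is.na(grid)] <- FALSE
  structure(
    list(grid = grid, spacing = spacing, origin = origin),
    class = "voxel_mask"
  )
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf(
    "<voxel_mask> %d x %d x %d voxels, spacing %s mm, %d foreground (%.2f cm^3)\n",
    d[1], d[2], d[3], paste(format(x$spacing, trim = TRUE), collapse = " x "),
    sum(x$grid), mask_volume_cm3(x)
  ))
  invisible(x)
}

#' @rdname voxel_mask
#' @param x Object to test.
#' @export
is_voxel_mask <- function(x) inherits(x, "voxel_mask")

assert_mask <- function(x, arg = deparse(substitute(x))) {
  if (!is_voxel_mask(x)) {
    stop(sprintf("`%s` must be a voxel_mask", arg), call. = FALSE)
  }
  invisible(x)
}

#' Number of foreground voxels
#' @param mask A [voxel_mask()].
#' @return Integer count of `TRUE` voxels.
#' @export
mask_count <- function(mask) {
  assert_mask(mask)
  sum(mask$grid)
}

#' Foreground volume in cm^3
#' @inheritParams mask_count
#' @return Volume of the foreground in cm^3.
#' @export
mask_volume_cm3 <- function(mask) {
  assert_mask(mask)
  sum(mask$grid) * prod(mask$spacing) / 1000
}

#' Physical centroid of the foreground
#' @inheritParams mask_count
#' @return Length-3 numeric, centroid of foreground voxel centres in mm.
#' @export
mask_centroid <- function(mask) {
  assert_mask(mask)
  idx <- which(mask$grid, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty", call. = FALSE)
  unname(colMeans(sweep(sweep(idx - 1, 2, mask$spacing, `*`), 2,
                        mask$origin, `+`)))
}

#' Physical coordinates of all foreground voxel centres
#' @inheritParams mask_count
#' @return n x 3 matrix of mm coordinates.
#' @export
mask_coordinates <- function(mask) {
  assert_mask(mask)
  idx <- which(mask$grid, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
}

#' Dice overlap coefficient between two masks
#'
#' `2 |X intersect Y| / (|X| + |Y|)` over foreground voxels.  Both masks must
#' share grid dimensions; spacing is not checked because Dice is a pure
#' voxel-count measure.
#'
#' @param x,y [voxel_mask()] objects on the same grid.
#' @return Dice coefficient in `[0, 1]` (1 if both masks are empty).
#' @export
dice <- function(x, y) {
  assert_mask(x)
  assert_mask(y)
  if (!identical(dim(x$grid), dim(y$grid))) {
    stop("masks must share grid dimensions", call. = FALSE)
  }
  denom <- sum(x$grid) + sum(y$grid)
  if (denom == 0) return(1)
  2 * sum(x$grid & y$grid) / denom
}

#' Crop a mask to the bounding box of its foreground
#'
#' @inheritParams mask_count
#' @param pad Number of background voxels to keep around the bounding box
#'   (clipped at the grid edge).
#' @return A smaller [voxel_mask()] with an adjusted origin.
#' @export
crop_mask <- function(mask, pad = 2L) {
  assert_mask(mask)
  idx <- which(mask$grid, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty", call. = FALSE)
  d <- dim(mask$grid)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, d)
  grid <- mask$grid[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  voxel_mask(grid, mask$spacing, mask$origin + (lo - 1) * mask$spacing)
}

#' Connected components of a mask
#'
#' @inheritParams mask_count
#' @param connectivity 6 (face) or 26 (face/edge/corner) neighbourhood.
#' @return Integer array of component labels (0 = background) with attribute
#'   `n_components`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  assert_mask(mask)
  if (!connectivity %in% c(6L, 26L)) {
    stop("`connectivity` must be 6 or 26", call. = FALSE)
  }
  lab <- cpp_label_components(mask$grid, dim(mask$grid), as.integer(connectivity))
  n <- attr(lab, "n_components")
  dim(lab) <- dim(mask$grid)
  attr(lab, "n_components") <- n
  lab
}

#' Read and write masks as NIfTI
#'
#' Thin wrappers over [RNifti::readNifti()] / [RNifti::writeNifti()] that map
#' between `voxel_mask` objects and NIfTI volumes.  Voxel spacing is carried
#' in `pixdim`; the mask is stored as 0/1.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_mask()` returns a [voxel_mask()]; `write_mask()` returns
#'   `path` invisibly.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  # origin is reset to zero: all package operations are origin-covariant, and
  # NIfTI sform/qform conventions are deliberately not interpreted here
  voxel_mask(array(as.array(img) > 0.5, dim(img)[1:3]),
             spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_mask
#' @param mask A [voxel_mask()].
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  img <- RNifti::asNifti(array(as.integer(mask$grid), dim(mask$grid)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
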