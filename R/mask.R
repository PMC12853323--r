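#' Binary tendon mask on a regular grid
#'
#' A 3D boolean voxel array plus the geometric and anatomical metadata the
#' region-of-interest operations need. The array is stored in canonical
#' orientation: axis 3 is the superior-inferior (slice) axis; axes 1-2 are
#' in-plane. Masks supplied with a different `slice_axis` are permuted at
#' construction.
#'
#' @param voxels logical 3D array.
#' @param voxel_dims numeric length-3 voxel edge lengths in mm (in the axis
#'   order of `voxels` as supplied).
#' @param origin numeric length-3 grid-corner position in mm.
#' @param slice_axis which axis of `voxels` runs superior-inferior (1-3).
#' @param proximal_end `"first"` or `"last"`: which end of the slice axis is
#'   proximal (toward the patella).
#' @param limb_side `"left"`, `"right"`, or `NA`. Required by [trisect_mask()].
#' @param medial_direction signed in-plane axis (one of `1, -1, 2, -2`, in
#'   canonical orientation) pointing medially, or `NA`. Required by
#'   [trisect_mask()].
#' @return A `tendon_mask` object.
#' @export
tendon_mask <- function(voxels, voxel_dims, origin = c(0, 0, 0),
                        slice_axis = 3L, proximal_end = c("first", "last"),
                        limb_side = NA_character_,
                        medial_direction = NA_integer_) {
  .assert(is.logical(voxels) && length(dim(voxels)) == 3L,
          "voxels must be a logical 3D array")
  .assert(length(voxel_dims) == 3L && all(voxel_dims > 0),
          "voxel_dims must be 3 positive lengths (mm)")
  proximal_end <- match.arg(proximal_end)
  slice_axis <- as.integer(slice_axis)
  .assert(slice_axis %in% 1:3, "slice_axis must be 1, 2 or 3")
  if (slice_axis != 3L) {
    perm <- c(setdiff(1:3, slice_axis), slice_axis)
    voxels <- aperm(voxels, perm)
    voxel_dims <- voxel_dims[perm]
    origin <- origin[perm]
  }
  if (!is.na(limb_side))
    .assert(limb_side %in% c("left", "right"), "limb_side must be 'left' or 'right'")
  if (!is.na(medial_direction))
    .assert(medial_direction %in% c(1L, -1L, 2L, -2L),
            "medial_direction must be one of 1, -1, 2, -2 (in-plane axes)")
  structure(list(voxels = voxels,
                 voxel_dims = as.numeric(voxel_dims),
                 origin = as.numeric(origin),
                 proximal_end = proximal_end,
                 limb_side = limb_side,
                 medial_direction = as.integer(medial_direction)),
            class = "tendon_mask")
}

#' @export
print.tendon_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<tendon_mask> %dx%dx%d grid, %.2gx%.2gx%.2g mm voxels, %d voxels set (%.2f cm^3)\n",
              d[1], d[2], d[3], x$voxel_dims[1], x$voxel_dims[2], x$voxel_dims[3],
              sum(x$voxels), mask_volume(x, "cm3")))
  invisible(x)
}

#' Grid descriptor of a mask or field
#' @param x a `tendon_mask`, `tensor_field`, `scalar_maps` or `dwi_volume`.
#' @return A [grid_spec()].
#' @export
mask_grid <- function(x) {
  if (inherits(x, "tendon_mask"))
    return(grid_spec(dim(x$voxels), x$voxel_dims, x$origin))
  if (!is.null(x$grid)) return(x$grid)
  stop("cannot derive a grid from this object", call. = FALSE)
}

# replace the voxel array, keeping metadata
.with_voxels <- function(mask, voxels) {
  mask$voxels <- voxels
  mask
}

#' Mask volume from voxel count
#'
#' Volume is the number of set voxels times the voxel volume.
#'
#' @param mask a [tendon_mask()].
#' @param units `"mm3"` (default) or `"cm3"` (as reported in result tables).
#' @return numeric volume.
#' @export
mask_volume <- function(mask, units = c("mm3", "cm3")) {
  units <- match.arg(units)
  v <- sum(mask$voxels) * prod(mask$voxel_dims)
  if (units == "cm3") v / 1000 else v
}

#' Exclude calcifications from a tendon mask
#'
#' Set difference between the tendon mask and a co-registered calcification
#' mask; downstream regions are derived from the result.
#'
#' @param mask tendon [tendon_mask()].
#' @param calcification_mask [tendon_mask()] (or logical array) on the same
#'   grid marking voxels to remove.
#' @return The tendon mask with calcified voxels cleared.
#' @export
exclude_calcifications <- function(mask, calcification_mask) {
  calc <- if (inherits(calcification_mask, "tendon_mask")) {
    .assert(.same_grid(mask_grid(mask), mask_grid(calcification_mask)),
            "tendon and calcification masks must share a grid")
    calcification_mask$voxels
  } else {
    .assert(identical(dim(calcification_mask), dim(mask$voxels)),
            "tendon and calcification masks must share a grid")
    calcification_mask
  }
  .with_voxels(mask, mask$voxels & !calc)
}

# indices of non-empty slices, ordered from the proximal end
.occupied_slices <- function(mask) {
  occ <- which(apply(mask$voxels, 3L, any))
  if (identical(mask$proximal_end, "last")) occ <- rev(occ)
  occ
}
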