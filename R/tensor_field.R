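#' Per-voxel diffusion tensor field
#'
#' Stores the six unique components of a symmetric 3x3 diffusion tensor per
#' voxel (order `xx, yy, zz, xy, xz, yz`, units mm^2/s), a fitted or
#' simulated baseline signal `s0`, and a per-voxel validity flag. Voxels
#' flagged invalid are excluded from all downstream statistics.
#'
#' @param tensors numeric 4D array `c(dim, 6)`.
#' @param s0 numeric 3D array of baseline signals.
#' @param valid logical 3D array.
#' @param grid a [grid_spec()].
#' @return A `tensor_field` object.
#' @export
tensor_field <- function(tensors, s0, valid, grid) {
  d <- dim(tensors)
  .assert(length(d) == 4L && d[4L] == 6L, "tensors must be a c(dim, 6) array")
  .assert(identical(dim(s0), d[1:3]) && identical(dim(valid), d[1:3]),
          "s0 and valid must match the tensor grid")
  .assert(all(d[1:3] == grid$dim), "grid dim must match the tensor array")
  structure(list(tensors = tensors, s0 = s0, valid = valid, grid = grid),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %s grid, %d valid voxels\n",
              paste(x$grid$dim, collapse = "x"), sum(x$valid)))
  invisible(x)
}

# 6-vector (xx,yy,zz,xy,xz,yz) -> symmetric 3x3
.tensor6_to_mat <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3L, 3L)
}

#' Pack a symmetric 3x3 tensor into its 6 unique components
#'
#' @param m numeric 3x3 matrix. An asymmetric matrix is rejected, since all
#'   diffusion tensors in this package are symmetric by construction.
#' @param tol relative symmetry tolerance.
#' @return numeric length-6 vector `(xx, yy, zz, xy, xz, yz)`.
#' @export
as_tensor6 <- function(m, tol = 1e-8) {
  .assert(is.matrix(m) && all(dim(m) == 3L), "m must be a 3x3 matrix")
  scale <- max(abs(m), 1e-300)
  .assert(max(abs(m - t(m))) <= tol * scale,
          "tensor is not symmetric; upstream invariant violated")
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}

# matrix (n_vox x 6) of in-mask tensor rows
.tensor_rows <- function(field, idx) {
  tn <- matrix(field$tensors, ncol = 6L)
  tn[idx, , drop = FALSE]
}

# quadratic forms g' D g for each voxel row (n x 6) and one direction g
.qform_rows <- function(rows, g) {
  rows[, 1L] * g[1]^2 + rows[, 2L] * g[2]^2 + rows[, 3L] * g[3]^2 +
    2 * (rows[, 4L] * g[1] * g[2] + rows[, 5L] * g[1] * g[3] + rows[, 6L] * g[2] * g[3])
}
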