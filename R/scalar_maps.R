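#' Eigenvalues, mean diffusivity and fractional anisotropy of one tensor
#'
#' @param lambda numeric length-3 eigenvalues (any order).
#' @return list with `lambda` (sorted descending), `md`, `fa`. FA is
#'   `sqrt(3/2) * sqrt(sum((lambda - md)^2)) / sqrt(sum(lambda^2))` and `NA`
#'   when all eigenvalues are zero.
#' @export
tensor_invariants <- function(lambda) {
  .assert(length(lambda) == 3L && all(is.finite(lambda)), "need 3 finite eigenvalues")
  lam <- sort(lambda, decreasing = TRUE)
  md <- mean(lam)
  den <- sqrt(sum(lam^2))
  fa <- if (den == 0) NA_real_ else sqrt(1.5) * sqrt(sum((lam - md)^2)) / den
  list(lambda = lam, md = md, fa = fa)
}

#' Scalar maps from a tensor field
#'
#' Eigen-decomposes each valid voxel's tensor and derives the maps used in
#' tendon DTI: sorted eigenvalues (lambda1 >= lambda2 >= lambda3, axial and
#' radial diffusivities), mean diffusivity `MD = (l1 + l2 + l3) / 3`, and
#' fractional anisotropy. Voxels whose eigenvalues are all zero get an
#' undefined FA and are flagged invalid; voxels with a negative eigenvalue
#' (possible under noise) are kept but flagged non-physical so that region
#' statistics can exclude them.
#'
#' @param tensor_field a [tensor_field()].
#' @return A `scalar_maps` object: arrays `lambda1`, `lambda2`, `lambda3`,
#'   `md`, `fa`, flags `valid` and `physical`, and the `grid`.
#' @export
scalar_maps <- function(tensor_field) {
  .assert(inherits(tensor_field, "tensor_field"), "tensor_field required")
  d <- tensor_field$grid$dim
  idx <- which(tensor_field$valid)
  rows <- .tensor_rows(tensor_field, idx)
  l1 <- l2 <- l3 <- md <- fa <- array(NA_real_, d)
  valid <- array(FALSE, d)
  physical <- array(FALSE, d)
  for (v in seq_along(idx)) {
    ev <- eigen(.tensor6_to_mat(rows[v, ]), symmetric = TRUE, only.values = TRUE)$values
    inv <- tensor_invariants(ev)
    i <- idx[v]
    l1[i] <- inv$lambda[1L]; l2[i] <- inv$lambda[2L]; l3[i] <- inv$lambda[3L]
    md[i] <- inv$md; fa[i] <- inv$fa
    valid[i] <- !is.na(inv$fa)
    physical[i] <- inv$lambda[3L] >= 0
  }
  structure(list(lambda1 = l1, lambda2 = l2, lambda3 = l3, md = md, fa = fa,
                 valid = valid, physical = physical, grid = tensor_field$grid),
            class = "scalar_maps")
}

#' @export
print.scalar_maps <- function(x, ...) {
  ok <- x$valid & x$physical
  cat(sprintf("<scalar_maps> %s grid, %d valid voxels (MD %.3g, FA %.3g at valid voxels)\n",
              paste(x$grid$dim, collapse = "x"), sum(ok),
              mean(x$md[ok]), mean(x$fa[ok])))
  invisible(x)
}
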