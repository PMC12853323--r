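`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Regular-grid descriptor
#'
#' A grid is a corner-anchored regular lattice: voxel `i` along an axis
#' covers `[origin + (i-1)*spacing, origin + i*spacing)` in millimetres,
#' with its centre at `origin + (i-1/2)*spacing`.
#'
#' @param dim integer length-3 array dimensions.
#' @param spacing numeric length-3 voxel edge lengths in mm.
#' @param origin numeric length-3 position of the grid corner in mm.
#' @return A `grid_spec` list with elements `dim`, `spacing`, `origin`.
#' @export
grid_spec <- function(dim, spacing, origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  .assert(length(dim) == 3L && all(dim >= 1L), "grid dim must be 3 positive integers")
  .assert(length(spacing) == 3L && all(spacing > 0), "grid spacing must be 3 positive numbers")
  .assert(length(origin) == 3L && all(is.finite(origin)), "grid origin must be 3 finite numbers")
  structure(list(dim = dim, spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "grid_spec")
}

.same_grid <- function(a, b, tol = 1e-9) {
  all(a$dim == b$dim) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

# linear index from an n-column coordinate matrix (1-based)
.coord_to_lin <- function(cc, d) {
  lin <- cc[, 1L]
  mult <- 1L
  for (ax in seq_along(d)[-1L]) {
    mult <- mult * d[ax - 1L]
    lin <- lin + (cc[, ax] - 1L) * mult
  }
  lin
}

#' Label face-connected components of a binary array
#'
#' Breadth-first labelling with face connectivity (4-connected in 2D,
#' 6-connected in 3D). Intended for the small mask grids this package
#' works on.
#'
#' @param x logical array (2D or 3D).
#' @return integer array of the same shape; 0 is background, components
#'   are numbered from 1 in first-encounter order.
#' @export
connected_components <- function(x) {
  d <- dim(x)
  .assert(!is.null(d) && length(d) %in% c(2L, 3L), "x must be a 2D or 3D array")
  lab <- array(0L, d)
  pending <- x
  idx_all <- which(x)
  nd <- length(d)
  next_lab <- 0L
  for (seed in idx_all) {
    if (!pending[seed]) next
    next_lab <- next_lab + 1L
    pending[seed] <- FALSE
    frontier <- seed
    while (length(frontier)) {
      lab[frontier] <- next_lab
      fc <- arrayInd(frontier, d)
      nb <- integer(0)
      for (ax in seq_len(nd)) {
        for (s in c(-1L, 1L)) {
          cc <- fc
          cc[, ax] <- cc[, ax] + s
          ok <- cc[, ax] >= 1L & cc[, ax] <= d[ax]
          if (any(ok)) nb <- c(nb, .coord_to_lin(cc[ok, , drop = FALSE], d))
        }
      }
      nb <- unique(nb)
      nb <- nb[pending[nb]]
      pending[nb] <- FALSE
      frontier <- nb
    }
  }
  lab
}

#' Keep the largest face-connected component
#'
#' @param x logical array (2D or 3D).
#' @return logical array retaining only the largest component (ties broken
#'   by lowest label, i.e. first encountered in array order).
#' @export
largest_component <- function(x) {
  lab <- connected_components(x)
  if (!any(lab > 0L)) return(x & FALSE)
  tab <- tabulate(lab)
  keep <- which.max(tab)  # ties -> lowest label
  lab == keep
}

# Squared Euclidean distance transform on an anisotropic grid.
# Separable min-plus transform along each axis; exact for the voxel-centre
# metric. O(m^2 * L) per axis, fine at mask-phantom sizes.
.edt_sq <- function(src, spacing) {
  d <- dim(src)
  nd <- length(d)
  BIG <- 1e18
  f <- array(BIG, d)
  f[src] <- 0
  for (ax in seq_len(nd)) {
    perm <- c(ax, setdiff(seq_len(nd), ax))
    fp <- aperm(f, perm)
    m <- dim(fp)[1L]
    M <- matrix(fp, nrow = m)
    pos <- (seq_len(m) - 1) * spacing[ax]
    out <- M
    for (j in seq_len(m)) {
      row <- M[j, ]
      if (all(row >= BIG / 2)) next
      cand <- matrix(row, nrow = m, ncol = ncol(M), byrow = TRUE) + (pos - pos[j])^2
      out <- pmin(out, cand)
    }
    f <- aperm(array(out, dim(fp)), order(perm))
  }
  f[f >= BIG / 2] <- Inf
  f
}

#' Signed distance to the mask boundary
#'
#' Positive inside the mask, negative outside, measured in mm between voxel
#' centres on the (possibly anisotropic) grid. Thresholding the result at 0
#' recovers the input mask exactly.
#'
#' @param mask logical array.
#' @param spacing numeric voxel edge lengths (one per array axis), mm.
#' @return numeric array of signed distances in mm.
#' @export
signed_distance <- function(mask, spacing) {
  .assert(is.logical(mask) && !is.null(dim(mask)), "mask must be a logical array")
  .assert(length(spacing) == length(dim(mask)) && all(spacing > 0),
          "spacing must match array rank and be positive")
  d_to_mask <- sqrt(.edt_sq(mask, spacing))
  d_to_bg <- sqrt(.edt_sq(!mask, spacing))
  d_to_bg - d_to_mask
}

# Separable Gaussian smoothing with edge replication. sigma_vox in voxels.
.gaussian_smooth <- function(x, sigma_vox) {
  d <- dim(x)
  for (ax in seq_along(d)) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    perm <- c(ax, setdiff(seq_along(d), ax))
    xp <- aperm(x, perm)
    m <- dim(xp)[1L]
    M <- matrix(xp, nrow = m)
    pad_rows <- pmax(pmin(seq_len(m + 2L * r) - r, m), 1L)
    P <- M[pad_rows, , drop = FALSE]
    out <- matrix(0, m, ncol(M))
    for (t in seq_along(k)) out <- out + k[t] * P[t:(t + m - 1L), , drop = FALSE]
    x <- aperm(array(out, dim(xp)), order(perm))
  }
  x
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b logical arrays of identical shape.
#' @return Dice coefficient 2|a&b|/(|a|+|b|); 1 when both are empty.
#' @export
dice_overlap <- function(a, b) {
  .assert(identical(dim(a), dim(b)), "masks must share a shape")
  den <- sum(a) + sum(b)
  if (den == 0) return(1)
  2 * sum(a & b) / den
}
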