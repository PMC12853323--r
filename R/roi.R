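#' Named tendon region masks on a shared grid
#'
#' @param masks named list of logical arrays (subset of `whole`, `medial`,
#'   `central`, `lateral`, `proximal`, `distal`) on one grid.
#' @param grid a [grid_spec()].
#' @param meta list of anatomical metadata (`limb_side`, `medial_direction`,
#'   `proximal_end`).
#' @param provenance free-form list recording how the set was derived.
#' @return A `region_set` object.
#' @export
region_set <- function(masks, grid, meta = list(), provenance = list()) {
  .assert(is.list(masks) && length(masks) > 0 && !is.null(names(masks)),
          "masks must be a named list")
  for (m in masks) .assert(identical(dim(m), as.integer(grid$dim)) ||
                             identical(dim(m), grid$dim),
                           "all region masks must live on the stated grid")
  structure(list(masks = masks, grid = grid, meta = meta, provenance = provenance),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %s grid: %s\n", paste(x$grid$dim, collapse = "x"),
              paste(sprintf("%s(%d)", names(x$masks), vapply(x$masks, sum, 0L)),
                    collapse = ", ")))
  invisible(x)
}

#' Region mask as a tendon_mask
#' @param regions a [region_set()].
#' @param name region name.
#' @return A [tendon_mask()] carrying the set's metadata.
#' @export
region_mask <- function(regions, name) {
  .assert(name %in% names(regions$masks), sprintf("no region '%s'", name))
  tendon_mask(regions$masks[[name]], regions$grid$spacing, regions$grid$origin,
              proximal_end = regions$meta$proximal_end %||% "first",
              limb_side = regions$meta$limb_side %||% NA_character_,
              medial_direction = regions$meta$medial_direction %||% NA_integer_)
}

# in-plane 4-neighbour counts (per slice) for boundary detection
.inplane_neighbour_and <- function(v) {
  d <- dim(v)
  sh <- function(ax, s) {
    out <- array(FALSE, d)
    if (ax == 1L) {
      if (s == 1L) out[2:d[1L], , ] <- v[1:(d[1L] - 1L), , ]
      else out[1:(d[1L] - 1L), , ] <- v[2:d[1L], , ]
    } else {
      if (s == 1L) out[, 2:d[2L], ] <- v[, 1:(d[2L] - 1L), ]
      else out[, 1:(d[2L] - 1L), ] <- v[, 2:d[2L], ]
    }
    out
  }
  v & sh(1L, 1L) & sh(1L, -1L) & sh(2L, 1L) & sh(2L, -1L)
}

#' Greatest in-plane diameter of a slice mask
#'
#' The longest chord between boundary-voxel centres of the slice's largest
#' connected component, the "greatest cross-sectional diameter in
#' transverse view" along which the tendon is trisected. Candidates are the
#' convex-hull vertices of the boundary points; distance ties are broken by
#' the lexicographically smallest endpoint pair. A single-voxel slice has
#' length 0 with the axis defaulting to the first in-plane axis.
#'
#' @param slice_mask logical matrix (one transverse slice).
#' @param spacing in-plane voxel dimensions, mm.
#' @param origin in-plane grid-corner coordinates, mm.
#' @return list with `endpoints` (2 x 2 matrix of mm coordinates), unit
#'   `axis`, and `length` in mm.
#' @export
longest_diameter <- function(slice_mask, spacing = c(1, 1), origin = c(0, 0)) {
  .assert(is.logical(slice_mask) && length(dim(slice_mask)) == 2L,
          "slice_mask must be a logical matrix")
  .assert(any(slice_mask), "slice is empty")
  comp <- largest_component(slice_mask)
  d <- dim(comp)
  # boundary voxels: in-component with a missing in-plane 4-neighbour
  interior <- .inplane_neighbour_and(array(comp, c(d, 1L)))[, , 1L]
  boundary <- comp & !interior
  coords <- which(boundary, arr.ind = TRUE)
  pts <- cbind(origin[1L] + (coords[, 1L] - 0.5) * spacing[1L],
               origin[2L] + (coords[, 2L] - 0.5) * spacing[2L])
  if (nrow(pts) == 1L)
    return(list(endpoints = rbind(pts[1L, ], pts[1L, ]), axis = c(1, 0), length = 0))
  hp <- pts
  if (nrow(pts) >= 3L) {
    h <- tryCatch(grDevices::chull(pts[, 1L], pts[, 2L]),
                  error = function(e) seq_len(nrow(pts)))
    hp <- pts[unique(h), , drop = FALSE]
    if (nrow(hp) < 2L) hp <- pts
  }
  D <- as.matrix(stats::dist(hp))
  dmax <- max(D)
  tol <- 1e-9 * max(1, dmax)
  cand <- which(D >= dmax - tol & upper.tri(D), arr.ind = TRUE)
  pairs <- lapply(seq_len(nrow(cand)), function(r) {
    p <- hp[cand[r, 1L], ]; q <- hp[cand[r, 2L], ]
    if (p[1L] > q[1L] || (p[1L] == q[1L] && p[2L] > q[2L])) rbind(q, p) else rbind(p, q)
  })
  km <- t(vapply(pairs, function(pq) c(pq[1, 1], pq[1, 2], pq[2, 1], pq[2, 2]),
                 numeric(4)))
  best <- pairs[[order(km[, 1L], km[, 2L], km[, 3L], km[, 4L])[1L]]]
  len <- sqrt(sum((best[2L, ] - best[1L, ])^2))
  axis <- if (len > 0) (best[2L, ] - best[1L, ]) / len else c(1, 0)
  list(endpoints = unname(best), axis = unname(axis), length = len)
}

# classify slice voxels into lateral/central/medial thirds along the diameter
.classify_thirds <- function(pts, dia, mvec, spacing, tol = 1e-9) {
  n <- nrow(pts)
  L <- dia$length
  # degenerate slice: extent under ~3 voxels along the axis -> all central
  if (L < 2 * mean(spacing)) return(rep("central", n))
  u <- dia$axis
  A <- dia$endpoints[1L, ]
  du <- sum(u * mvec)
  if (du < -tol) {
    u <- -u; A <- dia$endpoints[2L, ]
  } else if (abs(du) <= tol) {
    # diameter perpendicular to the medial direction; orient deterministically
    if (u[1L] < 0 || (u[1L] == 0 && u[2L] < 0)) { u <- -u; A <- dia$endpoints[2L, ] }
  }
  t <- (pts[, 1L] - A[1L]) * u[1L] + (pts[, 2L] - A[2L]) * u[2L]
  eps <- tol * max(1, L)
  out <- rep("central", n)                 # voxels exactly on a cut stay central
  out[t < L / 3 - eps] <- "lateral"
  out[t > 2 * L / 3 + eps] <- "medial"
  out
}

# signed unit vector of the medial direction in the in-plane frame
.medial_vector <- function(mask) {
  md <- mask$medial_direction
  v <- c(0, 0)
  v[abs(md)] <- sign(md)
  v
}

#' Trisect a tendon mask into medial, central and lateral thirds
#'
#' Per transverse slice, the greatest cross-sectional diameter is found
#' ([longest_diameter()]), voxel centres are projected onto the diameter
#' axis, and boundaries perpendicular to the axis are placed at 1/3 and 2/3
#' of the extent between the diameter endpoints, giving full-length
#' regions of equal width. Which end of the axis is medial is resolved from
#' the mask's `limb_side`/`medial_direction` metadata. Voxels projecting
#' exactly onto a cut point are assigned to the central region; slices with
#' an extent under about 3 voxels along the axis are assigned entirely to
#' central.
#'
#' @param mask a [tendon_mask()] with laterality metadata.
#' @return A [region_set()] with `whole`, `medial`, `central`, `lateral`.
#'   The three regions are pairwise disjoint and their union is the whole
#'   mask.
#' @export
trisect_mask <- function(mask) {
  .assert(inherits(mask, "tendon_mask"), "mask must be a tendon_mask")
  .assert(any(mask$voxels), "mask is empty")
  if (is.na(mask$limb_side) || is.na(mask$medial_direction))
    stop("limb_side (and medial_direction) metadata are required to resolve the medial side",
         call. = FALSE)
  g <- mask_grid(mask)
  sp <- g$spacing[1:2]
  or2 <- g$origin[1:2]
  mvec <- .medial_vector(mask)
  med <- cen <- lat <- array(FALSE, g$dim)
  for (k in which(apply(mask$voxels, 3L, any))) {
    sl <- mask$voxels[, , k]
    dia <- longest_diameter(sl, sp, or2)
    coords <- which(sl, arr.ind = TRUE)
    pts <- cbind(or2[1L] + (coords[, 1L] - 0.5) * sp[1L],
                 or2[2L] + (coords[, 2L] - 0.5) * sp[2L])
    lab <- .classify_thirds(pts, dia, mvec, sp)
    lin <- coords[, 1L] + (coords[, 2L] - 1L) * g$dim[1L] + (k - 1L) * g$dim[1L] * g$dim[2L]
    med[lin[lab == "medial"]] <- TRUE
    cen[lin[lab == "central"]] <- TRUE
    lat[lin[lab == "lateral"]] <- TRUE
  }
  region_set(list(whole = mask$voxels, medial = med, central = cen, lateral = lat),
             g,
             meta = list(limb_side = mask$limb_side,
                         medial_direction = mask$medial_direction,
                         proximal_end = mask$proximal_end),
             provenance = list(op = "trisect_mask"))
}

#' Bisect a tendon mask into proximal and distal halves
#'
#' Occupied slices are split into two runs of equal length starting from
#' the proximal end. With an odd number of occupied slices the middle slice
#' is included in both regions.
#'
#' @param mask a [tendon_mask()].
#' @return A [region_set()] with `whole`, `proximal`, `distal`.
#' @export
bisect_mask <- function(mask) {
  .assert(inherits(mask, "tendon_mask"), "mask must be a tendon_mask")
  .assert(any(mask$voxels), "mask is empty")
  g <- mask_grid(mask)
  occ <- .occupied_slices(mask)
  n <- length(occ)
  prox_slices <- occ[seq_len(ceiling(n / 2))]
  dist_slices <- occ[seq.int(floor(n / 2) + 1L, n)]
  prox <- dist <- array(FALSE, g$dim)
  prox[, , prox_slices] <- mask$voxels[, , prox_slices]
  dist[, , dist_slices] <- mask$voxels[, , dist_slices]
  region_set(list(whole = mask$voxels, proximal = prox, distal = dist),
             g,
             meta = list(limb_side = mask$limb_side,
                         medial_direction = mask$medial_direction,
                         proximal_end = mask$proximal_end),
             provenance = list(op = "bisect_mask"))
}

#' Full six-region tendon partition
#'
#' Combines [trisect_mask()] and [bisect_mask()] into the region set used
#' throughout the reliability analysis: whole, medial, central, lateral,
#' proximal, distal.
#'
#' @param mask a [tendon_mask()] with laterality metadata.
#' @return A [region_set()] with all six masks.
#' @export
partition_tendon <- function(mask) {
  tri <- trisect_mask(mask)
  bis <- bisect_mask(mask)
  region_set(c(tri$masks, bis$masks[c("proximal", "distal")]),
             tri$grid, meta = tri$meta,
             provenance = list(op = "partition_tendon"))
}

# axis overlap lengths between source cells (rows) and target cells (cols)
.axis_overlap <- function(n_s, sp_s, o_s, n_t, sp_t, o_t) {
  lo_s <- o_s + (seq_len(n_s) - 1) * sp_s
  lo_t <- o_t + (seq_len(n_t) - 1) * sp_t
  ov <- outer(lo_s + sp_s, lo_t + sp_t, pmin) - outer(lo_s, lo_t, pmax)
  ov[ov < 0] <- 0
  ov
}

# occupancy of each target voxel: covered fraction of its volume
.occupancy <- function(src_arr, src_grid, tgt_grid) {
  for (ax in 1:3) {
    lo_s <- src_grid$origin[ax]; hi_s <- lo_s + src_grid$dim[ax] * src_grid$spacing[ax]
    lo_t <- tgt_grid$origin[ax]; hi_t <- lo_t + tgt_grid$dim[ax] * tgt_grid$spacing[ax]
    if (min(hi_s, hi_t) <= max(lo_s, lo_t))
      stop("grids do not overlap; check origins and extents", call. = FALSE)
  }
  O <- lapply(1:3, function(ax)
    .axis_overlap(src_grid$dim[ax], src_grid$spacing[ax], src_grid$origin[ax],
                  tgt_grid$dim[ax], tgt_grid$spacing[ax], tgt_grid$origin[ax]))
  a <- array(as.numeric(src_arr), src_grid$dim)
  # contract axis 1
  r1 <- crossprod(O[[1L]], matrix(a, src_grid$dim[1L]))
  a <- array(r1, c(tgt_grid$dim[1L], src_grid$dim[2L], src_grid$dim[3L]))
  # contract axis 2
  ap <- aperm(a, c(2L, 1L, 3L))
  r2 <- crossprod(O[[2L]], matrix(ap, src_grid$dim[2L]))
  a <- aperm(array(r2, c(tgt_grid$dim[2L], tgt_grid$dim[1L], src_grid$dim[3L])),
             c(2L, 1L, 3L))
  # contract axis 3
  ap <- aperm(a, c(3L, 1L, 2L))
  r3 <- crossprod(O[[3L]], matrix(ap, src_grid$dim[3L]))
  a <- aperm(array(r3, c(tgt_grid$dim[3L], tgt_grid$dim[1L], tgt_grid$dim[2L])),
             c(2L, 3L, 1L))
  a / prod(tgt_grid$spacing)
}

#' Downsample a mask to a coarser grid by volume occupancy
#'
#' Each target voxel's occupancy is the fraction of its volume covered by
#' true source voxels; it is included iff occupancy >= `threshold` (ties at
#' the threshold are included).
#'
#' @param mask a high-resolution [tendon_mask()].
#' @param target_grid a [grid_spec()] (e.g. the DTI grid).
#' @param threshold occupancy threshold in `(0, 1]`, default 0.5.
#' @return A [tendon_mask()] on `target_grid` with the source metadata.
#' @export
downsample_mask <- function(mask, target_grid, threshold = 0.5) {
  .assert(inherits(mask, "tendon_mask"), "mask must be a tendon_mask")
  .assert(threshold > 0 && threshold <= 1, "threshold must be in (0, 1]")
  occ <- .occupancy(mask$voxels, mask_grid(mask), target_grid)
  tendon_mask(occ >= threshold - 1e-9, target_grid$spacing, target_grid$origin,
              proximal_end = mask$proximal_end, limb_side = mask$limb_side,
              medial_direction = mask$medial_direction)
}

#' Occupancy fractions of a mask on a target grid
#'
#' The partial-volume map underlying [downsample_mask()]; also used to mix
#' tendon and background tissue when simulating DWI at DTI resolution.
#'
#' @inheritParams downsample_mask
#' @return numeric array on `target_grid` with values in `[0, 1]`.
#' @export
mask_occupancy <- function(mask, target_grid) {
  pmin(pmax(.occupancy(mask$voxels, mask_grid(mask), target_grid), 0), 1)
}

#' Erode a mask by one boundary pixel, in-plane
#'
#' 2D morphological erosion per transverse slice with a 4-connected
#' (plus-shaped) structuring element. Erosion is deliberately in-plane:
#' with 3 mm slices a 3D erosion would delete the first and last slices
#' outright. Slices eroded to empty remain empty.
#'
#' @param mask a [tendon_mask()].
#' @return The eroded [tendon_mask()].
#' @export
erode_boundary <- function(mask) {
  .assert(inherits(mask, "tendon_mask"), "mask must be a tendon_mask")
  .assert(any(mask$voxels), "mask is empty")
  .with_voxels(mask, .inplane_neighbour_and(mask$voxels))
}

#' Transfer a high-resolution region partition to the DTI grid
#'
#' The whole-tendon mask is downsampled by occupancy (>= `threshold`) and,
#' optionally, eroded by one in-plane boundary pixel. Medial/central/lateral
#' labels are transferred to each retained DTI voxel by majority occupancy
#' among the three high-resolution label masks (ties prefer central, then
#' medial); proximal/distal are re-derived from the slice rule on the DTI
#' grid.
#'
#' @param regions a high-resolution [region_set()] from [partition_tendon()].
#' @param target_grid the DTI [grid_spec()].
#' @param threshold occupancy threshold, default 0.5.
#' @param erode logical, erode the whole mask by one boundary pixel
#'   (default `TRUE`).
#' @return A [region_set()] on `target_grid`.
#' @export
regions_to_grid <- function(regions, target_grid, threshold = 0.5, erode = TRUE) {
  .assert(inherits(regions, "region_set"), "regions must be a region_set")
  .assert(all(c("whole", "medial", "central", "lateral") %in% names(regions$masks)),
          "regions must contain whole/medial/central/lateral masks")
  src_grid <- regions$grid
  occ_w <- .occupancy(regions$masks$whole, src_grid, target_grid)
  whole <- occ_w >= threshold - 1e-9
  wm <- tendon_mask(whole, target_grid$spacing, target_grid$origin,
                    proximal_end = regions$meta$proximal_end %||% "first",
                    limb_side = regions$meta$limb_side %||% NA_character_,
                    medial_direction = regions$meta$medial_direction %||% NA_integer_)
  if (erode) wm <- erode_boundary(wm)
  whole <- wm$voxels
  occ_m <- .occupancy(regions$masks$medial, src_grid, target_grid)
  occ_c <- .occupancy(regions$masks$central, src_grid, target_grid)
  occ_l <- .occupancy(regions$masks$lateral, src_grid, target_grid)
  best <- pmax(occ_m, occ_c, occ_l)
  tie <- 1e-12
  cen <- whole & (occ_c >= best - tie)
  med <- whole & !cen & (occ_m >= best - tie)
  lat <- whole & !cen & !med
  bis <- if (any(whole)) bisect_mask(wm)$masks else
    list(proximal = whole, distal = whole)
  region_set(list(whole = whole, medial = med, central = cen, lateral = lat,
                  proximal = bis$proximal, distal = bis$distal),
             target_grid, meta = regions$meta,
             provenance = list(op = "regions_to_grid", threshold = threshold,
                               eroded = erode))
}
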