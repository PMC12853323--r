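#' Tendon tissue diffusion parameters
#'
#' Diffusivities along the sorted tensor eigenvectors plus the baseline
#' (b = 0) signal. The defaults describe a healthy tendon phantom with
#' mean diffusivity 0.693e-3 mm^2/s and fractional anisotropy ~0.42, in the
#' range reported for in vivo patellar tendon.
#'
#' @param lambda1,lambda2,lambda3 diffusivities in mm^2/s, sorted
#'   `lambda1 >= lambda2 >= lambda3 > 0`; `lambda1` lies along the tendon
#'   long axis.
#' @param principal_axis unit 3-vector of the nominal tendon long axis.
#' @param s0 baseline signal (arbitrary units, > 0).
#' @return A `tissue_params` object.
#' @export
tissue_params <- function(lambda1 = 1.05e-3, lambda2 = 0.55e-3, lambda3 = 0.48e-3,
                          principal_axis = c(0, 0, 1), s0 = 1) {
  .assert(lambda1 >= lambda2 && lambda2 >= lambda3 && lambda3 > 0,
          "diffusivities must satisfy lambda1 >= lambda2 >= lambda3 > 0")
  .assert(length(principal_axis) == 3L && sum(principal_axis^2) > 0,
          "principal_axis must be a non-zero 3-vector")
  .assert(s0 > 0, "s0 must be positive")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 principal_axis = principal_axis / sqrt(sum(principal_axis^2)),
                 s0 = s0),
            class = "tissue_params")
}

#' Synthetic tendon mask: curved elliptic cylinder
#'
#' Builds a connected binary tendon mask spanning `n_slices` axial slices.
#' Each slice is an ellipse (medial-lateral semi-axis `semi_axis_ml`,
#' antero-posterior semi-axis `semi_axis_ap`, mm) whose centre bows
#' in-plane by up to `curve_mm` along the length, mimicking the mild
#' superior-inferior curvature of the patellar tendon.
#'
#' @param shape_params list with elements `n_slices` (>= 3),
#'   `semi_axis_ml`, `semi_axis_ap` (mm, > 0), `curve_mm` (mm, >= 0),
#'   `first_slice` (index of the first occupied slice, default 1), and
#'   optional `center_mm` (in-plane ellipse centre, mm).
#' @param grid a [grid_spec()]; default 48 x 32 x 25 at 0.5 mm isotropic.
#' @param limb_side,medial_direction,proximal_end metadata stored on the
#'   mask; see [tendon_mask()].
#' @return A [tendon_mask()] in which every slice between the first and
#'   last occupied slice is non-empty and the mask is face-connected.
#' @export
make_tendon_mask <- function(shape_params = list(),
                             grid = grid_spec(c(48, 32, 25), c(0.5, 0.5, 0.5)),
                             limb_side = "left", medial_direction = 1L,
                             proximal_end = "first") {
  p <- utils::modifyList(list(n_slices = 25L, semi_axis_ml = 7.5,
                              semi_axis_ap = 4.0, curve_mm = 2.0,
                              first_slice = 1L, center_mm = NULL),
                         shape_params)
  .assert(p$semi_axis_ml > 0 && p$semi_axis_ap > 0,
          "degenerate shape: ellipse semi-axes must be positive (zero cross-section)")
  .assert(p$n_slices >= 3L, "the tendon must span at least 3 slices")
  .assert(p$first_slice >= 1L && p$first_slice + p$n_slices - 1L <= grid$dim[3L],
          "tendon slices must fit inside the grid")
  .assert(p$curve_mm >= 0, "curve_mm must be >= 0")
  cx <- grid$origin[1L] + grid$dim[1L] * grid$spacing[1L] / 2
  cy <- grid$origin[2L] + grid$dim[2L] * grid$spacing[2L] / 2
  if (!is.null(p$center_mm)) { cx <- p$center_mm[1L]; cy <- p$center_mm[2L] }
  xc <- grid$origin[1L] + (seq_len(grid$dim[1L]) - 0.5) * grid$spacing[1L]
  yc <- grid$origin[2L] + (seq_len(grid$dim[2L]) - 0.5) * grid$spacing[2L]
  vox <- array(FALSE, grid$dim)
  for (k in seq_len(p$n_slices)) {
    bow <- if (p$n_slices > 1L) p$curve_mm * sin(pi * (k - 1L) / (p$n_slices - 1L)) else 0
    ex <- (xc - cx - bow) / p$semi_axis_ml
    sl <- outer(ex^2, ((yc - cy) / p$semi_axis_ap)^2, `+`) <= 1
    vox[, , p$first_slice + k - 1L] <- sl
  }
  occupied <- which(apply(vox, 3L, any))
  .assert(length(occupied) == p$n_slices,
          "degenerate shape: some slices contain no voxels; enlarge the cross-section or grid")
  mask <- tendon_mask(vox, grid$spacing, grid$origin,
                      proximal_end = proximal_end, limb_side = limb_side,
                      medial_direction = medial_direction)
  .assert(sum(connected_components(vox) > 0) == sum(vox) &&
            max(connected_components(vox)) == 1L,
          "mask is not connected; reduce curvature relative to the cross-section")
  mask
}

# orthonormal basis with v1 along axis
.axis_basis <- function(axis) {
  v1 <- axis / sqrt(sum(axis^2))
  ref <- if (abs(v1[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v2 <- ref - sum(ref * v1) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  v3 <- c(v1[2L] * v2[3L] - v1[3L] * v2[2L],
          v1[3L] * v2[1L] - v1[1L] * v2[3L],
          v1[1L] * v2[2L] - v1[2L] * v2[1L])
  cbind(v1, v2, v3)
}

# mixing used by the pathology model: raise diffusivity, pull toward isotropy
.apply_pathology <- function(d6, a, gain = 0.5, mix = 0.6) {
  md <- (d6[1L] + d6[2L] + d6[3L]) / 3
  iso <- c(md, md, md, 0, 0, 0)
  (1 + gain * a) * ((1 - mix * a) * d6 + mix * a * iso)
}

#' Synthetic diffusion tensor field for a tendon mask
#'
#' Every in-mask voxel receives `D = R diag(lambda1, lambda2, lambda3) R'`
#' with the principal eigenvector along the local tendon axis (the tangent
#' of the per-slice centroid line when `follow_centerline = TRUE`, else the
#' tissue's nominal axis). An optional pathology amplitude map raises
#' diffusivities and lowers fractional anisotropy monotonically with its
#' amplitude.
#'
#' @param mask a [tendon_mask()]; the field lives on the mask's grid.
#' @param tissue a [tissue_params()].
#' @param pathology_map optional numeric array (mask grid) of per-voxel
#'   pathology amplitudes; 0 leaves the tissue unchanged.
#' @param background_tissue optional [tissue_params()] filling out-of-mask
#'   voxels (e.g. isotropic surrounding soft tissue); if `NULL`, out-of-mask
#'   voxels carry zero tensor and zero signal.
#' @param occupancy optional numeric array in `[0, 1]` (mask grid) giving
#'   the tendon partial-volume fraction per voxel; tensors and s0 are then
#'   `occ * tendon + (1 - occ) * background`, which models the partial
#'   voluming that arises at DTI resolution.
#' @param follow_centerline logical; rotate the tensor to follow the mask's
#'   curved centreline (default `TRUE`).
#' @return A [tensor_field()] whose `valid` flag marks voxels with signal.
#' @export
make_tensor_field <- function(mask, tissue, pathology_map = NULL,
                              background_tissue = NULL, occupancy = NULL,
                              follow_centerline = TRUE) {
  .assert(inherits(mask, "tendon_mask"), "mask must be a tendon_mask")
  .assert(inherits(tissue, "tissue_params"), "tissue must be tissue_params")
  .assert(any(mask$voxels), "mask is empty")
  g <- mask_grid(mask)
  d <- g$dim
  if (!is.null(pathology_map))
    .assert(identical(dim(pathology_map), dim(mask$voxels)),
            "pathology_map must live on the mask grid")
  if (!is.null(occupancy)) {
    .assert(identical(dim(occupancy), dim(mask$voxels)) &&
              all(occupancy >= 0 & occupancy <= 1),
            "occupancy must be an array in [0, 1] on the mask grid")
    .assert(!is.null(background_tissue),
            "occupancy mixing requires a background_tissue")
  }

  lam <- c(tissue$lambda1, tissue$lambda2, tissue$lambda3)
  occ_slices <- which(apply(mask$voxels, 3L, any))
  # per-slice tangent of the centroid line
  tangents <- matrix(rep(tissue$principal_axis, d[3L]), ncol = 3L, byrow = TRUE)
  if (follow_centerline && length(occ_slices) >= 2L) {
    cent <- t(vapply(occ_slices, function(k) {
      idx <- which(mask$voxels[, , k], arr.ind = TRUE)
      c(mean(g$origin[1L] + (idx[, 1L] - 0.5) * g$spacing[1L]),
        mean(g$origin[2L] + (idx[, 2L] - 0.5) * g$spacing[2L]),
        g$origin[3L] + (k - 0.5) * g$spacing[3L])
    }, numeric(3L)))
    n <- nrow(cent)
    tg <- rbind(cent[2L, ] - cent[1L, ],
                if (n > 2L) cent[3L:n, , drop = FALSE] - cent[1L:(n - 2L), , drop = FALSE],
                cent[n, ] - cent[n - 1L, ])
    tg <- tg / sqrt(rowSums(tg^2))
    tangents[occ_slices, ] <- tg
  }

  tensors <- array(0, c(d, 6L))
  s0 <- array(0, d)
  tn <- matrix(tensors, ncol = 6L)
  for (k in occ_slices) {
    R <- .axis_basis(tangents[k, ])
    Dm <- R %*% diag(lam) %*% t(R)
    d6 <- as_tensor6((Dm + t(Dm)) / 2)
    in_slice <- which(as.vector(mask$voxels[, , k])) + (k - 1L) * d[1L] * d[2L]
    tn[in_slice, ] <- matrix(d6, length(in_slice), 6L, byrow = TRUE)
  }
  s0[mask$voxels] <- tissue$s0

  if (!is.null(pathology_map)) {
    idx <- which(mask$voxels & pathology_map != 0)
    for (i in idx) {
      d6 <- .apply_pathology(tn[i, ], pathology_map[i])
      ev <- eigen(.tensor6_to_mat(d6), symmetric = TRUE, only.values = TRUE)$values
      .assert(all(ev > 0),
              "pathology scaling produced non-positive eigenvalues")
      tn[i, ] <- d6
    }
  }

  if (!is.null(background_tissue)) {
    Rb <- .axis_basis(background_tissue$principal_axis)
    Db <- Rb %*% diag(c(background_tissue$lambda1, background_tissue$lambda2,
                        background_tissue$lambda3)) %*% t(Rb)
    b6 <- as_tensor6((Db + t(Db)) / 2)
    if (is.null(occupancy)) {
      out_idx <- which(!mask$voxels)
      tn[out_idx, ] <- matrix(b6, length(out_idx), 6L, byrow = TRUE)
      s0[!mask$voxels] <- background_tissue$s0
    } else {
      occv <- as.vector(occupancy)
      bg <- matrix(b6, length(occv), 6L, byrow = TRUE)
      tn <- occv * tn + (1 - occv) * bg
      s0 <- array(occv * as.vector(s0) + (1 - occv) * background_tissue$s0, d)
      # pure-tendon voxels missed by the binary mask still get tendon tensor
    }
  }

  tensor_field(array(tn, c(d, 6L)), s0, s0 > 0, g)
}

#' Simulate a diffusion-weighted acquisition
#'
#' Noise-free signal follows the single-tensor model
#' `S(b, g) = S0 * exp(-b * g' D g)`. With finite `snr`, Rician noise is
#' applied per voxel: `S' = sqrt((S + n1)^2 + n2^2)` with
#' `n1, n2 ~ Normal(0, (S0/snr)^2)`, so `snr` is defined on the voxel's
#' b = 0 signal.
#'
#' @param tensor_field a [tensor_field()].
#' @param protocol a [dwi_protocol()].
#' @param snr signal-to-noise ratio (> 0), or `Inf` for noise-free data.
#' @param seed optional integer; when given, the volume is reproducible and
#'   the global RNG state is left untouched.
#' @param s0_map optional baseline-signal array overriding the field's `s0`;
#'   must live on the field's grid.
#' @return A `dwi_volume`: list with `data` (4D array, volumes along axis
#'   4), `protocol`, and `grid`.
#' @export
simulate_dwi <- function(tensor_field, protocol, snr = Inf, seed = NULL,
                         s0_map = NULL) {
  .assert(inherits(tensor_field, "tensor_field"), "tensor_field required")
  .assert(inherits(protocol, "dwi_protocol"), "protocol required")
  .assert(is.infinite(snr) || snr > 0, "snr must be > 0 or Inf")
  d <- tensor_field$grid$dim
  s0 <- s0_map %||% tensor_field$s0
  .assert(identical(dim(s0), dim(tensor_field$s0)),
          "protocol/tensor grid mismatch: s0 map does not match the tensor grid")
  nv <- length(protocol$bvalues)
  .assert(nv >= 1L, "protocol/tensor grid mismatch: protocol has no volumes")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  rows <- matrix(tensor_field$tensors, ncol = 6L)
  s0v <- as.vector(s0)
  out <- matrix(0, length(s0v), nv)
  for (j in seq_len(nv)) {
    q <- protocol$bvalues[j] * .qform_rows(rows, protocol$directions[j, ])
    out[, j] <- s0v * exp(-q)
  }
  if (is.finite(snr)) {
    sigma <- s0v / snr
    n1 <- matrix(stats::rnorm(length(out)), nrow(out), nv) * sigma
    n2 <- matrix(stats::rnorm(length(out)), nrow(out), nv) * sigma
    out <- sqrt((out + n1)^2 + n2^2)
  }
  structure(list(data = array(out, c(d, nv)), protocol = protocol,
                 grid = tensor_field$grid),
            class = "dwi_volume")
}

#' Simulate a second rater's segmentation
#'
#' Perturbs the mask's signed distance field with a spatially smooth
#' zero-mean Gaussian random field (correlation length `corr_length_mm`,
#' standard deviation `amplitude_mm`) and re-thresholds at zero, keeping the
#' largest connected component. Spatially correlated perturbations mimic
#' how human raters disagree along whole boundary stretches rather than on
#' isolated voxels.
#'
#' @param mask a [tendon_mask()].
#' @param amplitude_mm perturbation amplitude in mm (>= 0); 0 returns the
#'   input unchanged.
#' @param seed optional integer for reproducibility (global RNG untouched).
#' @param corr_length_mm correlation length of the random field, mm.
#' @return A perturbed [tendon_mask()] with the same metadata.
#' @export
perturb_rater <- function(mask, amplitude_mm, seed = NULL, corr_length_mm = 2) {
  .assert(inherits(mask, "tendon_mask"), "mask must be a tendon_mask")
  .assert(is.finite(amplitude_mm) && amplitude_mm >= 0, "amplitude_mm must be >= 0")
  if (amplitude_mm == 0) return(mask)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  d <- dim(mask$voxels)
  sdf <- signed_distance(mask$voxels, mask$voxel_dims)
  field <- array(stats::rnorm(prod(d)), d)
  field <- .gaussian_smooth(field, corr_length_mm / mask$voxel_dims)
  field <- field - mean(field)
  sdev <- stats::sd(as.vector(field))
  if (sdev > 0) field <- field / sdev
  new_vox <- (sdf + amplitude_mm * field) > 0
  .assert(any(new_vox), "perturbation erased the mask; reduce amplitude_mm")
  .with_voxels(mask, largest_component(new_vox))
}
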