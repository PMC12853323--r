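test_that("tendon mask construction matches its geometric contracts", {
  # straight cylinder spanning 20 slices: every slice occupied
  m <- make_tendon_mask(list(n_slices = 20, semi_axis_ml = 3, semi_axis_ap = 3,
                             curve_mm = 0),
                        grid_spec(c(16, 16, 20), c(1, 1, 1)))
  expect_equal(sum(apply(m$voxels, 3, any)), 20)
  per_slice <- apply(m$voxels, 3, sum)
  expect_true(all(per_slice == per_slice[1]))

  # doubling the in-plane semi-axes ~ quadruples the per-slice voxel count
  m2 <- make_tendon_mask(list(n_slices = 20, semi_axis_ml = 6, semi_axis_ap = 6,
                              curve_mm = 0),
                         grid_spec(c(32, 32, 20), c(1, 1, 1)))
  ratio <- sum(m2$voxels) / sum(m$voxels)
  expect_gt(ratio, 4 * 0.8)
  expect_lt(ratio, 4 * 1.2)

  # zero cross-section is rejected
  expect_error(make_tendon_mask(list(semi_axis_ml = 0),
                                grid_spec(c(16, 16, 25), c(1, 1, 1))),
               "degenerate")
})

test_that("tensor fields place the requested tensor at every in-mask voxel", {
  m <- make_tendon_mask(list(n_slices = 6, semi_axis_ml = 3, semi_axis_ap = 2,
                             curve_mm = 0),
                        grid_spec(c(14, 12, 6), c(1, 1, 1)))
  # isotropic tissue: D = 1e-3 * I everywhere in the mask
  iso <- make_tensor_field(m, tissue_params(1e-3, 1e-3, 1e-3))
  rows <- matrix(iso$tensors, ncol = 6)[which(m$voxels), , drop = FALSE]
  expect_equal(max(abs(sweep(rows, 2, c(1e-3, 1e-3, 1e-3, 0, 0, 0)))), 0,
               tolerance = 1e-18)

  # axis = +z on a straight cylinder: diagonal tensor (0.4, 0.5, 1.5)e-3 on
  # the (x, y, z) diagonal
  tf <- make_tensor_field(m, tissue_params(1.5e-3, 0.5e-3, 0.4e-3))
  rows <- matrix(tf$tensors, ncol = 6)[which(m$voxels), , drop = FALSE]
  expect_equal(unname(rows[1, 1:3]), c(0.5e-3, 0.4e-3, 1.5e-3), tolerance = 1e-9)
  expect_equal(max(abs(rows[, 4:6])), 0, tolerance = 1e-12)

  # pathology amplitude 0 leaves the field bit-identical
  path0 <- make_tensor_field(m, tissue_params(1.5e-3, 0.5e-3, 0.4e-3),
                             pathology_map = array(0, dim(m$voxels)))
  expect_identical(path0$tensors, tf$tensors)

  # positive amplitude raises MD and lowers FA, monotonically
  stats_at <- function(a) {
    f <- make_tensor_field(m, tissue_params(1.5e-3, 0.5e-3, 0.4e-3),
                           pathology_map = array(a, dim(m$voxels)))
    sm <- scalar_maps(f)
    c(md = mean(sm$md[m$voxels]), fa = mean(sm$fa[m$voxels]))
  }
  s <- vapply(c(0, 0.3, 0.6, 1), stats_at, numeric(2))
  expect_true(all(diff(s["md", ]) > 0))
  expect_true(all(diff(s["fa", ]) < 0))

  # scaling that destroys positive-definiteness is rejected
  expect_error(make_tensor_field(m, tissue_params(1.5e-3, 0.5e-3, 0.4e-3),
                                 pathology_map = array(-2.5, dim(m$voxels))),
               "non-positive")
})

test_that("simulated DWI follows the single-tensor signal model", {
  m <- make_tendon_mask(list(n_slices = 5, semi_axis_ml = 3, semi_axis_ap = 3,
                             curve_mm = 0),
                        grid_spec(c(14, 14, 5), c(1, 1, 1)))
  tf <- make_tensor_field(m, tissue_params(1.5e-3, 0.5e-3, 0.4e-3))
  p <- dwi_protocol(c(0, 800), rbind(c(0, 0, 0), c(0, 0, 1)))
  d <- simulate_dwi(tf, p, snr = Inf)
  idx <- which(m$voxels)
  b0 <- d$data[, , , 1][idx]
  expect_equal(b0, rep(1, length(idx)))                # b = 0 noise-free -> S0
  s <- d$data[, , , 2][idx]
  expect_equal(s, rep(exp(-800 * 1.5e-3), length(idx)), tolerance = 1e-12)

  # determinism under a fixed seed, and RNG-state preservation
  rng_before <- .Random.seed
  a <- simulate_dwi(tf, dti_protocol(), snr = 20, seed = 77)
  b <- simulate_dwi(tf, dti_protocol(), snr = 20, seed = 77)
  expect_identical(a$data, b$data)
  expect_identical(rng_before, .Random.seed)

  expect_error(simulate_dwi(tf, p, snr = 0), "snr")
  expect_error(simulate_dwi(tf, p, s0_map = array(1, c(2, 2, 2))), "mismatch")
})

test_that("Rician noise floor: noisy b=0 mean is at least the true S0", {
  n <- 12000
  tf <- field_from_tensors(replicate(n, diag(3) * 0.7e-3, simplify = FALSE))
  p <- dwi_protocol(0, matrix(0, 1, 3))
  d <- simulate_dwi(tf, p, snr = 5, seed = 4)
  expect_gte(mean(d$data), 1)
})

test_that("rater perturbation behaves like a smooth boundary jitter", {
  m <- cylinder_mask(radius_vox = 8, n_slices = 10, spacing = c(0.5, 0.5, 0.5),
                     dims = c(28, 28, 10))
  # amplitude 0 is the identity
  expect_identical(perturb_rater(m, 0), m)

  # Dice overlap decreases (on average) with amplitude; volume change stays
  # bounded for sub-voxel amplitudes on a large cylinder
  amps <- c(0.2, 0.6, 1.2)
  mean_dice <- vapply(amps, function(a) {
    mean(vapply(1:20, function(s)
      dice_overlap(m$voxels, perturb_rater(m, a, seed = s)$voxels), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_dice) < 0))
  vol_change <- vapply(1:20, function(s)
    abs(mask_volume(perturb_rater(m, 0.4, seed = s)) - mask_volume(m)) /
      mask_volume(m), numeric(1))
  expect_lt(max(vol_change), 0.2)

  # output is a single connected component
  pm <- perturb_rater(m, 1.5, seed = 9)
  lab <- connected_components(pm$voxels)
  expect_equal(max(lab), 1L)

  expect_error(perturb_rater(m, -1), "amplitude")
})

test_that("signed distance re-thresholds to the original mask", {
  m <- random_test_mask(101)
  sdf <- signed_distance(m$voxels, m$voxel_dims)
  expect_identical(sdf > 0, m$voxels)
  # distances are exact and respect anisotropic spacing
  v <- array(FALSE, c(9, 9, 3)); v[5, 5, 2] <- TRUE
  d2 <- signed_distance(v, c(1, 2, 1))
  expect_equal(d2[5, 5, 2], 1)       # nearest background: one 1 mm step
  expect_equal(d2[5, 4, 2], -2)      # one step along axis 2 costs 2 mm
  expect_equal(d2[4, 5, 2], -1)
  expect_equal(d2[3, 4, 2], -sqrt(2^2 + 2^2))
})
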