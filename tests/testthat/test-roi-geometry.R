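test_that("longest diameter matches its stated examples", {
  # 1 x 30 voxel row at 0.5 mm: length (30-1)*0.5 between extreme centres
  sl <- matrix(FALSE, 34, 5); sl[3:32, 3] <- TRUE
  dia <- longest_diameter(sl, c(0.5, 0.5))
  expect_equal(dia$length, 14.5)
  expect_equal(abs(dia$axis), c(1, 0))

  # digital disk of radius 10: diameter within one voxel of 2 * radius
  sl <- outer(seq_len(25) - 13, seq_len(25) - 13, function(x, y) x^2 + y^2 <= 100)
  dia <- longest_diameter(sl, c(1, 1))
  expect_lt(abs(dia$length - 20), 1)

  # single voxel: zero length, axis defaults to the first in-plane axis
  sl <- matrix(FALSE, 5, 5); sl[3, 3] <- TRUE
  dia <- longest_diameter(sl, c(1, 1))
  expect_equal(dia$length, 0)
  expect_equal(dia$axis, c(1, 0))

  expect_error(longest_diameter(matrix(FALSE, 4, 4)), "empty")
})

test_that("longest diameter equals the all-pairs brute-force oracle", {
  for (seed in 1:25) {
    m <- random_test_mask(seed)
    sl <- m$voxels[, , 1]
    got <- longest_diameter(sl, m$voxel_dims[1:2], m$origin[1:2])
    want <- oracle_longest_diameter(sl, m$voxel_dims[1:2], m$origin[1:2])
    expect_equal(got$length, want$length, tolerance = 1e-12)
    expect_equal(got$endpoints, want$endpoints, tolerance = 1e-12)
  }
})

test_that("trisection slices an axis-aligned rectangle into exact thirds", {
  v <- array(FALSE, c(34, 10, 3)); v[3:32, 3:8, ] <- TRUE
  m <- tendon_mask(v, c(0.5, 0.5, 3), limb_side = "left", medial_direction = 1L)
  tri <- trisect_mask(m)
  expect_equal(sum(tri$masks$medial), 10 * 6 * 3)
  expect_equal(sum(tri$masks$central), 10 * 6 * 3)
  expect_equal(sum(tri$masks$lateral), 10 * 6 * 3)
  # medial block sits on the positive side of axis 1 (medial_direction = +1)
  expect_true(all(which(tri$masks$medial, arr.ind = TRUE)[, 1] >= 23))

  # laterality metadata is mandatory
  m_na <- tendon_mask(v, c(0.5, 0.5, 3))
  expect_error(trisect_mask(m_na), "limb_side")
})

test_that("trisection of rotated and L-shaped slices matches the projection oracle", {
  for (seed in 26:55) {
    m <- random_test_mask(seed)
    tri <- trisect_mask(m)
    lab <- region_labels_of(tri)
    mvec <- c(1, 0)
    for (k in seq_len(dim(m$voxels)[3])) {
      sl <- m$voxels[, , k]
      if (!any(sl)) next
      want <- oracle_classify_slice(sl, m$voxel_dims[1:2], m$origin[1:2], mvec)
      got <- lab[, , k][which(sl)]
      expect_identical(got, want)
    }
    # rotated slices still give balanced thirds (within one voxel row of the
    # in-plane width)
    counts <- vapply(c("medial", "central", "lateral"),
                     function(r) sum(tri$masks[[r]]), numeric(1))
    expect_true(all(counts > 0) || sum(m$voxels) < 30)
  }
})

test_that("bisection obeys the odd-slice duplication rule", {
  mk <- function(n) cylinder_mask(radius_vox = 2, n_slices = n, dims = c(9, 9, n))
  b7 <- bisect_mask(mk(7))
  prox_slices <- which(apply(b7$masks$proximal, 3, any))
  dist_slices <- which(apply(b7$masks$distal, 3, any))
  expect_equal(prox_slices, 1:4)
  expect_equal(dist_slices, 4:7)

  b6 <- bisect_mask(mk(6))
  expect_equal(which(apply(b6$masks$proximal, 3, any)), 1:3)
  expect_equal(which(apply(b6$masks$distal, 3, any)), 4:6)
  expect_false(any(b6$masks$proximal & b6$masks$distal))

  v <- array(FALSE, c(5, 5, 1)); v[2:4, 2:4, 1] <- TRUE
  b1 <- bisect_mask(tendon_mask(v, c(1, 1, 1)))
  expect_identical(b1$masks$proximal, v)
  expect_identical(b1$masks$distal, v)

  # proximal_end = "last" reverses the slice ordering
  m7 <- mk(7); m7$proximal_end <- "last"
  b7r <- bisect_mask(m7)
  expect_equal(which(apply(b7r$masks$proximal, 3, any)), 4:7)
})

test_that("calcification exclusion is plain set arithmetic", {
  m <- cylinder_mask(radius_vox = 4, n_slices = 4, dims = c(13, 13, 4))
  empty <- array(FALSE, dim(m$voxels))
  expect_identical(exclude_calcifications(m, empty)$voxels, m$voxels)

  calc <- array(FALSE, dim(m$voxels)); calc[6:7, 6:7, 2] <- TRUE
  n_calc <- sum(calc & m$voxels)
  out <- exclude_calcifications(m, calc)
  expect_equal(sum(out$voxels), sum(m$voxels) - n_calc)

  # calcification covering the whole tendon leaves an empty mask, and
  # downstream region operations refuse it
  all_of_it <- array(TRUE, dim(m$voxels))
  gone <- exclude_calcifications(m, all_of_it)
  expect_equal(sum(gone$voxels), 0)
  expect_error(trisect_mask(gone), "empty")

  expect_error(exclude_calcifications(m, array(FALSE, c(2, 2, 2))), "grid")
})

test_that("mask volume is voxel count times voxel volume", {
  v <- array(FALSE, c(10, 10, 2)); v[which(array(seq_len(200), c(10, 10, 2)) <= 100)] <- TRUE
  expect_equal(mask_volume(tendon_mask(v, c(0.5, 0.5, 0.5))), 12.5)
  v2 <- array(FALSE, c(5, 2, 1)); v2[] <- TRUE
  expect_equal(mask_volume(tendon_mask(v2, c(1.4, 1.4, 3.0))), 58.8)
  expect_equal(mask_volume(tendon_mask(array(FALSE, c(3, 3, 3)), c(1, 1, 1))), 0)
  expect_equal(mask_volume(tendon_mask(v2, c(1.4, 1.4, 3.0)), "cm3"), 0.0588)
})

test_that("occupancy downsampling matches sub-voxel counting", {
  # integer 2x2x2 ratio: the counting oracle is exact
  set.seed(7)
  for (r in 1:20) {
    v <- array(runif(16 * 12 * 6) < 0.45, c(16, 12, 6))
    m <- tendon_mask(v, c(1, 1, 1))
    tgt <- grid_spec(c(8, 6, 3), c(2, 2, 2))
    occ <- mask_occupancy(m, tgt)
    want <- oracle_occupancy_integer(v, c(1, 1, 1), c(8, 6, 3), c(2, 2, 2))
    expect_equal(occ, want, tolerance = 1e-12)
    ds <- downsample_mask(m, tgt, threshold = 0.5)
    expect_identical(ds$voxels, want >= 0.5 - 1e-9)
  }

  # exact tie at the threshold is included (>= rule)
  v <- array(FALSE, c(2, 2, 2)); v[1, , ] <- TRUE   # covers half the target voxel
  m <- tendon_mask(v, c(1, 1, 1))
  ds <- downsample_mask(m, grid_spec(c(1, 1, 1), c(2, 2, 2)), threshold = 0.5)
  expect_true(ds$voxels[1, 1, 1])

  # a high-res block exactly filling one target voxel is included
  v <- array(TRUE, c(2, 2, 2))
  ds <- downsample_mask(tendon_mask(v, c(1, 1, 1)), grid_spec(c(1, 1, 1), c(2, 2, 2)))
  expect_true(ds$voxels[1, 1, 1])

  # non-integer ratio (anatomical 0.5 mm -> DTI 1.4/3.0 mm): occupancy equals
  # a fine sample-point estimate
  m <- cylinder_mask(radius_vox = 8, n_slices = 12, spacing = c(0.5, 0.5, 0.5),
                     dims = c(24, 24, 12))
  tgt <- grid_spec(c(9, 9, 2), c(1.4, 1.4, 3.0))
  occ <- mask_occupancy(m, tgt)
  ns <- 11
  for (probe in list(c(3, 4, 1), c(5, 5, 2), c(2, 7, 1))) {
    xs <- (probe[1] - 1) * 1.4 + (seq_len(ns) - 0.5) / ns * 1.4
    ys <- (probe[2] - 1) * 1.4 + (seq_len(ns) - 0.5) / ns * 1.4
    zs <- (probe[3] - 1) * 3.0 + (seq_len(ns) - 0.5) / ns * 3.0
    g <- expand.grid(x = xs, y = ys, z = zs)
    i <- pmin(pmax(ceiling(g$x / 0.5), 1), 24)
    j <- pmin(pmax(ceiling(g$y / 0.5), 1), 24)
    k <- pmin(pmax(ceiling(g$z / 0.5), 1), 12)
    est <- mean(m$voxels[cbind(i, j, k)])
    expect_equal(occ[probe[1], probe[2], probe[3]], est, tolerance = 0.06)
  }

  # disjoint grids are rejected
  far <- grid_spec(c(4, 4, 4), c(1, 1, 1), origin = c(100, 0, 0))
  expect_error(downsample_mask(m, far), "overlap")
})

test_that("in-plane erosion equals the brute-force neighbour oracle", {
  # 3x3 block in one slice erodes to its centre
  v <- array(FALSE, c(5, 5, 1)); v[2:4, 2:4, 1] <- TRUE
  er <- erode_boundary(tendon_mask(v, c(1, 1, 1)))
  expect_equal(which(er$voxels), which(array(seq_len(25), c(5, 5, 1)) == 13))

  # 1-voxel-wide line erodes to empty
  v <- array(FALSE, c(6, 6, 1)); v[2:5, 3, 1] <- TRUE
  er <- erode_boundary(tendon_mask(v, c(1, 1, 1)))
  expect_equal(sum(er$voxels), 0)

  for (seed in 56:75) {
    m <- random_test_mask(seed)
    expect_identical(erode_boundary(m)$voxels, oracle_erode(m$voxels))
  }
})

has_tied_diameter <- function(m) {
  # masks with several equally long diameters: the lexicographic tie-break
  # is not mirror-equivariant, so the swap property only holds for unique
  # diameters
  any(vapply(seq_len(dim(m$voxels)[3]), function(k) {
    sl <- m$voxels[, , k]
    if (!any(sl)) return(FALSE)
    dia <- oracle_longest_diameter(sl, m$voxel_dims[1:2], m$origin[1:2])
    comp <- largest_component(sl)
    coords <- which(comp, arr.ind = TRUE)
    pts <- cbind((coords[, 1] - 0.5) * m$voxel_dims[1],
                 (coords[, 2] - 0.5) * m$voxel_dims[2])
    D <- as.matrix(dist(pts))
    sum(D >= dia$length - 1e-9 & upper.tri(D)) > 1
  }, logical(1)))
}

test_that("mirror reflection with flipped limb side swaps medial and lateral", {
  n_checked <- 0
  for (seed in 76:105) {
    m <- random_test_mask(seed)             # left limb, medial along +axis1
    if (has_tied_diameter(m)) next
    n_checked <- n_checked + 1
    tri <- trisect_mask(m)
    refl <- m$voxels[rev(seq_len(dim(m$voxels)[1])), , , drop = FALSE]
    m2 <- tendon_mask(refl, m$voxel_dims, m$origin, limb_side = "right",
                      medial_direction = -1L)
    tri2 <- trisect_mask(m2)
    flip <- function(a) a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
    expect_identical(tri2$masks$medial, flip(tri$masks$medial))
    expect_identical(tri2$masks$lateral, flip(tri$masks$lateral))
    expect_identical(tri2$masks$central, flip(tri$masks$central))
  }
  expect_gte(n_checked, 10)
})

test_that("connected-component labelling agrees with EBImage in 2D", {
  suppressPackageStartupMessages(requireNamespace("EBImage"))
  set.seed(3)
  for (r in 1:10) {
    sl <- matrix(runif(30 * 24) < 0.4, 30, 24)
    ours <- connected_components(sl)
    ref <- EBImage::bwlabel(EBImage::Image(sl * 1))
    # same partition: component count and co-membership must agree
    expect_equal(max(ours), max(ref))
    key_ours <- as.vector(ours)[sl]
    key_ref <- as.vector(ref@.Data)[sl]
    expect_equal(length(unique(paste(key_ours, key_ref))), max(ours))
  }
})
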