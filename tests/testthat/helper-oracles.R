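# Independent brute-force oracles and procedural fixtures. These deliberately
# re-derive results with plain loops so they share no code path with the
# package implementation they check.

# --- fixtures -----------------------------------------------------------

# straight cylinder mask
cylinder_mask <- function(radius_vox = 3, n_slices = 20, dims = NULL,
                          spacing = c(1, 1, 1), limb_side = "left",
                          medial_direction = 1L) {
  if (is.null(dims)) dims <- c(2 * radius_vox + 5, 2 * radius_vox + 5, n_slices)
  cx <- (dims[1] + 1) / 2; cy <- (dims[2] + 1) / 2
  sl <- outer(seq_len(dims[1]) - cx, seq_len(dims[2]) - cy,
              function(x, y) x^2 + y^2 <= radius_vox^2)
  v <- array(FALSE, dims)
  for (k in seq_len(n_slices)) v[, , k] <- sl
  tendon_mask(v, spacing, limb_side = limb_side,
              medial_direction = medial_direction)
}

# random connected test masks: cylinders, bent tubes, L-shaped prisms
random_test_mask <- function(seed) {
  set.seed(seed)
  kind <- sample(c("cylinder", "bent", "L"), 1L)
  n_sl <- sample(3:6, 1L)
  dims <- c(26L, 20L, n_sl)
  v <- array(FALSE, dims)
  if (kind == "L") {
    arm1 <- sample(8:16, 1L); arm2 <- sample(6:12, 1L); th <- sample(3:6, 1L)
    sl <- matrix(FALSE, dims[1], dims[2])
    sl[3:(2 + arm1), 3:(2 + th)] <- TRUE
    sl[3:(2 + th), 3:(2 + arm2)] <- TRUE
    for (k in seq_len(n_sl)) v[, , k] <- sl
  } else {
    a <- runif(1, 3, 8); b <- runif(1, 2, 6)
    bow <- if (kind == "bent") runif(1, 0, 4) else 0
    th <- runif(1, 0, pi)  # in-plane rotation of the ellipse
    for (k in seq_len(n_sl)) {
      cx <- dims[1] / 2 + bow * sin(pi * (k - 1) / max(n_sl - 1, 1))
      cy <- dims[2] / 2
      xs <- seq_len(dims[1]) - 0.5 - cx
      ys <- seq_len(dims[2]) - 0.5 - cy
      g <- expand.grid(x = xs, y = ys)
      xr <- g$x * cos(th) + g$y * sin(th)
      yr <- -g$x * sin(th) + g$y * cos(th)
      v[, , k] <- matrix((xr / a)^2 + (yr / b)^2 <= 1, dims[1], dims[2])
    }
  }
  # ensure non-empty slices; fall back to a small disk if rotation clipped it
  for (k in seq_len(n_sl)) if (!any(v[, , k])) v[12:15, 9:12, k] <- TRUE
  tendon_mask(v, c(1, 1, 2), limb_side = "left", medial_direction = 1L)
}

# random protocol-consistent positive-definite tensor (units mm^2/s)
random_pd_tensor <- function() {
  lam <- sort(runif(3, 0.3e-3, 2.2e-3), decreasing = TRUE)
  A <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  D <- Q %*% diag(lam) %*% t(Q)
  (D + t(D)) / 2
}

# tensor field holding given 3x3 tensors at voxels (n x 1 x 1 grid)
field_from_tensors <- function(Ds, s0 = 1) {
  n <- length(Ds)
  tn <- t(vapply(Ds, function(D) c(D[1, 1], D[2, 2], D[3, 3],
                                   D[1, 2], D[1, 3], D[2, 3]), numeric(6)))
  tensor_field(array(tn, c(n, 1, 1, 6)), array(s0, c(n, 1, 1)),
               array(TRUE, c(n, 1, 1)), grid_spec(c(n, 1, 1), c(1, 1, 1)))
}

# --- geometry oracles ---------------------------------------------------

# longest chord between boundary-voxel centres: all pairs, same tie rule
oracle_longest_diameter <- function(slice, spacing = c(1, 1), origin = c(0, 0)) {
  comp <- largest_component(slice)
  d <- dim(comp)
  bnd <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!comp[i, j]) next
    interior <- i > 1 && i < d[1] && j > 1 && j < d[2] &&
      comp[i - 1, j] && comp[i + 1, j] && comp[i, j - 1] && comp[i, j + 1]
    if (!interior) bnd <- rbind(bnd, c(i, j))
  }
  pts <- cbind(origin[1] + (bnd[, 1] - 0.5) * spacing[1],
               origin[2] + (bnd[, 2] - 0.5) * spacing[2])
  best <- NULL; bl <- -1
  for (i in seq_len(nrow(pts))) for (j in seq_len(nrow(pts))) {
    if (j <= i) next
    len <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    p <- pts[i, ]; q <- pts[j, ]
    if (p[1] > q[1] || (p[1] == q[1] && p[2] > q[2])) { tmp <- p; p <- q; q <- tmp }
    if (len > bl + 1e-9 * max(1, len)) { bl <- len; best <- rbind(p, q) }
    else if (abs(len - bl) <= 1e-9 * max(1, len)) {
      # lexicographic tie-break on (p1x, p1y, p2x, p2y)
      key_new <- c(p[1], p[2], q[1], q[2])
      key_old <- c(best[1, 1], best[1, 2], best[2, 1], best[2, 2])
      for (t in 1:4) {
        if (key_new[t] < key_old[t]) { best <- rbind(p, q); break }
        if (key_new[t] > key_old[t]) break
      }
    }
  }
  if (bl < 0) return(list(endpoints = rbind(pts[1, ], pts[1, ]), axis = c(1, 0), length = 0))
  axis <- if (bl > 0) (best[2, ] - best[1, ]) / bl else c(1, 0)
  list(endpoints = unname(best), axis = axis, length = bl)
}

# per-voxel projection classification of one slice into thirds
oracle_classify_slice <- function(slice, spacing, origin, mvec) {
  dia <- oracle_longest_diameter(slice, spacing, origin)
  coords <- which(slice, arr.ind = TRUE)
  n <- nrow(coords)
  L <- dia$length
  if (L < 2 * mean(spacing)) return(rep("central", n))
  u <- dia$axis; A <- dia$endpoints[1, ]
  du <- sum(u * mvec)
  if (du < -1e-9) { u <- -u; A <- dia$endpoints[2, ] }
  else if (abs(du) <= 1e-9 && (u[1] < 0 || (u[1] == 0 && u[2] < 0))) {
    u <- -u; A <- dia$endpoints[2, ]
  }
  out <- character(n)
  eps <- 1e-9 * max(1, L)
  for (r in seq_len(n)) {
    p <- c(origin[1] + (coords[r, 1] - 0.5) * spacing[1],
           origin[2] + (coords[r, 2] - 0.5) * spacing[2])
    t_ <- sum((p - A) * u)
    out[r] <- if (t_ < L / 3 - eps) "lateral" else if (t_ > 2 * L / 3 + eps) "medial" else "central"
  }
  out
}

# label array of the package trisection, for comparison with the oracle
region_labels_of <- function(rs) {
  lab <- array("", dim(rs$masks$whole))
  lab[rs$masks$medial] <- "medial"
  lab[rs$masks$central] <- "central"
  lab[rs$masks$lateral] <- "lateral"
  lab
}

# plain-loop 4-connected in-plane erosion
oracle_erode <- function(v) {
  d <- dim(v)
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!v[i, j, k]) next
    ok <- i > 1 && i < d[1] && j > 1 && j < d[2] &&
      v[i - 1, j, k] && v[i + 1, j, k] && v[i, j - 1, k] && v[i, j + 1, k]
    out[i, j, k] <- ok
  }
  out
}

# sub-voxel counting occupancy oracle: target voxel subdivided into the
# integer number of source voxels it covers (requires integer spacing ratio
# and aligned origins)
oracle_occupancy_integer <- function(v, src_spacing, tgt_dim, ratio) {
  occ <- array(0, tgt_dim)
  d <- dim(v)
  for (a in seq_len(tgt_dim[1])) for (b in seq_len(tgt_dim[2])) for (c_ in seq_len(tgt_dim[3])) {
    xs <- ((a - 1) * ratio[1] + 1):min(a * ratio[1], d[1])
    ys <- ((b - 1) * ratio[2] + 1):min(b * ratio[2], d[2])
    zs <- ((c_ - 1) * ratio[3] + 1):min(c_ * ratio[3], d[3])
    occ[a, b, c_] <- sum(v[xs, ys, zs]) / prod(ratio)
  }
  occ
}

# --- statistics oracles -------------------------------------------------

# two-way mean-squares consistency ICC on balanced two-rating data
oracle_anova_icc <- function(tab) {
  aovf <- stats::anova(stats::lm(value ~ factor(participant) + factor(rating),
                                 data = tab))
  msb <- aovf["factor(participant)", "Mean Sq"]
  mse <- aovf["Residuals", "Mean Sq"]
  max((msb - mse) / (msb + mse), 0)
}

# balanced two-rating table with known variance components
balanced_icc_table <- function(n, s2p, s2r, rating_offset = 0.3) {
  u <- rnorm(n, 0, sqrt(s2p))
  data.frame(participant = rep(sprintf("S%03d", seq_len(n)), each = 2),
             rating = rep(c("r1", "r2"), n),
             value = rep(u, each = 2) + rep(c(0, rating_offset), n) +
               rnorm(2 * n, 0, sqrt(s2r)))
}

# retest-factor subset of a metric-level cohort table, one stratum
retest_stratum <- function(mt, limb = "contralateral", region = "whole",
                           metric = "md") {
  sub <- mt[mt$limb == limb & mt$region == region & mt$metric == metric &
              mt$rater == 1, , drop = FALSE]
  sub$rating <- paste0("session", sub$session)
  sub
}
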