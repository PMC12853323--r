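.limb_classes <- c("healthy", "tendinopathy", "BPTB")

# base tendon tissue per limb class: pathological tendons are more
# diffusive and less anisotropic than healthy tissue
.class_tissue <- function(class) {
  lam0 <- c(1.05e-3, 0.55e-3, 0.48e-3)
  lam <- switch(class,
                healthy = lam0,
                tendinopathy = 1.2 * .mix_iso(lam0, 0.25),
                BPTB = 1.3 * .mix_iso(lam0, 0.30),
                stop("unknown limb class: ", class))
  tissue_params(lam[1L], lam[2L], lam[3L])
}

# pull eigenvalues toward their mean (0 <= w < 1 lowers anisotropy;
# small w < 0 raises it)
.mix_iso <- function(lam, w) {
  md <- mean(lam)
  (1 - w) * lam + w * md
}

.metric_names <- c("lambda1", "lambda2", "lambda3", "md", "fa", "volume")

# grand means per metric for one limb class (diffusivities in 1e-3 mm^2/s,
# FA unitless, volume in cm^3)
.class_grand_means <- function(class) {
  ts <- .class_tissue(class)
  inv <- tensor_invariants(c(ts$lambda1, ts$lambda2, ts$lambda3))
  c(lambda1 = inv$lambda[1L] * 1e3, lambda2 = inv$lambda[2L] * 1e3,
    lambda3 = inv$lambda[3L] * 1e3, md = inv$md * 1e3, fa = inv$fa,
    volume = if (class == "healthy") 1.2 else 1.5)
}

.expand_by_class <- function(x, what) {
  if (length(x) == 1L && is.null(names(x))) x <- stats::setNames(rep(x, 3L), .limb_classes)
  .assert(all(.limb_classes %in% names(x)),
          sprintf("%s must be named with classes %s (or be a single number)",
                  what, paste(.limb_classes, collapse = ", ")))
  x[.limb_classes]
}

#' Specification of a synthetic reliability cohort
#'
#' Describes the study design the phantom cohort emulates: `n_subjects`
#' participants, each contributing a pathological limb (tendinopathy or
#' bone-patellar-tendon-bone graft) and a healthy contralateral limb; two
#' scan sessions; two raters segmenting session 1 and rater 1 segmenting
#' session 2. The requested test-retest ICC per limb class is realised
#' exactly (in expectation) by the metric-level generator and approximately
#' by the image-level generator; see [simulate_cohort()].
#'
#' @param n_subjects number of participants (default 10).
#' @param limb_types pathological-limb class per subject
#'   (`"tendinopathy"` or `"BPTB"`); default half and half.
#' @param true_icc_interrater target inter-rater consistency ICC, scalar or
#'   named per class; must be >= `true_icc_retest` classwise.
#' @param true_icc_retest target test-retest consistency ICC in `(0, 1]`,
#'   scalar or named per class.
#' @param between_subject_cv between-subject coefficient of variation of
#'   the diffusivities (log-normal scale SD).
#' @param fa_between_sd between-subject SD of the isotropy-mixing weight
#'   that drives FA variation.
#' @param rater_jitter_mm segmentation-jitter amplitude for simulated
#'   raters, mm (image level only).
#' @param snr b = 0 signal-to-noise ratio of the simulated DWI (`Inf` for
#'   noise-free).
#' @param seed integer RNG seed.
#' @param shape_params tendon shape defaults passed to [make_tendon_mask()].
#' @param anat_grid,dti_grid grids of the anatomical masks (0.5 mm
#'   isotropic) and the DTI acquisition (1.4 x 1.4 x 3.0 mm).
#' @param protocol a [dwi_protocol()]; default 30 directions at
#'   b = 800 s/mm^2 with 4 b = 0 volumes.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = 10,
                        limb_types = rep(c("tendinopathy", "BPTB"),
                                         length.out = n_subjects),
                        true_icc_interrater = 0.95,
                        true_icc_retest = c(healthy = 0.80,
                                            tendinopathy = 0.35, BPTB = 0.35),
                        between_subject_cv = 0.08,
                        fa_between_sd = 0.08,
                        rater_jitter_mm = 0.5,
                        snr = 30,
                        seed = 1L,
                        shape_params = list(),
                        anat_grid = grid_spec(c(48, 32, 25), c(0.5, 0.5, 0.5)),
                        dti_grid = grid_spec(c(18, 12, 5), c(1.4, 1.4, 3.0)),
                        protocol = dti_protocol()) {
  .assert(n_subjects >= 1, "n_subjects must be >= 1")
  .assert(length(limb_types) == n_subjects &&
            all(limb_types %in% c("tendinopathy", "BPTB")),
          "limb_types must give tendinopathy or BPTB per subject")
  icc_r <- .expand_by_class(true_icc_interrater, "true_icc_interrater")
  icc_t <- .expand_by_class(true_icc_retest, "true_icc_retest")
  .assert(all(icc_t > 0 & icc_t <= 1) && all(icc_r > 0 & icc_r <= 1),
          "true ICCs must lie in (0, 1]")
  .assert(all(icc_r >= icc_t),
          "true_icc_interrater must be >= true_icc_retest per class (raters view the same scan)")
  .assert(is.infinite(snr) || snr > 0, "snr must be > 0")
  .assert(rater_jitter_mm >= 0, "rater_jitter_mm must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects), limb_types = limb_types,
                 true_icc_interrater = icc_r, true_icc_retest = icc_t,
                 between_subject_cv = between_subject_cv,
                 fa_between_sd = fa_between_sd,
                 rater_jitter_mm = rater_jitter_mm, snr = snr,
                 seed = as.integer(seed), shape_params = shape_params,
                 anat_grid = anat_grid, dti_grid = dti_grid,
                 protocol = protocol),
            class = "cohort_spec")
}

# variance decomposition realising the requested consistency ICCs:
# value_{i,s,r} = mu + u_i + e_{is} + eps_{isr},
#   retest ICC (rater-1 values) : var(u) / (var(u) + var(e) + var(eps)) = rho_t
#   inter-rater ICC (session 1) : (var(u)+var(e)) / (var(u)+var(e)+var(eps)) = rho_r
.variance_split <- function(sigma2_u, rho_t, rho_r) {
  tot_extra <- sigma2_u * (1 - rho_t) / rho_t          # var(e) + var(eps)
  sigma2_eps <- (sigma2_u + tot_extra) * (1 - rho_r)
  sigma2_e <- tot_extra - sigma2_eps
  .assert(sigma2_e >= -1e-12, "infeasible ICC pair (interrater < retest)")
  c(e = max(sigma2_e, 0), eps = max(sigma2_eps, 0))
}

# metric-level between-subject SDs per class (same units as grand means)
.class_between_sd <- function(class, cv, fa_sd_w) {
  gm <- .class_grand_means(class)
  c(lambda1 = cv * gm[["lambda1"]], lambda2 = cv * gm[["lambda2"]],
    lambda3 = cv * gm[["lambda3"]], md = cv * gm[["md"]],
    fa = fa_sd_w * gm[["fa"]],       # mixing weight acts ~linearly on FA
    volume = 0.15 * gm[["volume"]])
}

.with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)
  force(expr)
}

# metric-level generator: draws region means directly from the variance
# model, bypassing image rendering; the analytic ground truth used for
# ICC-recovery calibration
.simulate_metric_table <- function(spec) {
  key <- expand.grid(metric = .metric_names, region = .region_names,
                     limb = c("pathological", "contralateral"),
                     subject = seq_len(spec$n_subjects),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key$participant <- sprintf("P%02d", key$subject)
  key$limb_type <- ifelse(key$limb == "pathological",
                          spec$limb_types[key$subject], "healthy")
  gm_tab <- vapply(.limb_classes, .class_grand_means, numeric(6L))
  sd_tab <- vapply(.limb_classes, .class_between_sd, numeric(6L),
                   cv = spec$between_subject_cv, fa_sd_w = spec$fa_between_sd)
  mi <- match(key$metric, .metric_names)
  ci <- match(key$limb_type, .limb_classes)
  mu <- gm_tab[cbind(mi, ci)]
  s2u <- sd_tab[cbind(mi, ci)]^2
  rho_t <- spec$true_icc_retest[key$limb_type]
  rho_r <- spec$true_icc_interrater[key$limb_type]
  tot_extra <- s2u * (1 - rho_t) / rho_t        # var(e) + var(eps)
  s2eps <- (s2u + tot_extra) * (1 - rho_r)
  s2e <- pmax(tot_extra - s2eps, 0)
  n <- nrow(key)
  u <- stats::rnorm(n, 0, sqrt(s2u))
  e1 <- stats::rnorm(n, 0, sqrt(s2e))
  e2 <- stats::rnorm(n, 0, sqrt(s2e))
  eps <- matrix(stats::rnorm(3L * n, 0, sqrt(rep(s2eps, 3L))), n, 3L)
  obs <- key[rep(seq_len(n), each = 3L), c("participant", "limb", "limb_type",
                                           "region", "metric")]
  obs$session <- rep(c(1L, 1L, 2L), n)
  obs$rater <- rep(c(1L, 2L, 1L), n)
  obs$value <- as.vector(rbind(mu + u + e1 + eps[, 1L],   # rater1 session1
                               mu + u + e1 + eps[, 2L],   # rater2 session1
                               mu + u + e2 + eps[, 3L]))  # rater1 session2
  obs$n_voxels <- NA_integer_
  obs$sd_within <- NA_real_
  rownames(obs) <- NULL
  obs
}

# image-level generator: masks, rater segmentations, tensor fields and DWI
.simulate_image_cohort <- function(spec) {
  iso_bg <- tissue_params(1.6e-3, 1.6e-3, 1.6e-3)
  limbs <- list()
  for (i in seq_len(spec$n_subjects)) {
    pid <- sprintf("P%02d", i)
    for (limb in c("pathological", "contralateral")) {
      class <- if (limb == "pathological") spec$limb_types[i] else "healthy"
      rho_t <- spec$true_icc_retest[[class]]
      base <- .class_tissue(class)
      lam0 <- c(base$lambda1, base$lambda2, base$lambda3)

      # subject geometry (volume variation between subjects)
      shp <- utils::modifyList(list(
        semi_axis_ml = 7.5 * exp(stats::rnorm(1, 0, 0.08)),
        semi_axis_ap = 4.0 * exp(stats::rnorm(1, 0, 0.08))),
        spec$shape_params)
      side <- if (limb == "pathological") "left" else "right"
      truth <- make_tendon_mask(shp, spec$anat_grid, limb_side = side,
                                medial_direction = if (side == "left") 1L else -1L)

      # tissue hierarchy: subject effect + session fluctuation scaled to the
      # requested retest ICC (exact on the log-diffusivity / mixing scales)
      sess_scale <- sqrt((1 - rho_t) / rho_t)
      b_i <- stats::rnorm(1, 0, spec$between_subject_cv)
      w_i <- stats::rnorm(1, 0, spec$fa_between_sd)
      e_is <- stats::rnorm(2, 0, spec$between_subject_cv * sess_scale)
      w_is <- stats::rnorm(2, 0, spec$fa_between_sd * sess_scale)
      tissue <- lapply(1:2, function(s) {
        lam <- .mix_iso(lam0 * exp(b_i + e_is[s]),
                        max(min(w_i + w_is[s], 0.9), -0.5))
        tissue_params(lam[1L], lam[2L], lam[3L])
      })

      # rater segmentations: raters 1 and 2 on the session-1 scan, rater 1
      # again on the session-2 scan
      rater_masks <- list(
        rater1_s1 = perturb_rater(truth, spec$rater_jitter_mm),
        rater2_s1 = perturb_rater(truth, spec$rater_jitter_mm),
        rater1_s2 = perturb_rater(truth, spec$rater_jitter_mm))

      occ <- mask_occupancy(truth, spec$dti_grid)
      mask_dti <- downsample_mask(truth, spec$dti_grid)
      dwi <- lapply(1:2, function(s) {
        field <- make_tensor_field(mask_dti, tissue[[s]],
                                   background_tissue = iso_bg, occupancy = occ)
        simulate_dwi(field, spec$protocol, snr = spec$snr)
      })
      limbs[[length(limbs) + 1L]] <- list(
        participant = pid, limb = limb, limb_type = class,
        truth_mask = truth, rater_masks = rater_masks,
        tissue = tissue, dwi = stats::setNames(dwi, c("s1", "s2")))
    }
  }
  limbs
}

#' Simulate a synthetic reliability cohort
#'
#' At `level = "image"` (default), generates per subject and limb a
#' high-resolution tendon mask, three simulated rater segmentations (two
#' raters on session 1, rater 1 on session 2), and per-session DWI volumes
#' on the DTI grid whose underlying tissue parameters carry a subject
#' random effect and a session fluctuation sized so that the induced
#' consistency ICC of region means approximates `true_icc_retest`.
#'
#' At `level = "metric"`, region-mean values are drawn directly from the
#' same participant/session/rater variance decomposition, for which the
#' requested ICCs hold exactly in expectation; this analytic mode is what
#' ICC-recovery calibration uses.
#'
#' All randomness is governed by `spec$seed`; identical specs give
#' bit-identical outputs, and the caller's RNG state is preserved.
#'
#' @param spec a [cohort_spec()].
#' @param level `"image"` or `"metric"`.
#' @return For `"image"`, a `cohort_dataset`: list with `spec` and `limbs`
#'   (one record per subject x limb holding `truth_mask`, `rater_masks`,
#'   per-session `tissue` and `dwi`). For `"metric"`, a long-format
#'   measurement data.frame (see [extract_region_stats()] plus `session`
#'   and `rater` columns).
#' @export
simulate_cohort <- function(spec, level = c("image", "metric")) {
  .assert(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  level <- match.arg(level)
  .with_preserved_rng(spec$seed, {
    if (level == "metric") {
      .simulate_metric_table(spec)
    } else {
      structure(list(spec = spec, limbs = .simulate_image_cohort(spec)),
                class = "cohort_dataset")
    }
  })
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d subjects x 2 limbs (%d limb records), seed %d\n",
              x$spec$n_subjects, length(x$limbs), x$spec$seed))
  invisible(x)
}
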