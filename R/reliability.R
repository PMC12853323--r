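#' Consistency ICC from a linear mixed model
#'
#' Fits, by REML, `value ~ rating + (1 | participant)` — the rating factor
#' (rater or session) as a fixed effect, participants as random intercepts —
#' and returns the consistency intraclass correlation
#' `ICC = sigma2_participant / (sigma2_participant + sigma2_residual)`.
#' Because the rating factor is fixed, its systematic offset does not enter
#' the denominator. Negative variance-component estimates cannot occur
#' under REML (they are truncated at the 0 boundary), so the ICC lies in
#' `[0, 1]`.
#'
#' Data in which every participant's ratings agree exactly (zero residual
#' variance after removing rating offsets) sit on a boundary the mixed
#' model cannot represent; they are detected and returned directly as
#' ICC = 1.
#'
#' @param table data.frame with columns `participant`, `rating` (2+ levels),
#'   `value`; additional columns are ignored. Unbalanced data are allowed.
#' @param extra_fixed optional character vector of additional fixed-effect
#'   column names (used by [pooled_icc_with_limbtype()]).
#' @return list with `icc`, `sigma2_participant`, `sigma2_residual`,
#'   `fixef` (fixed-effect estimates), `n_participants`, and `fit` (the
#'   lme4 fit, or `NULL` on the degenerate boundary).
#' @export
fit_icc_lmm <- function(table, extra_fixed = character(0)) {
  .assert(all(c("participant", "rating", "value") %in% names(table)),
          "table needs participant, rating and value columns")
  .assert(all(is.finite(table$value)), "non-finite values in table")
  .assert(nrow(table) >= 2L, "fewer than 2 ratings in total")
  tab <- table
  tab$participant <- factor(tab$participant)
  tab$rating <- factor(tab$rating)
  counts <- table(tab$participant)
  .assert(sum(counts >= 2L) >= 3L,
          "need at least 3 participants with at least 2 ratings each")

  rhs <- paste(c("rating", extra_fixed), collapse = " + ")
  # boundary: zero residual variance after removing participant/fixed means
  res <- stats::residuals(stats::lm(stats::as.formula(
    paste("value ~ participant +", rhs)), data = tab))
  scale2 <- stats::var(tab$value)
  if (scale2 > 0 && sum(res^2) <= 1e-12 * scale2 * nrow(tab)) {
    pm <- tapply(tab$value, tab$participant, mean)
    return(list(icc = 1, sigma2_participant = stats::var(as.numeric(pm)),
                sigma2_residual = 0,
                fixef = NULL, n_participants = nlevels(tab$participant), fit = NULL))
  }
  fml <- stats::as.formula(paste("value ~", rhs, "+ (1 | participant)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = tab, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))))
  vc <- lme4::VarCorr(fit)
  s2p <- max(as.numeric(vc$participant), 0)
  s2r <- attr(vc, "sc")^2
  list(icc = s2p / (s2p + s2r),
       sigma2_participant = s2p, sigma2_residual = s2r,
       fixef = lme4::fixef(fit), n_participants = nlevels(tab$participant),
       fit = fit)
}

# one bootstrap resample of participants (with replacement), ratings kept
.resample_participants <- function(table, ids) {
  take <- lapply(seq_along(ids), function(j) {
    sub <- table[table$participant == ids[j], , drop = FALSE]
    sub$participant <- sprintf("boot%03d", j)
    sub
  })
  do.call(rbind, take)
}

#' Participant bootstrap confidence interval for the ICC
#'
#' Participants are resampled with replacement (each keeping all their
#' ratings), the mixed-model ICC is refit per resample, and the percentile
#' 2.5/97.5 bounds over successful refits are returned. Balanced tables use
#' a fast response-refit path ([lme4::refit()]); resamples whose refit
#' fails are dropped and counted.
#'
#' @param table as in [fit_icc_lmm()].
#' @param n_boot number of resamples (default 1000).
#' @param seed optional integer seed; the global RNG state is restored.
#' @param extra_fixed passed to [fit_icc_lmm()].
#' @return list with `ci_low`, `ci_high`, `n_boot`, `n_failed`, and
#'   `warning` (`TRUE` when more than 20% of refits failed).
#' @export
bootstrap_ci <- function(table, n_boot = 1000, seed = NULL,
                         extra_fixed = character(0)) {
  .assert(n_boot >= 2, "n_boot must be >= 2")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  tab <- table
  tab$participant <- factor(tab$participant)
  tab$rating <- factor(tab$rating)
  ids <- levels(tab$participant)
  n <- length(ids)

  # fast path: balanced design (every participant has one row per rating);
  # resampled tables then share the model structure and only the response
  # changes, so lme4::refit applies
  k <- nlevels(tab$rating)
  balanced <- all(table(tab$participant, tab$rating) == 1L) && length(extra_fixed) == 0L
  V <- NULL
  if (balanced) {
    tab <- tab[order(tab$participant, tab$rating), , drop = FALSE]
    V <- matrix(tab$value, nrow = n, ncol = k, byrow = TRUE)
  }
  base <- fit_icc_lmm(tab, extra_fixed)
  icc_of_values <- function(vals_mat, idx) {
    # zero-residual boundary first (refit cannot represent it)
    centred <- sweep(vals_mat, 2L, colMeans(vals_mat))
    resid2 <- sum((centred - rowMeans(centred))^2)
    if (resid2 <= 1e-12 * max(stats::var(as.vector(vals_mat)), 1e-300) * length(vals_mat))
      return(1)
    if (!is.null(base$fit)) {
      ft <- tryCatch(suppressMessages(suppressWarnings(
        lme4::refit(base$fit, newresp = as.vector(t(vals_mat))))),
        error = function(e) NULL)
      if (!is.null(ft)) {
        vc <- lme4::VarCorr(ft)
        s2p <- max(as.numeric(vc$participant), 0)
        return(s2p / (s2p + attr(vc, "sc")^2))
      }
    }
    NA_real_
  }
  iccs <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (balanced) {
      iccs[b] <- icc_of_values(V[idx, , drop = FALSE], idx)
    } else {
      bt <- .resample_participants(tab, ids[idx])
      iccs[b] <- tryCatch(fit_icc_lmm(bt, extra_fixed)$icc, error = function(e) NA_real_)
    }
  }
  ok <- iccs[is.finite(iccs)]
  n_failed <- n_boot - length(ok)
  .assert(length(ok) >= 2, "bootstrap failed in nearly all resamples")
  q <- stats::quantile(ok, c(0.025, 0.975), names = FALSE)
  list(ci_low = q[1L], ci_high = q[2L], n_boot = n_boot, n_failed = n_failed,
       warning = n_failed > 0.2 * n_boot)
}

#' Standard error of measurement
#'
#' `SEM = SD * sqrt(1 - ICC)`: the absolute-units noise of a single rating,
#' where `SD` is the pooled standard deviation of all observations in the
#' stratum (across participants and ratings).
#'
#' @param sd_pooled pooled SD (>= 0).
#' @param icc intraclass correlation in `[0, 1]`.
#' @return numeric SEM.
#' @export
sem <- function(sd_pooled, icc) {
  .assert(is.finite(sd_pooled) && sd_pooled >= 0, "sd_pooled must be >= 0")
  .assert(is.finite(icc) && icc >= 0 && icc <= 1, "icc must be in [0, 1]")
  sd_pooled * sqrt(1 - icc)
}

#' Qualitative agreement class of an ICC
#'
#' Bins: below 0.50 poor, 0.50 to below 0.75 moderate, 0.75 to below 0.90
#' good, 0.90 and above excellent (bins are left-closed; 0.90 itself maps
#' to excellent).
#'
#' @param icc numeric vector of finite ICCs.
#' @return character vector of classes.
#' @export
classify_icc <- function(icc) {
  .assert(all(is.finite(icc)), "icc must be finite")
  cls <- rep("poor", length(icc))
  cls[icc >= 0.50] <- "moderate"
  cls[icc >= 0.75] <- "good"
  cls[icc >= 0.90] <- "excellent"
  cls
}

#' Full reliability battery for one stratum
#'
#' ICC point estimate from the mixed model, participant-bootstrap CI,
#' pooled SD, SEM and qualitative class.
#'
#' @param table as in [fit_icc_lmm()].
#' @param factor label recorded in the result (`"rater"` or `"session"`).
#' @param n_boot,seed passed to [bootstrap_ci()].
#' @param extra_fixed passed to [fit_icc_lmm()].
#' @return An `icc_result` list: `icc`, `ci_low`, `ci_high`, `n_boot`,
#'   `sem`, `sd_pooled`, `classification`, `n_subjects`, `factor`,
#'   `sigma2_participant`, `sigma2_residual`, `boot_warning`.
#' @export
icc_reliability <- function(table, factor = c("rater", "session"),
                            n_boot = 1000, seed = NULL,
                            extra_fixed = character(0)) {
  factor <- match.arg(factor)
  fit <- fit_icc_lmm(table, extra_fixed)
  ci <- bootstrap_ci(table, n_boot = n_boot, seed = seed, extra_fixed = extra_fixed)
  sd_pooled <- stats::sd(table$value)
  structure(list(icc = fit$icc, ci_low = ci$ci_low, ci_high = ci$ci_high,
                 n_boot = n_boot, sem = sem(sd_pooled, fit$icc),
                 sd_pooled = sd_pooled,
                 classification = classify_icc(fit$icc),
                 n_subjects = fit$n_participants, factor = factor,
                 sigma2_participant = fit$sigma2_participant,
                 sigma2_residual = fit$sigma2_residual,
                 boot_warning = ci$warning),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s) = %.3f (%.3f, %.3f) [%s], SEM = %.4g, n = %d, n_boot = %d\n",
              x$factor, x$icc, x$ci_low, x$ci_high, x$classification,
              x$sem, x$n_subjects, x$n_boot))
  invisible(x)
}

#' Pooled ICC across limb types
#'
#' Same mixed model with an additional fixed effect for limb type (healthy,
#' tendinopathy, BPTB), so that systematic limb-type offsets do not inflate
#' the between-participant variance. With a single limb type present it
#' falls back to the plain model with a warning.
#'
#' @param table as in [fit_icc_lmm()] plus a `limb_type` column.
#' @inheritParams icc_reliability
#' @return An `icc_result`.
#' @export
pooled_icc_with_limbtype <- function(table, factor = c("rater", "session"),
                                     n_boot = 1000, seed = NULL) {
  factor <- match.arg(factor)
  .assert("limb_type" %in% names(table), "table needs a limb_type column")
  if (length(unique(table$limb_type)) < 2L) {
    warning("single limb type present; fitting the plain model", call. = FALSE)
    return(icc_reliability(table, factor, n_boot, seed))
  }
  table$limb_type <- factor(table$limb_type)
  icc_reliability(table, factor, n_boot, seed, extra_fixed = "limb_type")
}

#' Outlier sensitivity: re-run the battery without one participant
#'
#' @param table as in [fit_icc_lmm()].
#' @param drop_participant_id participant to exclude.
#' @inheritParams icc_reliability
#' @return An `icc_result` for the reduced sample.
#' @export
outlier_sensitivity <- function(table, drop_participant_id,
                                factor = c("rater", "session"),
                                n_boot = 1000, seed = NULL) {
  factor <- match.arg(factor)
  .assert(drop_participant_id %in% table$participant,
          sprintf("participant '%s' not present", drop_participant_id))
  kept <- table[table$participant != drop_participant_id, , drop = FALSE]
  .assert(length(unique(kept$participant)) >= 3L,
          "dropping this participant leaves fewer than 3 participants")
  icc_reliability(kept, factor, n_boot, seed)
}

#' ICC sample size (Walter-Eliasziw-Donner approximation)
#'
#' Number of participants needed to distinguish an alternative ICC
#' `rho_alt` from a null `rho_null` with `k` ratings per participant:
#' `n = ceil(1 + 2k (z_{alpha/2} + z_beta)^2 / ((k - 1) (ln C0)^2))` with
#' `C0 = (1 + k rho0 / (1 - rho0)) / (1 + k rho1 / (1 - rho1))`.
#'
#' @param rho_null null ICC (`0 <= rho_null < rho_alt`).
#' @param rho_alt alternative ICC (`rho_alt < 1`).
#' @param k_ratings ratings per participant (>= 2).
#' @param alpha_two_sided two-sided type-I error rate.
#' @param power target power (1 - beta).
#' @return integer sample size.
#' @export
sample_size_icc <- function(rho_null = 0, rho_alt = 0.75, k_ratings = 2,
                            alpha_two_sided = 0.05, power = 0.80) {
  .assert(rho_null >= 0 && rho_null < rho_alt && rho_alt < 1,
          "need 0 <= rho_null < rho_alt < 1")
  .assert(k_ratings >= 2, "k_ratings must be >= 2")
  .assert(alpha_two_sided > 0 && alpha_two_sided < 1 && power > 0 && power < 1,
          "alpha and power must lie in (0, 1)")
  k <- k_ratings
  z <- stats::qnorm(1 - alpha_two_sided / 2) + stats::qnorm(power)
  c0 <- (1 + k * rho_null / (1 - rho_null)) / (1 + k * rho_alt / (1 - rho_alt))
  as.integer(ceiling(1 + 2 * k * z^2 / ((k - 1) * log(c0)^2)))
}
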