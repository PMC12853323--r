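test_that("perfect agreement with distinct participants gives ICC = 1", {
  set.seed(1)
  tab <- data.frame(participant = rep(1:6, each = 2), rating = rep(1:2, 6),
                    value = rep(rnorm(6), each = 2))
  fit <- fit_icc_lmm(tab)
  expect_equal(fit$icc, 1)
  expect_equal(fit$sigma2_residual, 0)
})

test_that("participant-independent noise estimates a near-zero ICC", {
  set.seed(2)
  tab <- data.frame(participant = rep(1:200, each = 2), rating = rep(1:2, 200),
                    value = rnorm(400))
  expect_lt(fit_icc_lmm(tab)$icc, 0.1)
})

test_that("known variance components are recovered (ICC 0.75 at n = 500)", {
  set.seed(3)
  tab <- balanced_icc_table(500, s2p = 3, s2r = 1)
  expect_equal(fit_icc_lmm(tab)$icc, 0.75, tolerance = 0.05 / 0.75)
})

test_that("the LMM ICC is invariant to affine rescaling of the values", {
  set.seed(4)
  tab <- balanced_icc_table(15, 2, 1)
  base <- fit_icc_lmm(tab)$icc
  tab2 <- tab; tab2$value <- -3.2 * tab2$value + 40
  expect_equal(fit_icc_lmm(tab2)$icc, base, tolerance = 1e-6)
})

test_that("input validation catches unusable tables", {
  expect_error(fit_icc_lmm(data.frame(participant = 1, rating = 1, value = 1)),
               "fewer than 2 ratings")
  expect_error(fit_icc_lmm(data.frame(participant = c(1, 1, 2, 2),
                                      rating = rep(1:2, 2), value = rnorm(4))),
               "3 participants")
  tab <- balanced_icc_table(5, 1, 1)
  tab$value[3] <- NA
  expect_error(fit_icc_lmm(tab), "non-finite")
})

test_that("degenerate bootstrap collapses to CI (1, 1) and seeds reproduce", {
  set.seed(5)
  tab <- data.frame(participant = rep(1:6, each = 2), rating = rep(1:2, 6),
                    value = rep(rnorm(6), each = 2))
  ci <- bootstrap_ci(tab, n_boot = 40, seed = 1)
  expect_equal(c(ci$ci_low, ci$ci_high), c(1, 1))

  tab2 <- balanced_icc_table(10, 2, 1)
  a <- bootstrap_ci(tab2, n_boot = 60, seed = 7)
  b <- bootstrap_ci(tab2, n_boot = 60, seed = 7)
  expect_identical(a, b)
  expect_true(a$ci_low <= a$ci_high)
  expect_equal(a$n_failed, 0)
})

test_that("unbalanced tables take the slow resampling path and still work", {
  set.seed(6)
  tab <- balanced_icc_table(12, 2, 1)
  tab <- tab[-1, ]  # drop one rating -> unbalanced
  fit <- fit_icc_lmm(tab)
  expect_true(fit$icc > 0 && fit$icc < 1)
  ci <- bootstrap_ci(tab, n_boot = 30, seed = 2)
  expect_true(ci$ci_low <= ci$ci_high)
})

test_that("SEM follows SD * sqrt(1 - ICC)", {
  expect_equal(sem(2, 1), 0)
  expect_equal(sem(2, 0), 2)
  expect_equal(sem(2, 0.75), 1)
  expect_error(sem(2, 1.2), "icc")
  expect_error(sem(-1, 0.5), "sd_pooled")
  # monotone decreasing in ICC at fixed SD
  vals <- vapply(seq(0, 1, by = 0.1), sem, numeric(1), sd_pooled = 3)
  expect_true(all(diff(vals) < 0))
})

test_that("qualitative classes use left-closed bins with 0.90 excellent", {
  expect_equal(classify_icc(0.49), "poor")
  expect_equal(classify_icc(0.50), "moderate")
  expect_equal(classify_icc(0.75), "good")
  expect_equal(classify_icc(0.90), "excellent")
  expect_equal(classify_icc(c(-0.2, 0.6, 0.89, 0.99)),
               c("poor", "moderate", "good", "excellent"))
})

test_that("limb-type fixed effect prevents pooled-ICC inflation", {
  set.seed(7)
  make_pooled <- function(offset) {
    n <- 60
    u <- rnorm(n, 0, 1)
    lt <- rep(c("healthy", "tendinopathy", "BPTB"), length.out = n)
    shift <- c(healthy = 0, tendinopathy = offset, BPTB = 2 * offset)[lt]
    data.frame(participant = rep(seq_len(n), each = 2),
               rating = rep(c("r1", "r2"), n),
               limb_type = rep(lt, each = 2),
               value = rep(u + shift, each = 2) + rnorm(2 * n, 0, 1))
  }
  # identical limb-type distributions: pooled ~ plain
  tab0 <- make_pooled(0)
  plain0 <- fit_icc_lmm(tab0)$icc
  pooled0 <- suppressWarnings(fit_icc_lmm(tab0, extra_fixed = "limb_type"))$icc
  expect_equal(pooled0, plain0, tolerance = 0.1)

  # strong limb-type offsets: the fixed effect keeps the ICC near truth,
  # omitting it inflates the between-participant variance
  tab <- make_pooled(4)
  with_fe <- fit_icc_lmm(tab, extra_fixed = "limb_type")$icc
  without_fe <- fit_icc_lmm(tab)$icc
  expect_gt(without_fe, with_fe + 0.1)
  expect_equal(with_fe, 0.5, tolerance = 0.3)

  # zero residual variance: ICC 1 regardless of limb-type effects
  tabz <- make_pooled(4)
  tabz$value <- rep(tabz$value[seq(1, nrow(tabz), 2)], each = 2)
  expect_equal(pooled_icc_with_limbtype(tabz, "rater", n_boot = 10, seed = 1)$icc, 1)

  # single limb type falls back with a warning
  single <- tab[tab$limb_type == "healthy", ]
  expect_warning(pooled_icc_with_limbtype(single, "rater", n_boot = 10, seed = 1),
                 "single limb type")
})

test_that("outlier removal battery matches a direct refit", {
  set.seed(8)
  tab <- balanced_icc_table(10, 2, 0.3)
  # make participant S010 wildly discordant between ratings
  tab$value[tab$participant == "S010"] <- c(-6, 6)
  full <- icc_reliability(tab, "session", n_boot = 50, seed = 3)
  dropped <- outlier_sensitivity(tab, "S010", "session", n_boot = 50, seed = 3)
  expect_gt(dropped$icc, full$icc)
  direct <- fit_icc_lmm(tab[tab$participant != "S010", ])
  expect_equal(dropped$icc, direct$icc, tolerance = 1e-12)
  expect_equal(dropped$n_subjects, 9)

  # dropping an average participant barely moves the ICC on a large cohort
  set.seed(9)
  big <- balanced_icc_table(300, 2, 1)
  gm <- mean(big$value)
  big$value[big$participant == "S001"] <- gm
  drop1 <- outlier_sensitivity(big, "S001", "session", n_boot = 10, seed = 1)
  expect_lt(abs(drop1$icc - fit_icc_lmm(big)$icc), 0.05)

  expect_error(outlier_sensitivity(balanced_icc_table(3, 1, 1), "S001"),
               "fewer than 3")
  expect_error(outlier_sensitivity(balanced_icc_table(5, 1, 1), "nope"),
               "not present")
})

test_that("ICC sample size follows the variance-ratio approximation", {
  # hand evaluation: k = 2, z = 1.959964 + 0.8416212, C0 = 1/7
  z2 <- (stats::qnorm(0.975) + stats::qnorm(0.80))^2
  n_direct <- ceiling(1 + 4 * z2 / log(1 / 7)^2)
  expect_equal(sample_size_icc(0, 0.75, 2, 0.05, 0.80), n_direct)
  expect_equal(n_direct, 10)

  # monotone in power; diverges as the alternative approaches the null
  pw <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.99), function(p)
    sample_size_icc(0, 0.75, 2, 0.05, p), integer(1))
  expect_true(all(diff(pw) >= 0))
  expect_gt(sample_size_icc(0.74, 0.75, 2, 0.05, 0.80), 1e4)
  expect_error(sample_size_icc(0.8, 0.75), "rho")
})

test_that("icc_reliability bundles a coherent result", {
  set.seed(10)
  tab <- balanced_icc_table(10, 3, 1)
  res <- icc_reliability(tab, "rater", n_boot = 60, seed = 4)
  expect_s3_class(res, "icc_result")
  expect_true(res$ci_low <= res$ci_high)
  expect_equal(res$sem, sd(tab$value) * sqrt(1 - res$icc))
  expect_equal(res$classification, classify_icc(res$icc))
  expect_equal(res$n_subjects, 10)
  expect_output(print(res), "ICC\\(rater\\)")
})
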