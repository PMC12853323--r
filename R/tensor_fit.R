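# Design matrix of the log-linearised tensor model:
# ln S = ln S0 - b g' D g  =  X theta,
# theta = (ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
.tensor_design <- function(protocol) {
  b <- protocol$bvalues
  g <- protocol$directions
  X <- cbind(1,
             -b * g[, 1L]^2, -b * g[, 2L]^2, -b * g[, 3L]^2,
             -2 * b * g[, 1L] * g[, 2L],
             -2 * b * g[, 1L] * g[, 3L],
             -2 * b * g[, 2L] * g[, 3L])
  colnames(X) <- c("lnS0", "xx", "yy", "zz", "xy", "xz", "yz")
  X
}

.check_design <- function(X) {
  r <- qr(X)$rank
  if (r < 7L)
    stop(sprintf(paste0("rank-deficient gradient scheme (design rank %d < 7): ",
                        "directions are coplanar or too few for a tensor fit"), r),
         call. = FALSE)
  invisible(X)
}

# pull in-mask signals into an n_vol x n_vox matrix
.signal_matrix <- function(dwi, idx) {
  d <- dim(dwi$data)
  m <- matrix(dwi$data, prod(d[1:3]), d[4L])
  t(m[idx, , drop = FALSE])
}

#' Weighted log-linear tensor fit
#'
#' Per-voxel weighted least squares on the log-linearised single-tensor
#' model `ln S = ln S0 - b g' D g`. An ordinary least-squares pass is
#' followed by one reweighted pass with weights equal to the squared
#' predicted signal, which undoes the variance distortion of the log
#' transform. This is the standard initialiser for the nonlinear fit.
#'
#' @param dwi a `dwi_volume` (see [simulate_dwi()] / [read_dwi()]).
#' @param protocol a [dwi_protocol()]; defaults to the one carried by `dwi`.
#' @param mask optional logical array restricting the fit; default all
#'   voxels with positive b = 0 signal.
#' @return A [tensor_field()]. Non-positive signals are clamped to a small
#'   epsilon before the log; affected voxels are recorded in
#'   `attr(, "clamped")`.
#' @export
fit_tensor_loglinear <- function(dwi, protocol = dwi$protocol, mask = NULL) {
  .assert(inherits(protocol, "dwi_protocol"), "protocol required")
  .assert(length(protocol$bvalues) >= 7L && protocol$n_b0 >= 1L,
          "need at least 7 volumes including at least one b = 0")
  X <- .check_design(.tensor_design(protocol))
  d <- dim(dwi$data)[1:3]
  if (is.null(mask)) {
    b0 <- which(protocol$bvalues == 0)[1L]
    mask <- array(dwi$data[, , , b0] > 0, d)
  }
  .assert(identical(dim(mask), d), "mask must live on the DWI grid")
  idx <- which(mask)
  .assert(length(idx) > 0L, "fit mask is empty")
  Y <- .signal_matrix(dwi, idx)                     # n_vol x n_vox
  eps <- 1e-10 * max(Y, 1e-300)
  clamped <- colSums(Y <= 0) > 0
  Y[Y <= 0] <- eps
  L <- log(Y)
  beta <- qr.coef(qr(X), L)                          # OLS pass, all voxels at once
  # reweighted pass: weights = squared predicted signal
  What <- exp(X %*% beta)
  for (v in seq_along(idx)) {
    w <- What[, v]^2
    Xw <- X * w
    beta[, v] <- solve(crossprod(X, Xw), crossprod(Xw, L[, v]))
  }
  tn <- matrix(0, prod(d), 6L)
  s0 <- array(0, d)
  valid <- array(FALSE, d)
  tn[idx, ] <- t(beta[2:7, , drop = FALSE])
  s0[idx] <- exp(beta[1L, ])
  valid[idx] <- TRUE
  out <- tensor_field(array(tn, c(d, 6L)), s0, valid,
                      dwi$grid %||% grid_spec(d, c(1, 1, 1)))
  cl <- array(FALSE, d); cl[idx] <- clamped
  attr(out, "clamped") <- cl
  out
}

# residual/jacobian for the un-logged model in (lnS0, D6) coordinates
.nls_resid <- function(theta, X, y) y - exp(drop(X %*% theta))
.nls_jac <- function(theta, X, y) {
  m <- exp(drop(X %*% theta))
  -m * X  # d r / d theta
}

# Cholesky parameterisation: theta = (lnS0, L11, L21, L22, L31, L32, L33),
# D = L L' guarantees non-negative eigenvalues.
.chol_to_d6 <- function(th) {
  L <- matrix(0, 3L, 3L)
  L[lower.tri(L, diag = TRUE)] <- th[2:7]
  D <- L %*% t(L)
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}
.d6_to_chol <- function(d6, floor_ev = 1e-12) {
  M <- .tensor6_to_mat(d6)
  e <- eigen(M, symmetric = TRUE)
  ev <- pmax(e$values, floor_ev)
  L <- t(chol(e$vectors %*% diag(ev) %*% t(e$vectors)))
  L[lower.tri(L, diag = TRUE)]
}
.nls_resid_chol <- function(theta, X, y) {
  d6 <- .chol_to_d6(theta)
  y - exp(theta[1L] + drop(X[, -1L] %*% d6))
}

#' Nonlinear tensor fit
#'
#' Per-voxel least squares on the un-logged signal model
#' `S0 * exp(-b g' D g)` by damped Levenberg-Marquardt iteration, started
#' from the log-linear estimate. The objective never exceeds the
#' initialiser's objective; voxels that fail to converge within `max_iter`
#' iterations are flagged invalid (not fatal). With `positivity = TRUE` the
#' tensor is re-parameterised through its Cholesky factor, forcing all
#' eigenvalues to be non-negative.
#'
#' @param dwi a `dwi_volume`.
#' @param protocol a [dwi_protocol()]; defaults to the one carried by `dwi`.
#' @param mask optional logical array restricting the fit; default: voxels
#'   valid in `init`.
#' @param init initial [tensor_field()] from [fit_tensor_loglinear()];
#'   computed automatically when omitted.
#' @param positivity logical; use the Cholesky parameterisation.
#' @param max_iter maximum Levenberg-Marquardt iterations per voxel.
#' @param ftol relative objective-decrease convergence tolerance.
#' @return A [tensor_field()] with per-voxel residual sum of squares in
#'   `attr(, "rss")` (array) and the initialiser's un-logged objective in
#'   `attr(, "rss_init")`.
#' @export
fit_tensor_nonlinear <- function(dwi, protocol = dwi$protocol, mask = NULL,
                                 init = NULL, positivity = FALSE,
                                 max_iter = 100L, ftol = 1e-10) {
  if (is.null(init)) init <- fit_tensor_loglinear(dwi, protocol, mask)
  .assert(inherits(init, "tensor_field"), "init must be a tensor_field")
  X <- .check_design(.tensor_design(protocol))
  d <- dim(dwi$data)[1:3]
  if (is.null(mask)) mask <- init$valid
  idx <- which(mask & init$valid)
  .assert(length(idx) > 0L, "fit mask is empty")
  Y <- .signal_matrix(dwi, idx)
  init_rows <- .tensor_rows(init, idx)
  s0_init <- init$s0[idx]

  tn <- matrix(init$tensors, ncol = 6L)
  s0 <- init$s0
  valid <- array(FALSE, d)
  rss <- array(NA_real_, d)
  rss0 <- array(NA_real_, d)
  ctrl <- minpack.lm::nls.lm.control(maxiter = as.integer(max_iter),
                                     ftol = ftol, ptol = 1e-12, gtol = 0)
  for (v in seq_along(idx)) {
    y <- Y[, v]
    th0_lin <- c(log(max(s0_init[v], 1e-300)), init_rows[v, ])
    obj0 <- sum(.nls_resid(th0_lin, X, y)^2)
    fit <- if (positivity) {
      th0 <- c(th0_lin[1L], .d6_to_chol(init_rows[v, ]))
      tryCatch(minpack.lm::nls.lm(par = th0, fn = .nls_resid_chol,
                                  X = X, y = y, control = ctrl),
               error = function(e) NULL)
    } else {
      tryCatch(minpack.lm::nls.lm(par = th0_lin, fn = .nls_resid,
                                  jac = .nls_jac, X = X, y = y, control = ctrl),
               error = function(e) NULL)
    }
    i <- idx[v]
    rss0[i] <- obj0
    if (is.null(fit) || fit$deviance > obj0 + 1e-12 * max(obj0, 1)) {
      # keep the initialiser (LM is monotone; this is a numerical safety net)
      tn[i, ] <- init_rows[v, ]
      s0[i] <- s0_init[v]
      valid[i] <- !is.null(fit)
      rss[i] <- obj0
      next
    }
    th <- fit$par
    d6 <- if (positivity) .chol_to_d6(th) else th[2:7]
    tn[i, ] <- d6
    s0[i] <- exp(th[1L])
    rss[i] <- fit$deviance
    # info 1-4: converged; 5: max iterations exhausted -> flag invalid
    valid[i] <- fit$info %in% 1:4
  }
  out <- tensor_field(array(tn, c(d, 6L)), s0, valid,
                      dwi$grid %||% grid_spec(d, c(1, 1, 1)))
  attr(out, "rss") <- rss
  attr(out, "rss_init") <- rss0
  out
}
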