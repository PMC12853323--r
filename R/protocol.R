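#' Diffusion-weighting protocol (gradient table)
#'
#' Bundles the per-volume b-values and gradient directions of a DWI
#' acquisition. Directions of diffusion-weighted volumes must be unit
#' vectors; b = 0 volumes may carry an arbitrary (conventionally zero)
#' direction.
#'
#' @param bvalues numeric vector of b-values in s/mm^2, one per volume.
#' @param directions numeric matrix with one row per volume and 3 columns.
#' @return A `dwi_protocol` object: list with `bvalues`, `directions`
#'   (n x 3 matrix), and `n_b0`.
#' @export
dwi_protocol <- function(bvalues, directions) {
  bvalues <- as.numeric(bvalues)
  directions <- as.matrix(directions)
  dimnames(directions) <- NULL
  .assert(ncol(directions) == 3L, "directions must have 3 columns")
  .assert(nrow(directions) == length(bvalues),
          "bvalues and directions must have one entry per volume")
  .assert(all(is.finite(bvalues)) && all(bvalues >= 0), "all b-values must be >= 0")
  nrm <- sqrt(rowSums(directions^2))
  dwi <- bvalues > 0
  .assert(all(abs(nrm[dwi] - 1) <= 1e-6),
          "directions of b > 0 volumes must have unit norm (tolerance 1e-6)")
  structure(list(bvalues = bvalues,
                 directions = directions,
                 n_b0 = sum(!dwi)),
            class = "dwi_protocol")
}

#' @export
print.dwi_protocol <- function(x, ...) {
  cat(sprintf("<dwi_protocol> %d volumes: %d b=0, %d diffusion-weighted (b = %s s/mm^2)\n",
              length(x$bvalues), x$n_b0, sum(x$bvalues > 0),
              paste(unique(x$bvalues[x$bvalues > 0]), collapse = ", ")))
  invisible(x)
}

#' Standard 30-direction tendon DTI protocol
#'
#' The acquisition scheme emulated throughout the package: `n_b0` unweighted
#' volumes followed by `n_dir` diffusion-weighted volumes at a single shell.
#' Directions are a deterministic golden-angle spiral over the hemisphere,
#' which is well-conditioned for tensor estimation.
#'
#' @param bvalue shell b-value in s/mm^2 (default 800).
#' @param n_dir number of diffusion directions (default 30).
#' @param n_b0 number of b = 0 volumes (default 4).
#' @return A [dwi_protocol()].
#' @export
dti_protocol <- function(bvalue = 800, n_dir = 30, n_b0 = 4) {
  .assert(n_dir >= 6, "at least 6 directions are required for a tensor fit")
  i <- seq_len(n_dir)
  z <- (i - 0.5) / n_dir
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  g <- cbind(r * cos(phi), r * sin(phi), z)
  g <- g / sqrt(rowSums(g^2))
  dwi_protocol(c(rep(0, n_b0), rep(bvalue, n_dir)),
               rbind(matrix(0, n_b0, 3), g))
}

#' Read an FSL-dialect bval/bvec pair
#'
#' `bval` holds one line of space-separated b-values; `bvec` holds three
#' lines with the x, y and z components of each direction.
#'
#' @param bval_path,bvec_path paths to the two text files.
#' @return A [dwi_protocol()].
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  rows <- readLines(bvec_path)
  rows <- rows[nzchar(trimws(rows))]
  .assert(length(rows) == 3L, "bvec file must contain exactly 3 non-empty lines")
  comp <- lapply(rows, function(r) as.numeric(strsplit(trimws(r), "[[:space:]]+")[[1]]))
  .assert(length(unique(lengths(comp))) == 1L, "bvec lines must have equal length")
  dwi_protocol(bvals, t(do.call(rbind, comp)))
}

#' Write an FSL-dialect bval/bvec pair
#'
#' @param protocol a [dwi_protocol()].
#' @param bval_path,bvec_path output paths.
#' @return Invisibly, the protocol.
#' @export
write_bval_bvec <- function(protocol, bval_path, bvec_path) {
  writeLines(paste(format(protocol$bvalues, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  writeLines(apply(t(protocol$directions), 1L, function(r)
    paste(format(r, trim = TRUE, digits = 15), collapse = " ")), bvec_path)
  invisible(protocol)
}
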