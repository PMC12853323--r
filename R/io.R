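.as_nifti <- function(arr, grid) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$spacing
  img
}

#' Write a 3D scalar map as NIfTI
#'
#' @param arr numeric 3D array.
#' @param grid a [grid_spec()] supplying the voxel dimensions.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return Invisibly, the path.
#' @export
write_scalar_nifti <- function(arr, grid, path) {
  RNifti::writeNifti(.as_nifti(arr, grid$spacing), path)
  invisible(path)
}

#' Read/write binary masks as uint8 NIfTI
#'
#' Anatomical metadata (laterality, proximal end) is not representable in
#' the NIfTI header and must be supplied on read.
#'
#' @param mask a [tendon_mask()].
#' @param path NIfTI path.
#' @return Invisibly, the path.
#' @export
write_mask_nifti <- function(mask, path) {
  RNifti::writeNifti(.as_nifti(array(as.integer(mask$voxels), dim(mask$voxels)),
                               mask_grid(mask)),
                     path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask_nifti
#' @inheritParams tendon_mask
#' @export
read_mask_nifti <- function(path, proximal_end = "first",
                            limb_side = NA_character_,
                            medial_direction = NA_integer_) {
  img <- RNifti::readNifti(path)
  tendon_mask(array(as.vector(img) > 0.5, dim(img)),
              RNifti::pixdim(img)[1:3],
              proximal_end = proximal_end, limb_side = limb_side,
              medial_direction = medial_direction)
}

#' Write a trisection label map as NIfTI
#'
#' Labels: 0 background, 1 medial, 2 central, 3 lateral.
#'
#' @param regions a [region_set()] containing the three longitudinal masks.
#' @param path NIfTI path.
#' @return Invisibly, the path.
#' @export
write_labelmap_nifti <- function(regions, path) {
  lab <- array(0L, regions$grid$dim)
  lab[regions$masks$medial] <- 1L
  lab[regions$masks$central] <- 2L
  lab[regions$masks$lateral] <- 3L
  RNifti::writeNifti(.as_nifti(lab, regions$grid), path, datatype = "uint8")
  invisible(path)
}

#' Write/read a DWI series as 4D NIfTI plus FSL-dialect bval/bvec
#'
#' @param dwi a `dwi_volume` (see [simulate_dwi()]).
#' @param prefix output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`.
#' @return Invisibly, the prefix.
#' @export
write_dwi <- function(dwi, prefix) {
  RNifti::writeNifti(.as_nifti(dwi$data, dwi$grid), paste0(prefix, ".nii.gz"))
  write_bval_bvec(dwi$protocol, paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' @rdname write_dwi
#' @param path 4D NIfTI path.
#' @param bval_path,bvec_path gradient-table paths; defaults replace the
#'   NIfTI extension.
#' @export
read_dwi <- function(path, bval_path = NULL, bvec_path = NULL) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  img <- RNifti::readNifti(path)
  .assert(length(dim(img)) == 4L, "DWI NIfTI must be 4D")
  protocol <- read_bval_bvec(bval_path %||% paste0(stem, ".bval"),
                             bvec_path %||% paste0(stem, ".bvec"))
  .assert(dim(img)[4L] == length(protocol$bvalues),
          "volume count does not match the gradient table")
  structure(list(data = array(as.vector(img), dim(img)),
                 protocol = protocol,
                 grid = grid_spec(dim(img)[1:3], RNifti::pixdim(img)[1:3])),
            class = "dwi_volume")
}

#' Write a simulated cohort to disk
#'
#' Masks go out as uint8 NIfTI on the anatomical grid, DWI as 4D NIfTI with
#' FSL-dialect bval/bvec, and a `manifest.csv` records subject, limb, limb
#' type, session, rater and file paths.
#'
#' @param cohort a `cohort_dataset` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data.frame.
#' @export
write_cohort <- function(cohort, dir) {
  .assert(inherits(cohort, "cohort_dataset"), "cohort_dataset required")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  add <- function(rec, kind, session, rater, file) {
    rows[[length(rows) + 1L]] <<- data.frame(
      participant = rec$participant, limb = rec$limb, limb_type = rec$limb_type,
      kind = kind, session = session, rater = rater, file = file,
      stringsAsFactors = FALSE)
  }
  for (rec in cohort$limbs) {
    stem <- sprintf("%s_%s", rec$participant, rec$limb)
    f <- file.path(dir, paste0(stem, "_truth.nii.gz"))
    write_mask_nifti(rec$truth_mask, f); add(rec, "truth_mask", NA, NA, f)
    for (nm in names(rec$rater_masks)) {
      rater <- as.integer(sub("rater(\\d)_s\\d", "\\1", nm))
      session <- as.integer(sub("rater\\d_s(\\d)", "\\1", nm))
      f <- file.path(dir, paste0(stem, "_", nm, ".nii.gz"))
      write_mask_nifti(rec$rater_masks[[nm]], f)
      add(rec, "rater_mask", session, rater, f)
    }
    for (s in 1:2) {
      prefix <- file.path(dir, sprintf("%s_dwi_s%d", stem, s))
      write_dwi(rec$dwi[[s]], prefix)
      add(rec, "dwi", s, NA, paste0(prefix, ".nii.gz"))
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
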