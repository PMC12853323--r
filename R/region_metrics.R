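.dti_metrics <- c("lambda1", "lambda2", "lambda3", "md", "fa")
.region_names <- c("whole", "medial", "central", "lateral", "proximal", "distal")

#' Per-region scalar-map statistics
#'
#' Voxel-weighted arithmetic mean and SD of each DTI scalar metric over the
#' valid, physically plausible voxels of each region mask, plus a tendon
#' volume row per region computed from the anatomical-resolution masks
#' (volume = voxel count x voxel volume, reported in cm^3). Diffusivities
#' are reported in 1e-3 mm^2/s, the conventional unit for tendon DTI
#' tables.
#'
#' @param maps a [scalar_maps()] object on the DTI grid.
#' @param regions_dti a [region_set()] on the DTI grid (downsampled and
#'   eroded), used for the DTI metrics.
#' @param regions_anat optional high-resolution [region_set()] used for the
#'   volume rows; omitted -> no volume rows.
#' @param keys named list of identifying columns prepended to every row
#'   (e.g. participant, limb, session, rater).
#' @return data.frame with columns from `keys` plus `region`, `metric`,
#'   `value`, `sd_within`, `n_voxels`, `missing`. A region with no valid
#'   voxel yields a row flagged `missing = TRUE` with `NA` value.
#' @export
extract_region_stats <- function(maps, regions_dti, regions_anat = NULL,
                                 keys = list()) {
  .assert(inherits(maps, "scalar_maps"), "maps must be scalar_maps")
  .assert(inherits(regions_dti, "region_set"), "regions_dti must be a region_set")
  ok <- maps$valid & maps$physical
  rows <- list()
  for (rg in intersect(.region_names, names(regions_dti$masks))) {
    sel <- regions_dti$masks[[rg]] & ok
    n <- sum(sel)
    for (met in .dti_metrics) {
      scale <- if (met == "fa") 1 else 1e3   # mm^2/s -> 1e-3 mm^2/s
      vals <- maps[[met]][sel] * scale
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, metric = met,
        value = if (n > 0) mean(vals) else NA_real_,
        sd_within = if (n > 1) stats::sd(vals) else if (n == 1) 0 else NA_real_,
        n_voxels = n, missing = n == 0,
        stringsAsFactors = FALSE)
    }
    if (!is.null(regions_anat) && rg %in% names(regions_anat$masks)) {
      vol <- sum(regions_anat$masks[[rg]]) * prod(regions_anat$grid$spacing) / 1000
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, metric = "volume", value = vol, sd_within = NA_real_,
        n_voxels = sum(regions_anat$masks[[rg]]), missing = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (length(keys)) out <- cbind(as.data.frame(keys, stringsAsFactors = FALSE), out,
                                 row.names = NULL)
  out
}
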