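#' Tibial plateau footprint area from a single-slice segmentation
#'
#' The footprint is segmented on a single axial slice at the widest point of
#' the tibial plateau; its area is the segmented volume divided by the voxel
#' height, i.e. `n_voxels * voxel_size^2` for isotropic voxels.
#'
#' @param vol a [label_volume()] whose mask occupies exactly one index along
#'   the axial axis.
#' @return An object of class `footprint_result` with `area` (mm^2),
#'   `n_voxels` and `voxel_size`.
#' @export
plateau_footprint <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  occ <- which(vol$mask == 1L, arr.ind = TRUE)
  if (nrow(occ) == 0L) stop("empty footprint mask")
  ax <- which(vol$axis_labels == "axial")
  slices <- sort(unique(occ[, ax]))
  if (length(slices) > 1L) {
    stop("footprint mask spans more than one axial slice (indices ",
         paste(slices, collapse = ", "), "); segment a single slice")
  }
  n <- nrow(occ)
  structure(list(area = n * vol$voxel_size^2, n_voxels = n,
                 voxel_size = vol$voxel_size, axial_index = slices),
            class = "footprint_result")
}

#' @export
print.footprint_result <- function(x, ...) {
  cat(sprintf("tibial plateau footprint: %.4f mm^2 (%d voxels at %g mm)\n",
              x$area, x$n_voxels, x$voxel_size))
  invisible(x)
}

#' Compare paired footprint areas from two imaging modalities
#'
#' Agreement between, e.g., MRI-derived and microCT-derived tibial plateau
#' areas on the same specimens: a paired two-sided rank-sum test plus
#' Bland-Altman bias and 95% limits of agreement.
#'
#' @param mri_areas numeric vector of areas (mm^2).
#' @param ct_areas paired numeric vector of the same length (n >= 3).
#' @return A list with `rank_sum` (a `stat_result`) and `bland_altman` (an
#'   `agreement_result`).
#' @export
compare_footprints <- function(mri_areas, ct_areas) {
  if (length(mri_areas) != length(ct_areas)) {
    stop("paired area lists must have equal length")
  }
  if (length(mri_areas) < 3L) stop("need at least 3 paired areas")
  list(rank_sum = rank_sum(mri_areas, ct_areas, paired = TRUE),
       bland_altman = bland_altman(mri_areas, ct_areas))
}
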