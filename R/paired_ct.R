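#' Construct a paired inspiration/expiration CT object
#'
#' Bundles two pre-aligned HU volumes, a lung segmentation mask (airways
#' removed) and the voxel spacing. Registration and segmentation are upstream
#' preconditions: the inspiratory scan must already live in the expiratory
#' geometric frame, so all three volumes share one grid.
#'
#' @param insp_hu,exp_hu 3D numeric arrays of Hounsfield units on the same
#'   grid (inspiration resampled to the expiratory frame).
#' @param lung_mask 3D logical (or 0/1) array marking lung voxels.
#' @param spacing_mm voxel spacing in mm, length 3.
#' @param insp_volume_l,exp_volume_l optional scanner-reported lung volumes
#'   (litres) of the *original* inspiratory and expiratory segmentations,
#'   used by [qc_flag()]. After registration both scans share one mask, so
#'   these cannot be recovered from `lung_mask` alone.
#' @return An object of class `paired_ct`.
#' @export
paired_ct <- function(insp_hu, exp_hu, lung_mask, spacing_mm,
                      insp_volume_l = NULL, exp_volume_l = NULL) {
  for (nm in c("insp_hu", "exp_hu", "lung_mask")) {
    v <- get(nm)
    if (is.null(dim(v)) || length(dim(v)) != 3L) {
      stop(sprintf("`%s` must be a 3D array", nm), call. = FALSE)
    }
  }
  if (!identical(dim(insp_hu), dim(exp_hu)) ||
      !identical(dim(insp_hu), dim(lung_mask))) {
    stop("inspiration, expiration and mask volumes must share one grid",
         call. = FALSE)
  }
  mask <- array(as.logical(lung_mask), dim = dim(lung_mask))
  if (anyNA(mask)) stop("lung_mask contains NA", call. = FALSE)
  if (!any(mask)) stop("lung_mask is empty", call. = FALSE)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop("spacing_mm must be three positive values", call. = FALSE)
  }
  structure(
    list(insp_hu = insp_hu, exp_hu = exp_hu, lung_mask = mask,
         spacing_mm = as.numeric(spacing_mm),
         insp_volume_l = insp_volume_l, exp_volume_l = exp_volume_l),
    class = "paired_ct")
}

#' @export
print.paired_ct <- function(x, ...) {
  d <- dim(x$insp_hu)
  cat(sprintf("<paired_ct> %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  lung voxels: %d (%.2f L on this grid)\n",
              sum(x$lung_mask),
              sum(x$lung_mask) * voxel_volume_l(x$spacing_mm)))
  invisible(x)
}
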