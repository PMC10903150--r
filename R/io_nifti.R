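#' Read a registered inspiration/expiration pair from NIfTI
#'
#' Loads the two HU volumes and the lung mask, checks that all three share
#' one grid and consistent affines, and returns a [paired_ct()]. A
#' suspicious intensity range (no air-like voxels, or values far outside the
#' CT range) triggers a warning, not an error.
#'
#' @param insp_path,exp_path,mask_path NIfTI file paths.
#' @param insp_volume_l,exp_volume_l optional scanner-reported lung volumes
#'   for [qc_flag()].
#' @return A [paired_ct()].
#' @export
read_paired_ct <- function(insp_path, exp_path, mask_path,
                           insp_volume_l = NULL, exp_volume_l = NULL) {
  insp <- RNifti::readNifti(insp_path)
  exp_ <- RNifti::readNifti(exp_path)
  mask <- RNifti::readNifti(mask_path)
  dims <- list(dim(insp), dim(exp_), dim(mask))
  if (!identical(dims[[1]], dims[[2]]) || !identical(dims[[1]], dims[[3]])) {
    stop("grid mismatch between inspiration/expiration/mask volumes",
         call. = FALSE)
  }
  xf <- lapply(list(insp, exp_, mask), function(x) RNifti::xform(x))
  if (max(abs(xf[[1]] - xf[[2]])) > 1e-3 ||
      max(abs(xf[[1]] - xf[[3]])) > 1e-3) {
    stop("affine mismatch between volumes", call. = FALSE)
  }
  mv <- sort(unique(as.vector(mask)))
  if (!all(mv %in% c(0, 1))) {
    stop("mask must be binary 0/1", call. = FALSE)
  }
  for (nm in list(list(insp, "inspiration"), list(exp_, "expiration"))) {
    rng <- range(nm[[1]])
    if (rng[1] > -500 || rng[1] < -1100 || rng[2] > 3200) {
      warning(sprintf("%s intensities look non-HU-like (range %.0f..%.0f)",
                      nm[[2]], rng[1], rng[2]), call. = FALSE)
    }
  }
  spacing <- RNifti::pixdim(insp)[1:3]
  paired_ct(array(as.numeric(insp), dim(insp)),
            array(as.numeric(exp_), dim(exp_)),
            array(as.vector(mask) != 0, dim(mask)),
            spacing,
            insp_volume_l = insp_volume_l, exp_volume_l = exp_volume_l)
}

write_nifti_vol <- function(arr, spacing_mm, path) {
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- spacing_mm
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Write a paired CT (and optionally ground-truth labels) as NIfTI
#'
#' @param ct a [paired_ct()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param truth optional ground-truth label array (written with the same
#'   integer coding as [write_prm()]).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_paired_ct <- function(ct, dir, prefix = "case", truth = NULL) {
  stopifnot(inherits(ct, "paired_ct"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    insp = file.path(dir, paste0(prefix, "_insp.nii.gz")),
    exp = file.path(dir, paste0(prefix, "_exp.nii.gz")),
    mask = file.path(dir, paste0(prefix, "_mask.nii.gz")))
  write_nifti_vol(ct$insp_hu, ct$spacing_mm, paths["insp"])
  write_nifti_vol(ct$exp_hu, ct$spacing_mm, paths["exp"])
  write_nifti_vol(array(as.integer(ct$lung_mask), dim(ct$lung_mask)),
                  ct$spacing_mm, paths["mask"])
  if (!is.null(truth)) {
    paths["truth"] <- file.path(dir, paste0(prefix, "_truth.nii.gz"))
    lab <- truth
    lab[is.na(lab)] <- 0L
    write_nifti_vol(array(as.integer(lab), dim(lab)), ct$spacing_mm,
                    paths["truth"])
  }
  invisible(paths)
}

#' Write a PRM label volume with its JSON code sidecar
#'
#' Voxels outside the lung are written as 0; the sidecar documents the
#' integer code of every class ([prm_codes()]).
#'
#' @param prm a `prm_map` from [classify_voxels()].
#' @param path output NIfTI path (sidecar gets the same stem + `.json`).
#' @return The NIfTI path, invisibly.
#' @export
write_prm <- function(prm, path) {
  stopifnot(inherits(prm, "prm_map"))
  lab <- prm$labels
  lab[is.na(lab)] <- 0L
  write_nifti_vol(array(as.integer(lab), dim(lab)), prm$spacing_mm, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(codes = as.list(prm_codes()), background = 0L),
    sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a PRM label volume written by [write_prm()]
#'
#' @param path NIfTI path.
#' @return A `prm_map` (percent volumes recomputed from the labels; the lung
#'   mask is every non-zero voxel).
#' @export
read_prm <- function(path) {
  im <- RNifti::readNifti(path)
  lab <- array(as.integer(im), dim(im))
  mask <- array(lab != 0L, dim(lab))
  lab[lab == 0L] <- NA_integer_
  out <- structure(list(labels = lab, lung_mask = mask,
                        spacing_mm = RNifti::pixdim(im)[1:3]),
                   class = "prm_map")
  out$percent_volume <- percent_volume(out)
  out
}

#' Write interpolated tPRM maps as one NIfTI per class and measure
#'
#' Files are named `<prefix>_<measure>_<class>.nii.gz` (e.g.
#' `case_V_fSAD.nii.gz`); a JSON sidecar records the window, stride and
#' normalisation conventions.
#'
#' @param tprm a `tprm_maps` object.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return Named character vector of paths, invisibly.
#' @export
write_tprm_maps <- function(tprm, dir, prefix = "case") {
  stopifnot(inherits(tprm, "tprm_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (cl in tprm$classes) {
    for (ms in c("V", "chi")) {
      p <- file.path(dir, sprintf("%s_%s_%s.nii.gz", prefix, ms, cl))
      arr <- tprm[[ms]][[cl]]
      arr[is.na(arr)] <- 0
      write_nifti_vol(arr, c(1, 1, 1), p)
      paths[sprintf("%s_%s", ms, cl)] <- p
    }
  }
  sidecar <- file.path(dir, paste0(prefix, "_tprm.json"))
  jsonlite::write_json(
    list(window_vox = tprm$window_vox, stride_vox = tprm$stride_vox,
         grid_anchor = "volume origin (voxel index 1)",
         chi_convention = "closed-voxel cubical complex, 26-connected foreground, normalized by masked window voxel count",
         V_convention = "cube-cell volume of class over cube-cell volume of mask in window",
         classes = tprm$classes),
    sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
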