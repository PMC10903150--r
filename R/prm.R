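#' PRM class labels and integer codes
#'
#' One canonical coding shared by every writer/reader in the package:
#' Norm = 1, fSAD = 2, Emph = 3, PD = 4, Unclassified = 5; voxels outside the
#' lung mask are NA in-memory and 0 on disk.
#'
#' @return Named integer vector of codes.
#' @export
prm_codes <- function() {
  c(Norm = 1L, fSAD = 2L, Emph = 3L, PD = 4L, Unclassified = 5L)
}

#' @rdname prm_codes
#' @export
prm_classes <- function() names(prm_codes())

# joint HU decision rules, kept in one place. Thresholds follow the standard
# PRM convention: the normal/fSAD split of the expiratory scan sits at
# -856 HU, the emphysema threshold of the inspiratory scan at -950 HU and the
# parenchymal-disease threshold at -810 HU; only voxels with both scans in
# [-1000, -250] HU are classifiable. The printed inequalities are honoured
# literally (insp exactly -950 satisfies neither "> -950" nor "< -950" and
# routes to Unclassified), as do indeterminate voxels (insp < -950 with
# exp > -856).
prm_rule <- function(insp, exp) {
  lab <- rep(prm_codes()[["Unclassified"]], length(insp))
  in_range <- insp >= -1000 & insp <= -250 & exp >= -1000 & exp <= -250
  norm <- in_range & insp > -950 & insp <= -810 & exp >= -856
  fsad <- in_range & insp > -950 & insp <= -810 & exp < -856
  emph <- in_range & insp < -950 & exp < -856
  pd   <- in_range & insp > -810
  lab[norm] <- prm_codes()[["Norm"]]
  lab[fsad] <- prm_codes()[["fSAD"]]
  lab[emph] <- prm_codes()[["Emph"]]
  lab[pd]   <- prm_codes()[["PD"]]
  lab
}

#' Voxel-wise PRM classification of a paired CT
#'
#' Classifies every lung voxel of a registered inspiration/expiration pair by
#' joint HU thresholds into normal parenchyma (Norm), functional small
#' airways disease (fSAD), emphysema (Emph) or parenchymal disease (PD).
#' Voxels outside \[-1000, -250\] HU on either scan, indeterminate voxels
#' (inspiration < -950 with expiration > -856) and threshold-boundary voxels
#' that satisfy none of the printed rules are labelled Unclassified.
#'
#' @param ct a [paired_ct()] object.
#' @return An object of class `prm_map`: list with `labels` (3D integer array
#'   coded per [prm_codes()], NA outside the lung), `percent_volume` (tibble)
#'   and the lung mask.
#' @export
classify_voxels <- function(ct) {
  if (!inherits(ct, "paired_ct")) stop("`ct` must be a paired_ct", call. = FALSE)
  labels <- array(NA_integer_, dim = dim(ct$insp_hu))
  idx <- which(ct$lung_mask)
  labels[idx] <- prm_rule(as.numeric(ct$insp_hu[idx]),
                          as.numeric(ct$exp_hu[idx]))
  out <- structure(list(labels = labels, lung_mask = ct$lung_mask,
                        spacing_mm = ct$spacing_mm),
                   class = "prm_map")
  out$percent_volume <- percent_volume(out)
  out
}

#' Percent volume of each PRM class
#'
#' Percent of the expiratory lung volume occupied by each PRM class:
#' `100 * n_class / n_lung`. Unclassified voxels are excluded from the
#' numerators but kept in the denominator, which is the total lung volume at
#' expiration.
#'
#' @param prm a `prm_map` (or a 3D integer label array coded per
#'   [prm_codes()]).
#' @param lung_mask lung mask; taken from `prm` when it is a `prm_map`.
#' @return Tibble with columns `class`, `n_voxels`, `percent`.
#' @export
percent_volume <- function(prm, lung_mask = NULL) {
  if (inherits(prm, "prm_map")) {
    labels <- prm$labels
    lung_mask <- prm$lung_mask
  } else {
    labels <- prm
    if (is.null(lung_mask)) stop("`lung_mask` required", call. = FALSE)
  }
  n_lung <- sum(lung_mask)
  if (n_lung == 0) stop("lung mask is empty", call. = FALSE)
  codes <- prm_codes()
  lab <- labels[lung_mask]
  counts <- vapply(codes, function(cd) sum(lab == cd, na.rm = TRUE), integer(1))
  tibble::tibble(
    class = names(codes),
    n_voxels = as.integer(counts),
    percent = ifelse(names(codes) == "Unclassified",
                     NA_real_, 100 * counts / n_lung))
}

#' @export
print.prm_map <- function(x, ...) {
  cat("<prm_map>\n")
  pv <- x$percent_volume
  for (i in seq_len(nrow(pv))) {
    cat(sprintf("  %-12s %8d voxels", pv$class[i], pv$n_voxels[i]))
    if (!is.na(pv$percent[i])) cat(sprintf("  %6.2f %%", pv$percent[i]))
    cat("\n")
  }
  invisible(x)
}

#' Quality-control flag for a paired CT
#'
#' A registered pair is flagged when the expiratory lung volume is greater
#' than or equal to the inspiratory one (an erroneous volume change: the lung
#' cannot be at least as large at relaxed expiration as at full inflation) or
#' when either volume is physiologically implausible (< 1 L or > 10 L).
#' Because the pair shares one post-registration mask, the two volumes must
#' come from the original segmentations; pass them explicitly or store them
#' in the [paired_ct()] metadata. With no volume information available both
#' volumes are estimated from the shared mask and the case fails (equal
#' volumes are an erroneous volume change by construction).
#'
#' @param ct a [paired_ct()] object.
#' @param insp_volume_l,exp_volume_l lung volumes in litres; default to the
#'   `paired_ct` metadata fields, then to the mask-derived volume.
#' @return List with `pass` (logical) and `reason` (character, `""` on pass).
#' @export
qc_flag <- function(ct, insp_volume_l = NULL, exp_volume_l = NULL) {
  if (!inherits(ct, "paired_ct")) stop("`ct` must be a paired_ct", call. = FALSE)
  mask_vol <- sum(ct$lung_mask) * voxel_volume_l(ct$spacing_mm)
  vi <- insp_volume_l %||% ct$insp_volume_l %||% mask_vol
  ve <- exp_volume_l %||% ct$exp_volume_l %||% mask_vol
  if (vi < 1 || vi > 10) {
    return(list(pass = FALSE,
                reason = sprintf("implausible inspiratory lung volume (%.2f L)", vi)))
  }
  if (ve < 1 || ve > 10) {
    return(list(pass = FALSE,
                reason = sprintf("implausible expiratory lung volume (%.2f L)", ve)))
  }
  if (ve >= vi) {
    return(list(pass = FALSE, reason = "erroneous volume change"))
  }
  list(pass = TRUE, reason = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
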