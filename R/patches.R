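#' Extract random multi-channel tPRM patches from within the lung
#'
#' Samples `n_patches` cubic patches of edge `patch_edge_vox` at random
#' in-lung locations and vectorises the four tPRM channels (V_Norm, V_fSAD,
#' chi_Norm, chi_fSAD by default) at each location into one feature vector
#' per patch (channel blocks concatenated in a fixed, recorded order).
#' Eligible centres keep the patch fully inside the volume with at least
#' `min_lung_frac` of its voxels in the lung; field values at non-lung
#' voxels inside a patch are taken as 0.
#'
#' @param maps a `tprm_maps` object (needs classes Norm and fSAD) or a named
#'   list of full-grid fields.
#' @param lung_mask lung mask; taken from `maps` when it is `tprm_maps`.
#' @param n_patches number of patches.
#' @param patch_edge_vox odd patch edge (default 21, matching the tPRM
#'   window scale).
#' @param seed integer seed; the same seed reproduces the same patch set.
#' @param channels channel names; for `tprm_maps` input the default is
#'   `c("V_Norm","V_fSAD","chi_Norm","chi_fSAD")`.
#' @param min_lung_frac minimum in-lung fraction per patch.
#' @return Object of class `tprm_patch_set`: list with `X` (features x
#'   patches matrix), `locations` (patch centres), `channels`,
#'   `patch_edge_vox`, `seed`.
#' @export
extract_patches <- function(maps, lung_mask = NULL, n_patches = 500L,
                            patch_edge_vox = 21L, seed = 1L,
                            channels = NULL, min_lung_frac = 0.5) {
  if (inherits(maps, "tprm_maps")) {
    lung_mask <- maps$lung_mask
    fields <- list()
    for (cl in maps$classes) {
      fields[[paste0("V_", cl)]] <- maps$V[[cl]]
      fields[[paste0("chi_", cl)]] <- maps$chi[[cl]]
    }
    if (is.null(channels)) {
      channels <- intersect(c("V_Norm", "V_fSAD", "chi_Norm", "chi_fSAD"),
                            names(fields))
    }
    fields <- fields[channels]
  } else {
    fields <- maps
    if (is.null(channels)) channels <- names(fields)
    fields <- fields[channels]
    if (is.null(lung_mask)) stop("`lung_mask` required", call. = FALSE)
  }
  if (!length(fields)) stop("no channels to extract", call. = FALSE)
  edge <- as.integer(patch_edge_vox)
  if (edge < 1L || edge %% 2L == 0L) stop("patch_edge_vox must be odd", call. = FALSE)
  lm <- as_binary_array(lung_mask, "lung_mask")
  d <- dim(lm)
  if (any(d < edge)) stop("lung too small for patch size", call. = FALSE)
  h <- (edge - 1L) %/% 2L

  lungN <- array(.box_count_cpp(as.vector(lm), d, edge), d)
  interior <- array(FALSE, d)
  interior[(1L + h):(d[1] - h), (1L + h):(d[2] - h), (1L + h):(d[3] - h)] <- TRUE
  eligible <- which(interior & lungN >= min_lung_frac * edge^3)
  if (!length(eligible)) stop("lung too small for patch size", call. = FALSE)

  set.seed(as.integer(seed))
  picks <- sample(eligible, n_patches, replace = n_patches > length(eligible))
  ctr <- arrayInd(picks, d)

  p_per <- edge^3
  X <- matrix(0, nrow = p_per * length(fields), ncol = n_patches)
  offs <- seq_len(edge) - h - 1L
  for (i in seq_len(n_patches)) {
    xs <- ctr[i, 1] + offs; ys <- ctr[i, 2] + offs; zs <- ctr[i, 3] + offs
    for (ci in seq_along(fields)) {
      blk <- fields[[ci]][xs, ys, zs]
      blk[is.na(blk)] <- 0
      X[(ci - 1L) * p_per + seq_len(p_per), i] <- blk
    }
  }
  structure(
    list(X = X, locations = ctr, channels = channels,
         patch_edge_vox = edge, seed = as.integer(seed),
         dim = d),
    class = "tprm_patch_set")
}

#' @export
print.tprm_patch_set <- function(x, ...) {
  cat(sprintf("<tprm_patch_set> %d patches, edge %d, channels: %s\n",
              ncol(x$X), x$patch_edge_vox, paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Render per-patch labels as a case probability map
#'
#' Accumulates the abnormal (fast-associated) patch indicator over each
#' patch's footprint and returns the per-voxel mean; voxels covered by no
#' patch are NA. Thresholding this map at 0.5 gives the case's abnormal
#' region at patch resolution.
#'
#' @param patches a `tprm_patch_set`.
#' @param labels per-patch labels (`"fast"`/`"slow"`), e.g. from
#'   [classify_patches()].
#' @return 3D numeric array in \[0, 1\] (NA where uncovered).
#' @export
patch_probability_map <- function(patches, labels) {
  stopifnot(inherits(patches, "tprm_patch_set"))
  if (length(labels) != ncol(patches$X)) {
    stop("one label per patch required", call. = FALSE)
  }
  d <- patches$dim
  h <- (patches$patch_edge_vox - 1L) %/% 2L
  acc <- array(0, d); cnt <- array(0, d)
  offs <- -h:h
  for (i in seq_len(nrow(patches$locations))) {
    xs <- patches$locations[i, 1] + offs
    ys <- patches$locations[i, 2] + offs
    zs <- patches$locations[i, 3] + offs
    acc[xs, ys, zs] <- acc[xs, ys, zs] + (labels[i] == "fast")
    cnt[xs, ys, zs] <- cnt[xs, ys, zs] + 1
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Dice overlap coefficient of two binary masks
#'
#' @param a,b logical arrays of equal dimension.
#' @return `2 |A and B| / (|A| + |B|)`; NA when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must share one grid", call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  a[is.na(a)] <- FALSE; b[is.na(b)] <- FALSE
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}
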