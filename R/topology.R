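#' Euler-Poincare characteristic of a 3D binary volume
#'
#' Computes chi = n0 - n1 + n2 - n3 of the cubical complex formed by the
#' union of closed unit voxels (foreground 26-connectivity), where n_k counts
#' k-dimensional cells. chi is +1 per isolated convex component, drops below
#' zero for mesh-like structures with tunnels, and gains +1 per enclosed
#' cavity (a hollow shell has chi = 2). Additive over disjoint unions.
#'
#' @param x 3D logical or 0/1 array.
#' @return Integer chi.
#' @export
euler_characteristic <- function(x) {
  a <- as_binary_array(x, "x")
  .euler3d_cpp(as.vector(a), dim(a))
}

#' Windowed Minkowski maps of a PRM class on the stride grid
#'
#' At each node of a regular grid (every `stride_vox`-th voxel per axis,
#' anchored at the array origin) a cubic window of edge `window_vox` is
#' clipped to the volume and two local Minkowski measures of the class mask
#' are evaluated: volume density `V = nu(class in window) / nu(lung in
#' window)` where `nu` is the cube-cell (voxel) counting volume measure, and
#' the per-masked-voxel Euler characteristic `chi = chi(class in window) /
#' |lung in window|`. Windows containing no lung voxels are flagged invalid
#' and later filled by [interpolate_to_grid()].
#'
#' @param class_mask 3D binary mask of the PRM class (subset of the lung).
#' @param lung_mask 3D binary lung mask, same grid.
#' @param window_vox odd window edge in voxels (default 21).
#' @param stride_vox grid step in voxels (default 5).
#' @return List of class `minkowski_grid`: arrays `V`, `chi`, `valid` on the
#'   grid, 1-based node voxel indices `centers` per axis, plus window/stride
#'   metadata.
#' @export
minkowski_window_maps <- function(class_mask, lung_mask,
                                  window_vox = 21L, stride_vox = 5L) {
  cm <- as_binary_array(class_mask, "class_mask")
  lm <- as_binary_array(lung_mask, "lung_mask")
  if (!identical(dim(cm), dim(lm))) stop("masks must share one grid", call. = FALSE)
  if (any(cm > lm)) stop("class_mask must be a subset of lung_mask", call. = FALSE)
  res <- .window_maps_cpp(as.vector(cm), as.vector(lm), dim(cm),
                          as.integer(window_vox), as.integer(stride_vox))
  gd <- res$grid_dim
  structure(
    list(V = array(res$V, gd),
         chi = array(res$chi, gd),
         valid = array(res$valid, gd),
         centers = list(x = res$centers_x + 1L, y = res$centers_y + 1L,
                        z = res$centers_z + 1L),
         dim = dim(cm),
         window_vox = as.integer(window_vox),
         stride_vox = as.integer(stride_vox)),
    class = "minkowski_grid")
}

# replace invalid grid nodes by the mean of their valid 6-neighbours,
# iterating until all nodes are filled (nearest-valid flood fill)
fill_invalid_grid <- function(g, valid) {
  if (all(valid)) return(g)
  if (!any(valid)) stop("all grid nodes are invalid", call. = FALSE)
  d <- dim(g)
  while (!all(valid)) {
    acc <- array(0, d); cnt <- array(0, d)
    for (ax in 1:3) for (by in c(-1L, 1L)) {
      idx <- lapply(d, seq_len)
      take <- idx
      take[[ax]] <- idx[[ax]] + by
      ok <- take[[ax]] >= 1L & take[[ax]] <= d[ax]
      take[[ax]] <- pmin(pmax(take[[ax]], 1L), d[ax])
      vshift <- valid[take[[1]], take[[2]], take[[3]], drop = FALSE]
      gshift <- g[take[[1]], take[[2]], take[[3]], drop = FALSE]
      # rows pulled from a clamped (out-of-range) index contribute nothing
      if (!all(ok)) {
        sel <- lapply(d, seq_len)
        sel[[ax]] <- which(!ok)
        vshift[sel[[1]], sel[[2]], sel[[3]]] <- FALSE
      }
      w <- vshift & !valid
      acc[w] <- acc[w] + gshift[w]
      cnt[w] <- cnt[w] + 1
    }
    newly <- !valid & cnt > 0
    if (!any(newly)) stop("invalid grid region cannot be filled", call. = FALSE)
    g[newly] <- acc[newly] / cnt[newly]
    valid[newly] <- TRUE
  }
  g
}

#' Interpolate a stride-grid map to the full voxel grid
#'
#' Trilinear interpolation between grid nodes; lung voxels outside the grid
#' hull take the nearest node's value (coordinates are clamped to the hull).
#' Invalid nodes (windows without lung voxels) are first filled from their
#' nearest valid neighbours. Values are returned only inside the lung mask
#' (NA elsewhere).
#'
#' @param grid_map a `minkowski_grid` from [minkowski_window_maps()].
#' @param lung_mask 3D binary mask on the full voxel grid.
#' @param measure `"V"` or `"chi"`.
#' @return 3D numeric array, NA outside `lung_mask`.
#' @export
interpolate_to_grid <- function(grid_map, lung_mask, measure = c("V", "chi")) {
  measure <- match.arg(measure)
  stopifnot(inherits(grid_map, "minkowski_grid"))
  lm <- array(as.logical(lung_mask), dim = dim(lung_mask))
  if (!identical(dim(lm), grid_map$dim)) {
    stop("lung_mask grid does not match the map", call. = FALSE)
  }
  g <- fill_invalid_grid(grid_map[[measure]], grid_map$valid)
  ctr <- grid_map$centers
  d <- dim(lm)
  idx <- which(lm)
  if (length(idx) == 0) stop("lung mask is empty", call. = FALSE)
  coord <- arrayInd(idx, d)

  axis_locate <- function(pos, centers) {
    # clamp outside-hull positions to the terminal nodes
    i0 <- findInterval(pos, centers, all.inside = TRUE)
    c0 <- centers[i0]; c1 <- centers[i0 + 1L]
    t <- (pos - c0) / (c1 - c0)
    t <- pmin(pmax(t, 0), 1)
    list(i0 = i0, t = t)
  }
  if (length(ctr$x) < 2L || length(ctr$y) < 2L || length(ctr$z) < 2L) {
    stop("grid too coarse to interpolate (needs >= 2 nodes per axis)",
         call. = FALSE)
  }
  lx <- axis_locate(coord[, 1], ctr$x)
  ly <- axis_locate(coord[, 2], ctr$y)
  lz <- axis_locate(coord[, 3], ctr$z)
  gd <- dim(g)
  val <- numeric(length(idx))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) lx$t else 1 - lx$t) *
         (if (dy) ly$t else 1 - ly$t) *
         (if (dz) lz$t else 1 - lz$t)
    node <- cbind(lx$i0 + dx, ly$i0 + dy, lz$i0 + dz)
    val <- val + w * g[node]
  }
  out <- array(NA_real_, d)
  out[idx] <- val
  out
}

#' Full tPRM analysis of a PRM map
#'
#' For each requested PRM class, computes the windowed V and chi grids,
#' interpolates them to every lung voxel, and summarises whole-lung means.
#'
#' @param prm a `prm_map` from [classify_voxels()] (or an integer label array
#'   plus `lung_mask`).
#' @param lung_mask lung mask when `prm` is a bare array.
#' @param classes PRM classes to analyse (default Norm and fSAD, the two the
#'   downstream models consume; Emph and PD are available for completeness).
#' @param window_vox,stride_vox window edge and grid step in voxels.
#' @return Object of class `tprm_maps`: list with per-class full-grid fields
#'   `V[[class]]`, `chi[[class]]`, the grids, parameters and
#'   `whole_lung_means` tibble (`class`, `V_mean`, `chi_mean`).
#' @export
tprm_maps <- function(prm, lung_mask = NULL, classes = c("Norm", "fSAD"),
                      window_vox = 21L, stride_vox = 5L) {
  if (inherits(prm, "prm_map")) {
    labels <- prm$labels
    lung_mask <- prm$lung_mask
  } else {
    labels <- prm
    if (is.null(lung_mask)) stop("`lung_mask` required", call. = FALSE)
  }
  classes <- match.arg(classes, prm_classes(), several.ok = TRUE)
  codes <- prm_codes()
  lm <- array(as.logical(lung_mask), dim = dim(lung_mask))
  V <- list(); chi <- list(); grids <- list()
  for (cl in classes) {
    cmask <- array(0L, dim(labels))
    cmask[which(lm)] <- as.integer(labels[which(lm)] == codes[[cl]])
    g <- minkowski_window_maps(cmask, lm, window_vox, stride_vox)
    grids[[cl]] <- g
    V[[cl]] <- interpolate_to_grid(g, lm, "V")
    chi[[cl]] <- interpolate_to_grid(g, lm, "chi")
  }
  out <- structure(
    list(V = V, chi = chi, grids = grids, lung_mask = lm,
         classes = classes, window_vox = as.integer(window_vox),
         stride_vox = as.integer(stride_vox)),
    class = "tprm_maps")
  out$whole_lung_means <- whole_lung_means(out)
  out
}

#' Whole-lung means of interpolated tPRM fields
#'
#' Arithmetic mean of each class's V and chi fields over the lung voxels.
#' The V mean reproduces the class's percent volume divided by 100 (up to
#' grid discretisation), which ties the topological maps back to the
#' classical PRM percent-volume readout.
#'
#' @param tprm a `tprm_maps` object.
#' @param lung_mask optional override mask.
#' @return Tibble with `class`, `V_mean`, `chi_mean`.
#' @export
whole_lung_means <- function(tprm, lung_mask = NULL) {
  stopifnot(inherits(tprm, "tprm_maps"))
  lm <- if (is.null(lung_mask)) tprm$lung_mask else
    array(as.logical(lung_mask), dim = dim(lung_mask))
  idx <- which(lm)
  tibble::tibble(
    class = tprm$classes,
    V_mean = vapply(tprm$classes, function(cl) mean(tprm$V[[cl]][idx]),
                    numeric(1)),
    chi_mean = vapply(tprm$classes, function(cl) mean(tprm$chi[[cl]][idx]),
                      numeric(1)))
}

#' @export
print.tprm_maps <- function(x, ...) {
  cat(sprintf("<tprm_maps> window %d, stride %d\n", x$window_vox, x$stride_vox))
  print(x$whole_lung_means)
  invisible(x)
}
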