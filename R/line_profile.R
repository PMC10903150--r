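# trilinear sampling of a full-grid field at fractional voxel coordinates
sample_field <- function(field, pts) {
  d <- dim(field)
  val <- numeric(nrow(pts))
  base <- floor(pts)
  frac <- pts - base
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- pmin(pmax(base[, 1] + dx, 1), d[1])
    iy <- pmin(pmax(base[, 2] + dy, 1), d[2])
    iz <- pmin(pmax(base[, 3] + dz, 1), d[3])
    w <- (if (dx) frac[, 1] else 1 - frac[, 1]) *
         (if (dy) frac[, 2] else 1 - frac[, 2]) *
         (if (dz) frac[, 3] else 1 - frac[, 3])
    val <- val + w * field[cbind(ix, iy, iz)]
  }
  val
}

#' Spatial line profile between a high- and a low-emphysema point
#'
#' Samples two tPRM fields along the straight segment from `point_hi`
#' (chosen in a high-emphysema region, V_Emph > 0.6) to `point_lo` (low
#' emphysema, V_Emph < 0.2), with the distance axis in centimetres from
#' `point_hi` computed from the voxel dimensions. Sampling is inclusive of
#' both endpoints at steps of one minimum voxel spacing.
#'
#' @param field_a,field_b 3D fields on the same grid (e.g. V_Emph and
#'   V_fSAD); `field_a` is checked against the endpoint selection rule.
#' @param point_hi,point_lo voxel coordinates (length 3, 1-based).
#' @param spacing_mm voxel spacing in mm.
#' @param check_bounds when TRUE, warn (not error) if `field_a` at
#'   `point_hi` is not > 0.6 or at `point_lo` not < 0.2.
#' @return Tibble with `distance_cm`, `value_a`, `value_b`.
#' @export
line_profile <- function(field_a, field_b, point_hi, point_lo, spacing_mm,
                         check_bounds = TRUE) {
  if (!identical(dim(field_a), dim(field_b))) {
    stop("fields must share one grid", call. = FALSE)
  }
  point_hi <- as.numeric(point_hi); point_lo <- as.numeric(point_lo)
  if (length(point_hi) != 3 || length(point_lo) != 3) {
    stop("endpoints must be length-3 voxel coordinates", call. = FALSE)
  }
  d <- dim(field_a)
  for (p in list(point_hi, point_lo)) {
    if (any(p < 1) || any(p > d)) stop("endpoint outside the volume", call. = FALSE)
  }
  if (check_bounds) {
    a_hi <- sample_field(field_a, rbind(point_hi))
    a_lo <- sample_field(field_a, rbind(point_lo))
    if (!is.na(a_hi) && a_hi <= 0.6) {
      warning("point_hi does not satisfy field_a > 0.6", call. = FALSE)
    }
    if (!is.na(a_lo) && a_lo >= 0.2) {
      warning("point_lo does not satisfy field_a < 0.2", call. = FALSE)
    }
  }
  delta_mm <- (point_lo - point_hi) * spacing_mm
  len_mm <- sqrt(sum(delta_mm^2))
  step_mm <- min(spacing_mm)
  n_steps <- max(1L, round(len_mm / step_mm))
  t <- seq(0, 1, length.out = n_steps + 1L)
  pts <- outer(t, point_lo - point_hi) + rep(point_hi, each = length(t))
  tibble::tibble(
    distance_cm = t * len_mm / 10,
    value_a = sample_field(field_a, pts),
    value_b = sample_field(field_b, pts))
}
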