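#' Specification of a paired-CT lung phantom
#'
#' Describes a synthetic torso: an ellipsoidal lung inside a cubic grid,
#' lesion classes planted as unions of spherical pockets, and HU values drawn
#' inside each planted class's admissible joint (inspiration, expiration)
#' HU rectangle so that the PRM classification of a noise-free phantom
#' recovers the planted labels exactly.
#'
#' Two planting modes:
#' * geometry mode (`class_fractions = NULL`): `n_fsad_pockets` fSAD balls of
#'   radius `pocket_radius_vox` are planted; nothing else.
#' * fraction mode (`class_fractions` named): each named non-Norm class is
#'   grown around its pocket centres by nearest-distance ranking until its
#'   target voxel count is met exactly, so percent volumes match the targets
#'   up to rounding.
#'
#' `coalescence` in \[0, 1\] sets the pocket-centre lattice spacing from
#' "disjoint balls" (0: spacing > one diameter, chi = +k) down to an
#' overlapping arrangement that fuses the balls into a mesh with tunnels
#' (1: spacing about 1.55 radii, chi < 0).
#'
#' @param grid_shape integer length-3, each >= 45 (two windows plus stride).
#' @param spacing_mm voxel spacing, mm (default isotropic 0.65 mm, a typical
#'   CT in-plane resolution, so cm-scale distance profiles are meaningful).
#' @param lung_semiaxes_frac ellipsoid semi-axes as fractions of the grid.
#' @param class_fractions named numeric vector of target lung fractions over
#'   `c("Norm","fSAD","Emph","PD")`; entries sum to at most 1; unnamed
#'   remainder is Norm. If `Norm` is given explicitly the entries must sum
#'   to 1.
#' @param n_fsad_pockets,n_emph_pockets,n_pd_pockets pocket counts.
#' @param pocket_radius_vox ball radius in voxels (geometry mode), >= 1.
#' @param coalescence pocket overlap parameter in \[0, 1\].
#' @param pocket_placement `"clustered"` packs the pocket centres around a
#'   random seed site (compact lesion field), `"spread"` scatters them over
#'   the whole lung; both preserve pocket count, radius and hence whole-lung
#'   V and chi, so the pair isolates purely local spatial signal.
#' @param hu_noise_sd Gaussian HU noise sd; class HU rectangles are shrunk by
#'   3 sd (plus a 0.5 HU guard) before sampling, so label recovery is exact
#'   at zero noise and misclassification is controlled otherwise.
#' @param seed integer seed; all phantom randomness flows through it.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 48L),
                         spacing_mm = c(0.65, 0.65, 0.65),
                         lung_semiaxes_frac = c(0.42, 0.42, 0.42),
                         class_fractions = NULL,
                         n_fsad_pockets = 5L,
                         n_emph_pockets = 3L,
                         n_pd_pockets = 2L,
                         pocket_radius_vox = 3,
                         coalescence = 0,
                         pocket_placement = c("clustered", "spread"),
                         hu_noise_sd = 0,
                         seed = 1L) {
  pocket_placement <- match.arg(pocket_placement)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 45L)) {
    stop("grid_shape must be three integers >= 45", call. = FALSE)
  }
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    stop("spacing_mm must be three positive values", call. = FALSE)
  }
  stopifnot_scalar(pocket_radius_vox, "pocket_radius_vox", lo = 1)
  stopifnot_scalar(coalescence, "coalescence", lo = 0, hi = 1)
  stopifnot_scalar(hu_noise_sd, "hu_noise_sd", lo = 0)
  if (!is.null(class_fractions)) {
    cf <- unlist(class_fractions)
    if (is.null(names(cf)) || !all(names(cf) %in% c("Norm", "fSAD", "Emph", "PD"))) {
      stop("class_fractions must be named over Norm/fSAD/Emph/PD", call. = FALSE)
    }
    if (any(cf < 0) || any(cf > 1)) {
      stop("class_fractions must lie in [0, 1]", call. = FALSE)
    }
    if (sum(cf) > 1 + 1e-9) stop("class_fractions must sum to <= 1", call. = FALSE)
    if ("Norm" %in% names(cf) && abs(sum(cf) - 1) > 1e-6) {
      stop("when Norm is given explicitly, class_fractions must sum to 1",
           call. = FALSE)
    }
    class_fractions <- as.list(cf)
  }
  structure(
    list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
         lung_semiaxes_frac = as.numeric(lung_semiaxes_frac),
         class_fractions = class_fractions,
         n_fsad_pockets = as.integer(n_fsad_pockets),
         n_emph_pockets = as.integer(n_emph_pockets),
         n_pd_pockets = as.integer(n_pd_pockets),
         pocket_radius_vox = as.numeric(pocket_radius_vox),
         coalescence = as.numeric(coalescence),
         pocket_placement = pocket_placement,
         hu_noise_sd = as.numeric(hu_noise_sd),
         seed = as.integer(seed)),
    class = "phantom_spec")
}

# admissible joint HU rectangle per class, shrunk by a margin so draws stay
# strictly inside the class region of the PRM decision rules
hu_rectangles <- function(margin) {
  list(
    Norm = c(insp_lo = -950 + margin, insp_hi = -810 - margin,
             exp_lo = -856 + margin, exp_hi = -250 - margin),
    fSAD = c(insp_lo = -950 + margin, insp_hi = -810 - margin,
             exp_lo = -1000 + margin, exp_hi = -856 - margin),
    Emph = c(insp_lo = -1000 + margin, insp_hi = -950 - margin,
             exp_lo = -1000 + margin, exp_hi = -856 - margin),
    PD = c(insp_lo = -810 + margin, insp_hi = -250 - margin,
           exp_lo = -1000 + margin, exp_hi = -250 - margin))
}

#' Synthesise paired HU volumes from a planted label volume
#'
#' For each labelled lung voxel, draws (inspiration, expiration) HU uniformly
#' inside the class's admissible rectangle shrunk by `3 * hu_noise_sd + 0.5`
#' HU, then adds independent Gaussian noise. At zero noise every voxel pair
#' lies strictly inside its class region, so [classify_voxels()] recovers the
#' planted labels exactly.
#'
#' @param labels 3D integer array coded per [prm_codes()] (NA outside lung).
#' @param lung_mask 3D logical mask.
#' @param spacing_mm voxel spacing, mm.
#' @param hu_noise_sd Gaussian noise sd in HU.
#' @param seed integer seed.
#' @return A [paired_ct()] object.
#' @export
phantom_from_labels <- function(labels, lung_mask, spacing_mm,
                                hu_noise_sd = 0, seed = 1L) {
  margin <- 3 * hu_noise_sd + 0.5
  rects <- hu_rectangles(margin)
  if (any(vapply(rects, function(r) r["insp_hi"] <= r["insp_lo"] ||
                   r["exp_hi"] <= r["exp_lo"], logical(1)))) {
    stop("hu_noise_sd too large: shrunk HU rectangles are empty", call. = FALSE)
  }
  set.seed(as.integer(seed))
  d <- dim(labels)
  insp <- array(0, d); exp_ <- array(0, d)
  codes <- prm_codes()
  for (cl in c("Norm", "fSAD", "Emph", "PD")) {
    idx <- which(lung_mask & !is.na(labels) & labels == codes[[cl]])
    if (length(idx) == 0) next
    r <- rects[[cl]]
    insp[idx] <- runif(length(idx), r["insp_lo"], r["insp_hi"]) +
      rnorm(length(idx), 0, hu_noise_sd)
    exp_[idx] <- runif(length(idx), r["exp_lo"], r["exp_hi"]) +
      rnorm(length(idx), 0, hu_noise_sd)
  }
  paired_ct(insp, exp_, lung_mask, spacing_mm)
}

# fraction of a unit cube covered by balls of radius `ratio` centred at its
# corners (periodic lattice coverage), by grid quadrature
unit_cell_coverage <- function(ratio, n = 40L) {
  g <- (seq_len(n) - 0.5) / n
  dx <- pmin(g, 1 - g)
  d2 <- outer(outer(dx^2, dx^2, "+"), dx^2, "+")
  mean(d2 <= ratio^2)
}

# lattice pocket centres for one class inside the ellipsoidal lung.
# `spacing` encodes the coalescence regime: > one ball diameter gives
# disjoint pockets, about 1.55 radii fuses them into a mesh with tunnels.
# Spacing is capped so k sites always fit the lung (a fraction target that
# cannot be met by disjoint balls degrades gracefully into partial overlap).
place_pockets <- function(k, spacing, centre, semiaxes,
                          other_centres, other_clearance, what,
                          placement = "clustered") {
  lung_vol <- 4 / 3 * pi * prod(pmax(semiaxes - 1, 1))
  a_cap <- (0.95 * lung_vol / k)^(1 / 3)
  spacing <- max(2, min(spacing, a_cap))
  eff_semi <- pmax(semiaxes - 1, 0.5)
  build_sites <- function(spacing) {
    nsteps <- ceiling(max(semiaxes) / spacing)
    off <- seq(-nsteps, nsteps) * spacing
    sites <- as.matrix(expand.grid(x = centre[1] + off, y = centre[2] + off,
                                   z = centre[3] + off))
    inside <- rowSums(sweep(sweep(sites, 2, centre), 2, eff_semi, "/")^2) <= 1
    sites[inside, , drop = FALSE]
  }
  sites <- build_sites(spacing)
  # a target that cannot be met at the requested spacing degrades into a
  # denser (more overlapping) arrangement rather than failing outright
  while (nrow(sites) < k && spacing > 2) {
    spacing <- max(2, spacing * 0.85)
    sites <- build_sites(spacing)
  }
  if (length(other_centres)) {
    oc <- do.call(rbind, other_centres)
    clear <- rep(other_clearance,
                 vapply(other_centres, nrow, integer(1)))
    keep <- rep(TRUE, nrow(sites))
    for (i in seq_len(nrow(oc))) {
      dd <- sqrt(rowSums(sweep(sites, 2, oc[i, ])^2))
      keep <- keep & dd > clear[i]
    }
    # clearance from other classes is best-effort: selection is restricted to
    # still-unassigned voxels, so overlapping pockets cannot corrupt labels
    if (sum(keep) >= k) sites <- sites[keep, , drop = FALSE]
  }
  if (nrow(sites) < k) {
    stop(sprintf("class fractions infeasible for geometry: only %d of %d %s pockets fit",
                 nrow(sites), k, what), call. = FALSE)
  }
  if (placement == "spread") {
    return(sites[sample.int(nrow(sites), k), , drop = FALSE])
  }
  seed_site <- sites[sample.int(nrow(sites), 1L), ]
  dd <- rowSums(sweep(sites, 2, seed_site)^2) + runif(nrow(sites), 0, 1e-6)
  sites[order(dd)[seq_len(k)], , drop = FALSE]
}

#' Generate a paired-CT phantom with known PRM ground truth
#'
#' Builds an ellipsoidal lung, plants the requested PRM classes as pocket
#' structures (see [phantom_spec()]), synthesises HU volumes consistent with
#' the planted labels, and returns both the paired CT and the ground truth.
#'
#' @param spec a [phantom_spec()].
#' @return Object of class `tprm_phantom`: list with `ct` ([paired_ct()]),
#'   `truth` (3D integer label array, NA outside the lung), `centers`
#'   (per-class pocket centres) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$grid_shape
  centre <- (d + 1) / 2
  semiaxes <- spec$lung_semiaxes_frac * d
  coord <- arrayInd(seq_len(prod(d)), d)
  ell <- rowSums(sweep(sweep(coord, 2, centre), 2, semiaxes, "/")^2)
  lung <- array(ell <= 1, d)
  n_lung <- sum(lung)
  lung_idx <- which(lung)
  lung_coord <- coord[lung_idx, , drop = FALSE]

  codes <- prm_codes()
  labels <- array(NA_integer_, d)
  labels[lung_idx] <- codes[["Norm"]]
  assigned <- rep(FALSE, n_lung)

  cf <- spec$class_fractions
  pocket_n <- c(fSAD = spec$n_fsad_pockets, Emph = spec$n_emph_pockets,
                PD = spec$n_pd_pockets)
  co <- spec$coalescence
  plant <- list()
  if (is.null(cf)) {
    if (spec$n_fsad_pockets > 0) {
      r <- spec$pocket_radius_vox
      plant$fSAD <- list(
        target = NA_integer_, radius = r,
        spacing = (1 - co) * (2 * r + 2) + co * (1.55 * r))
    }
  } else {
    # mesh regime: balls of radius ~0.62 lattice spacings leave tunnels at
    # the face diagonals; the coverage constant converts a voxel target into
    # the lattice spacing that realises that regime
    cov_mesh <- unit_cell_coverage(0.62)
    for (cl in c("fSAD", "Emph", "PD")) {
      frac <- cf[[cl]]
      if (is.null(frac) || frac <= 0) next
      target <- round(frac * n_lung)
      if (target < 1) next
      if (target > n_lung) {
        stop("class fractions infeasible for geometry: lung too small",
             call. = FALSE)
      }
      k <- max(1L, pocket_n[[cl]])
      r0 <- (3 * target / (4 * pi * k))^(1 / 3) # disjoint-ball radius
      a0 <- 2 * r0 + 2                          # disjoint spacing
      a1 <- (target / (k * cov_mesh))^(1 / 3)   # mesh spacing
      plant[[cl]] <- list(
        target = target,
        radius = (1 - co) * r0 + co * 0.62 * a1,
        spacing = (1 - co) * a0 + co * a1)
    }
  }

  centres <- list()
  planted_radius <- numeric(0)
  for (cl in names(plant)) {
    k <- max(1L, pocket_n[[cl]])
    info <- plant[[cl]]
    ctrs <- place_pockets(k, info$spacing, centre, semiaxes, centres,
                          planted_radius + info$radius + 2, cl,
                          placement = spec$pocket_placement)
    centres[[cl]] <- ctrs
    planted_radius <- c(planted_radius, info$radius)
    d2 <- rep(Inf, n_lung)
    for (i in seq_len(nrow(ctrs))) {
      d2 <- pmin(d2, rowSums(sweep(lung_coord, 2, ctrs[i, ])^2))
    }
    if (is.na(info$target)) {
      sel <- which(!assigned & d2 <= info$radius^2)
    } else {
      cand <- which(!assigned)
      if (length(cand) < info$target) {
        stop("class fractions infeasible for geometry: lung too small",
             call. = FALSE)
      }
      sel <- cand[order(d2[cand])[seq_len(info$target)]]
    }
    labels[lung_idx[sel]] <- codes[[cl]]
    assigned[sel] <- TRUE
  }

  ct <- phantom_from_labels(labels, lung, spec$spacing_mm,
                            hu_noise_sd = spec$hu_noise_sd,
                            seed = child_seeds(spec$seed, 1L))
  structure(list(ct = ct, truth = labels, centers = centres, spec = spec),
            class = "tprm_phantom")
}

#' @export
print.tprm_phantom <- function(x, ...) {
  cat("<tprm_phantom>\n")
  print(x$ct)
  tab <- table(factor(x$truth[x$ct$lung_mask], levels = prm_codes(),
                      labels = prm_classes()))
  for (nm in names(tab)) {
    if (tab[[nm]] > 0) cat(sprintf("  planted %-6s %8d voxels (%.1f%%)\n", nm,
                                   tab[[nm]], 100 * tab[[nm]] / sum(tab)))
  }
  invisible(x)
}

#' Library of binary shapes with known Euler characteristics
#'
#' Oracle fixtures for the chi computation: a single voxel (chi = 1), a solid
#' cube (1), a one-slice square ring (an annulus, 0), a hollow 3x3x3 shell (a
#' topological sphere, 2) and a pair of disjoint voxels (2, additivity).
#' Each shape is embedded in a background margin of one voxel.
#'
#' @return Named list; each element has `mask` (3D logical) and `chi`.
#' @export
shape_phantoms <- function() {
  emb <- function(m) {
    d <- dim(m)
    out <- array(FALSE, d + 2L)
    out[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <- m
    out
  }
  single <- array(TRUE, c(1L, 1L, 1L))
  cube <- array(TRUE, c(3L, 3L, 3L))
  ring <- array(TRUE, c(3L, 3L, 1L)); ring[2, 2, 1] <- FALSE
  shell <- array(TRUE, c(3L, 3L, 3L)); shell[2, 2, 2] <- FALSE
  pair <- array(FALSE, c(3L, 1L, 1L)); pair[c(1, 3), 1, 1] <- TRUE
  list(
    single_voxel = list(mask = emb(single), chi = 1L),
    solid_cube = list(mask = emb(cube), chi = 1L),
    ring = list(mask = emb(ring), chi = 0L),
    hollow_shell = list(mask = emb(shell), chi = 2L),
    disjoint_pair = list(mask = emb(pair), chi = 2L))
}

#' Serialise/deserialise a phantom spec as JSON
#' @param spec a [phantom_spec()].
#' @param json JSON string from `phantom_spec_to_json()`.
#' @return JSON string / `phantom_spec`.
#' @export
phantom_spec_to_json <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname phantom_spec_to_json
#' @export
phantom_spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  do.call(phantom_spec, x)
}
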