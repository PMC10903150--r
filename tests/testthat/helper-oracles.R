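# Independent brute-force Euler characteristic: enumerate every vertex, edge,
# face and cube of the union of closed unit voxels by explicit cell keys and
# count chi = nV - nE + nF - nC. Deliberately shares no code with the
# package's lookup-table kernel.
chi_bruteforce <- function(mask) {
  co <- which(mask != 0, arr.ind = TRUE)
  if (!nrow(co)) return(0L)
  key3 <- function(a, b, c) paste(a, b, c, sep = ",")
  uniq_n <- function(keys) length(unique(keys))

  verts <- unlist(lapply(0:7, function(b) {
    dx <- b %% 2; dy <- (b %/% 2) %% 2; dz <- b %/% 4
    key3(co[, 1] + dx, co[, 2] + dy, co[, 3] + dz)
  }))
  ex <- unlist(lapply(0:3, function(b) {
    dy <- b %% 2; dz <- b %/% 2
    key3(co[, 1], co[, 2] + dy, co[, 3] + dz)
  }))
  ey <- unlist(lapply(0:3, function(b) {
    dx <- b %% 2; dz <- b %/% 2
    key3(co[, 1] + dx, co[, 2], co[, 3] + dz)
  }))
  ez <- unlist(lapply(0:3, function(b) {
    dx <- b %% 2; dy <- b %/% 2
    key3(co[, 1] + dx, co[, 2] + dy, co[, 3])
  }))
  fx <- unlist(lapply(0:1, function(dx) key3(co[, 1] + dx, co[, 2], co[, 3])))
  fy <- unlist(lapply(0:1, function(dy) key3(co[, 1], co[, 2] + dy, co[, 3])))
  fz <- unlist(lapply(0:1, function(dz) key3(co[, 1], co[, 2], co[, 3] + dz)))

  uniq_n(verts) - (uniq_n(ex) + uniq_n(ey) + uniq_n(ez)) +
    (uniq_n(fx) + uniq_n(fy) + uniq_n(fz)) - nrow(co)
}

# random blob volume: union of random balls inside a box, reproducible
random_blob_volume <- function(dim, n_balls, r_range, seed) {
  set.seed(seed)
  out <- array(FALSE, dim)
  co <- arrayInd(seq_len(prod(dim)), dim)
  for (i in seq_len(n_balls)) {
    ctr <- runif(3, 1, dim)
    r <- runif(1, r_range[1], r_range[2])
    out[rowSums(sweep(co, 2, ctr)^2) <= r^2] <- TRUE
  }
  out
}

# planted-class binary mask from a phantom truth volume
class_mask_of <- function(phantom, class) {
  codes <- prm_codes()
  m <- array(0L, dim(phantom$truth))
  m[which(phantom$truth == codes[[class]])] <- 1L
  m
}

# a small fully-labelled zero-noise phantom reused across tests; pockets are
# spread over the lung, the representative arrangement of distributed fSAD
fixture_phantom <- function(seed = 7) {
  generate_phantom(phantom_spec(
    class_fractions = list(fSAD = 0.25, Emph = 0.08, PD = 0.12),
    n_fsad_pockets = 12L, coalescence = 0.3, pocket_placement = "spread",
    hu_noise_sd = 0, seed = seed))
}
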