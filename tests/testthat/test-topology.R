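test_that("euler characteristic matches brute-force cell counting on canonical shapes", {
  for (s in shape_phantoms()) {
    expect_identical(euler_characteristic(s$mask), as.integer(s$chi))
    expect_identical(chi_bruteforce(s$mask), as.integer(s$chi))
  }
})

test_that("euler characteristic agrees with the brute-force oracle on random volumes", {
  for (seed in 1:12) {
    v <- random_blob_volume(c(9, 8, 7), n_balls = sample(1:6, 1),
                            r_range = c(1, 3), seed = seed)
    expect_identical(euler_characteristic(v), as.integer(chi_bruteforce(v)),
                     info = paste("seed", seed))
  }
})

test_that("chi is additive over disjoint unions and translation invariant", {
  a <- array(FALSE, c(12, 12, 12))
  a[2:4, 2:4, 2:4] <- TRUE # solid block, chi 1
  b <- a
  b[8:10, 8:10, 2:4] <- TRUE # plus disjoint second block
  expect_identical(euler_characteristic(b),
                   euler_characteristic(a) + 1L)
  shifted <- array(FALSE, c(12, 12, 12))
  shifted[6:8, 7:9, 8:10] <- TRUE
  expect_identical(euler_characteristic(shifted), euler_characteristic(a))
})

test_that("euler characteristic rejects non-binary input", {
  expect_error(euler_characteristic(array(2, c(3, 3, 3))), "binary")
  expect_error(euler_characteristic(matrix(1, 3, 3)), "3D")
})

test_that("windowed maps: class equal to lung gives V = 1 and block interior chi", {
  lung <- array(0L, c(30, 30, 30))
  lung[4:27, 4:27, 4:27] <- 1L
  g <- minkowski_window_maps(lung, lung, window_vox = 11, stride_vox = 5)
  expect_true(all(g$V[g$valid] == 1))
  # an interior window is a solid box: chi = 1 over the full window count
  ic <- which(g$centers$x == 16)
  expect_equal(g$chi[ic, ic, ic], 1 / 11^3)
})

test_that("windowed maps: empty class gives V = 0 and chi = 0", {
  lung <- array(0L, c(25, 25, 25)); lung[3:23, 3:23, 3:23] <- 1L
  cls <- array(0L, dim(lung))
  g <- minkowski_window_maps(cls, lung, window_vox = 11, stride_vox = 5)
  expect_true(all(g$V[g$valid] == 0))
  expect_true(all(g$chi[g$valid] == 0))
})

test_that("an isolated class voxel contributes chi = 1 / masked window count", {
  lung <- array(1L, c(41, 41, 41))
  cls <- array(0L, dim(lung)); cls[21, 21, 21] <- 1L
  # stride 20 puts a grid node at voxel 21, whose window is a full 21^3 box
  g <- minkowski_window_maps(cls, lung, window_vox = 21, stride_vox = 20)
  expect_equal(g$chi[2, 2, 2], 1 / 21^3)
  expect_equal(g$V[2, 2, 2], 1 / 21^3)
})

test_that("windowed chi equals brute-force enumeration on every window", {
  vol <- random_blob_volume(c(31, 31, 31), n_balls = 10, r_range = c(2, 5),
                            seed = 99)
  lung <- array(1L, dim(vol))
  cls <- array(as.integer(vol), dim(vol))
  g <- minkowski_window_maps(cls, lung, window_vox = 21, stride_vox = 5)
  h <- 10L
  d <- dim(vol)
  for (ic in seq_along(g$centers$x))
    for (jc in seq_along(g$centers$y))
      for (kc in seq_along(g$centers$z)) {
        xs <- max(1, g$centers$x[ic] - h):min(d[1], g$centers$x[ic] + h)
        ys <- max(1, g$centers$y[jc] - h):min(d[2], g$centers$y[jc] + h)
        zs <- max(1, g$centers$z[kc] - h):min(d[3], g$centers$z[kc] + h)
        sub <- vol[xs, ys, zs, drop = FALSE]
        expected <- chi_bruteforce(sub) / length(sub)
        expect_equal(g$chi[ic, jc, kc], expected,
                     info = sprintf("window (%d,%d,%d)", ic, jc, kc))
      }
})

test_that("V of complementary classes sums to one within each window", {
  ph <- fixture_phantom()
  lung <- array(as.integer(ph$ct$lung_mask), dim(ph$truth))
  grids <- lapply(c("Norm", "fSAD", "Emph", "PD"), function(cl) {
    minkowski_window_maps(class_mask_of(ph, cl), lung)
  })
  tot <- Reduce(`+`, lapply(grids, function(g) g$V))
  valid <- grids[[1]]$valid
  expect_true(all(abs(tot[valid] - 1) < 1e-12))
})

test_that("interpolation preserves node values, constants and midpoints", {
  lung <- array(1L, c(25, 25, 25))
  cls <- array(0L, dim(lung)); cls[1:12, , ] <- 1L
  g <- minkowski_window_maps(cls, lung, window_vox = 5, stride_vox = 6)
  f <- interpolate_to_grid(g, lung, "V")
  # node values preserved exactly
  for (ic in seq_along(g$centers$x)) {
    expect_equal(f[g$centers$x[ic], g$centers$y[1], g$centers$z[1]],
                 g$V[ic, 1, 1])
  }
  # constant grid -> constant field
  gc <- g; gc$V[] <- 0.4
  fc <- interpolate_to_grid(gc, lung, "V")
  expect_true(all(abs(fc - 0.4) < 1e-12))
  # linear midpoint between two nodes
  gm <- g; gm$V[] <- 0; gm$V[2, , ] <- 1 # nodes at x = 1, 7, 13, ...
  fm <- interpolate_to_grid(gm, lung, "V")
  expect_equal(fm[4, 10, 10], 0.5)
})

test_that("whole-lung V means reproduce percent volumes on zero-noise phantoms", {
  ph <- fixture_phantom()
  prm <- classify_voxels(ph$ct)
  tm <- tprm_maps(prm, classes = c("Norm", "fSAD", "Emph", "PD"))
  wl <- tm$whole_lung_means
  pv <- prm$percent_volume
  for (cl in wl$class) {
    expect_lt(abs(wl$V_mean[wl$class == cl] -
                    pv$percent[pv$class == cl] / 100), 0.02)
  }
})

test_that("whole-lung chi mean is positive for sparse pockets, negative for a mesh", {
  sparse <- generate_phantom(phantom_spec(
    class_fractions = list(fSAD = 0.08), n_fsad_pockets = 10L,
    coalescence = 0, seed = 11))
  mesh <- generate_phantom(phantom_spec(
    class_fractions = list(fSAD = 0.25), n_fsad_pockets = 30L,
    coalescence = 1, seed = 12))
  # raw chi of the planted masks confirms the regimes independently
  expect_identical(euler_characteristic(class_mask_of(sparse, "fSAD")), 10L)
  expect_lt(euler_characteristic(class_mask_of(mesh, "fSAD")), 0L)
  tms <- tprm_maps(classify_voxels(sparse$ct), classes = "fSAD")
  tmm <- tprm_maps(classify_voxels(mesh$ct), classes = "fSAD")
  expect_gt(tms$whole_lung_means$chi_mean, 0)
  expect_lt(tmm$whole_lung_means$chi_mean, 0)
})
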