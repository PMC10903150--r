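# build a paired_ct holding specific (insp, exp) HU pairs in a tiny lung
ct_with_pairs <- function(pairs) {
  n <- nrow(pairs)
  d <- c(max(4, n), 4, 4)
  insp <- array(0, d); exp_ <- array(0, d)
  mask <- array(FALSE, d)
  for (i in seq_len(n)) {
    insp[i, 1, 1] <- pairs[i, 1]
    exp_[i, 1, 1] <- pairs[i, 2]
    mask[i, 1, 1] <- TRUE
  }
  paired_ct(insp, exp_, mask, c(1, 1, 1))
}

test_that("PRM thresholds classify canonical HU pairs correctly", {
  pairs <- rbind(
    c(-900, -850), # Norm: exp >= -856
    c(-900, -870), # fSAD: exp < -856
    c(-960, -900), # Emph
    c(-700, -600), # PD
    c(-960, -800), # indeterminate -> Unclassified
    c(-200, -300)) # out of HU range -> Unclassified
  labels <- classify_voxels(ct_with_pairs(pairs))$labels
  got <- labels[cbind(1:6, 1, 1)]
  codes <- prm_codes()
  expect_identical(got, unname(codes[c("Norm", "fSAD", "Emph", "PD",
                                       "Unclassified", "Unclassified")]))
})

test_that("threshold boundary values follow the printed inequalities literally", {
  pairs <- rbind(
    c(-950, -900), # insp exactly -950 satisfies no rule
    c(-810, -850), # insp exactly -810 is Norm-side (<= -810)
    c(-810, -860), # ... and fSAD-side with exp < -856
    c(-900, -856), # exp exactly -856 is Norm (>= -856)
    c(-1000, -1000), # extreme but in range: Emph
    c(-250, -250)) # boundary of the HU range, insp > -810: PD
  labels <- classify_voxels(ct_with_pairs(pairs))$labels
  got <- labels[cbind(1:6, 1, 1)]
  codes <- prm_codes()
  expect_identical(got, unname(codes[c("Unclassified", "Norm", "fSAD",
                                       "Norm", "Emph", "PD")]))
})

test_that("every lung voxel receives exactly one of the five labels", {
  ph <- generate_phantom(phantom_spec(class_fractions = list(fSAD = 0.3),
                                      hu_noise_sd = 6, seed = 9))
  prm <- classify_voxels(ph$ct)
  lab <- prm$labels[ph$ct$lung_mask]
  expect_false(anyNA(lab))
  expect_true(all(lab %in% prm_codes()))
  expect_true(all(is.na(prm$labels[!ph$ct$lung_mask])))
})

test_that("percent volumes use the whole lung as denominator", {
  # 10-voxel lung: 5 Norm, 3 fSAD, 2 Emph
  pairs <- rbind(matrix(rep(c(-900, -800), 5), ncol = 2, byrow = TRUE),
                 matrix(rep(c(-900, -880), 3), ncol = 2, byrow = TRUE),
                 matrix(rep(c(-970, -900), 2), ncol = 2, byrow = TRUE))
  pv <- classify_voxels(ct_with_pairs(pairs))$percent_volume
  expect_equal(pv$percent[pv$class %in% c("Norm", "fSAD", "Emph", "PD")],
               c(50, 30, 20, 0))
  # 2 Unclassified + 8 Norm: Norm percent is 80, not 100
  pairs2 <- rbind(matrix(rep(c(-900, -800), 8), ncol = 2, byrow = TRUE),
                  matrix(rep(c(-960, -800), 2), ncol = 2, byrow = TRUE))
  pv2 <- classify_voxels(ct_with_pairs(pairs2))$percent_volume
  expect_equal(pv2$percent[pv2$class == "Norm"], 80)
  expect_equal(pv2$n_voxels[pv2$class == "Unclassified"], 2L)
})

test_that("percent volumes are invariant to voxel order and spacing", {
  ph <- fixture_phantom()
  prm <- classify_voxels(ph$ct)
  perm <- sample(which(ph$ct$lung_mask))
  counts <- table(prm$labels[perm])
  expect_equal(as.integer(counts[as.character(prm_codes()[c("Norm", "fSAD", "Emph", "PD")])]),
               prm$percent_volume$n_voxels[1:4],
               ignore_attr = TRUE)
  ct2 <- paired_ct(ph$ct$insp_hu, ph$ct$exp_hu, ph$ct$lung_mask, c(2, 2, 2))
  expect_equal(classify_voxels(ct2)$percent_volume$percent,
               prm$percent_volume$percent)
})

test_that("shape mismatches and empty masks are rejected", {
  a <- array(0, c(4, 4, 4)); b <- array(0, c(4, 4, 5))
  expect_error(paired_ct(a, b, array(TRUE, dim(a)), c(1, 1, 1)), "grid")
  expect_error(paired_ct(a, a, array(FALSE, dim(a)), c(1, 1, 1)), "empty")
})

test_that("qc flags erroneous and implausible volume changes", {
  ph <- generate_phantom(phantom_spec(seed = 4))
  expect_true(qc_flag(ph$ct, insp_volume_l = 5, exp_volume_l = 3)$pass)
  f1 <- qc_flag(ph$ct, insp_volume_l = 3, exp_volume_l = 3.5)
  expect_false(f1$pass)
  expect_match(f1$reason, "erroneous volume change")
  f2 <- qc_flag(ph$ct, insp_volume_l = 5, exp_volume_l = 0.2)
  expect_false(f2$pass)
  expect_match(f2$reason, "implausible")
  # equal mask-derived volumes fail by construction
  expect_false(qc_flag(ph$ct)$pass)
})
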