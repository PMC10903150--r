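test_that("pure-Norm zero-noise phantom classifies as 100% Norm", {
  ph <- generate_phantom(phantom_spec(class_fractions = list(Norm = 1.0),
                                      hu_noise_sd = 0, seed = 2))
  prm <- classify_voxels(ph$ct)
  pv <- prm$percent_volume
  expect_equal(pv$percent[pv$class == "Norm"], 100)
})

test_that("disjoint pockets: planted count equals the fSAD mask's chi", {
  ph <- generate_phantom(phantom_spec(n_fsad_pockets = 5L,
                                      pocket_radius_vox = 3,
                                      coalescence = 0, seed = 3))
  m <- class_mask_of(ph, "fSAD")
  expect_identical(euler_characteristic(m), 5L)
  # components are disjoint: each pocket is one ball
  expect_identical(chi_bruteforce(m), 5L)
})

test_that("fraction targets are met to within discretisation", {
  ph <- generate_phantom(phantom_spec(
    class_fractions = list(Norm = 0.6, fSAD = 0.3, Emph = 0.1),
    hu_noise_sd = 0, seed = 7))
  pv <- classify_voxels(ph$ct)$percent_volume
  expect_lt(abs(pv$percent[pv$class == "Norm"] - 60), 2)
  expect_lt(abs(pv$percent[pv$class == "fSAD"] - 30), 2)
  expect_lt(abs(pv$percent[pv$class == "Emph"] - 10), 2)
})

test_that("zero-noise phantoms are recovered voxel-exactly; HU stay in range", {
  ph <- fixture_phantom()
  prm <- classify_voxels(ph$ct)
  lung <- ph$ct$lung_mask
  expect_true(all(prm$labels[lung] == ph$truth[lung]))
  expect_true(all(ph$ct$insp_hu[lung] >= -1000 & ph$ct$insp_hu[lung] <= -250))
  expect_true(all(ph$ct$exp_hu[lung] >= -1000 & ph$ct$exp_hu[lung] <= -250))
})

test_that("phantom generation is deterministic under its seed", {
  s <- phantom_spec(class_fractions = list(fSAD = 0.2), seed = 31,
                    hu_noise_sd = 4)
  p1 <- generate_phantom(s); p2 <- generate_phantom(s)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$ct$insp_hu, p2$ct$insp_hu)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(grid_shape = c(30, 48, 48)), ">= 45")
  expect_error(phantom_spec(class_fractions = list(fSAD = 0.8, PD = 0.5)),
               "sum")
  expect_error(phantom_spec(class_fractions = list(Norm = 0.5, fSAD = 0.2)),
               "sum to 1")
  expect_error(phantom_spec(pocket_radius_vox = 0), "pocket_radius_vox")
  expect_error(generate_phantom(phantom_spec(hu_noise_sd = 20,
                                             class_fractions = list(Emph = 0.1))),
               "hu_noise_sd too large")
})

test_that("phantom spec round-trips through JSON", {
  s <- phantom_spec(class_fractions = list(fSAD = 0.22, Emph = 0.05),
                    n_fsad_pockets = 9L, coalescence = 0.4,
                    hu_noise_sd = 3, seed = 77)
  s2 <- phantom_spec_from_json(phantom_spec_to_json(s))
  expect_equal(unclass(s2), unclass(s))
  expect_identical(generate_phantom(s)$truth, generate_phantom(s2)$truth)
})

test_that("cohort generator honours counts, labels and effect-size contract", {
  cs <- cohort_spec(n_subjects = 100, fast_fraction = 0.34, effect_size = 0,
                    seed = 5)
  sim <- generate_cohort(cs)
  co <- sim$cohort
  expect_equal(sum(co$progressor == "fast"), 34)
  # labels reproduce exactly under delta_fev1
  lab <- delta_fev1(co$fev1_l, co$fev1_y5_l)$progressor
  expect_identical(lab, co$progressor)
  expect_true(all(co$delta_fev1_ml_yr[co$progressor == "fast"] <= -60 + 1e-9))
  expect_true(all(co$delta_fev1_ml_yr[co$progressor == "slow"] > -60))
  # gold grades consistent with drawn spirometry
  expect_identical(gold_classify(co$fev1_pct_pred, co$fev1_fvc_ratio),
                   co$gold_class)
  # effect size 0: phantom parameter distributions identical between classes
  expect_gt(stats::t.test(fsad_fraction ~ progressor, data = co)$p.value, 0.01)
})

test_that("cohort spec round-trips through JSON", {
  cs <- cohort_spec(n_subjects = 12, effect_size = 2, fast_fraction = 0.25,
                    seed = 3)
  cs2 <- cohort_spec_from_json(cohort_spec_to_json(cs))
  expect_equal(unclass(cs2), unclass(cs))
})
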