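test_that("stratified split reproduces per-class rounding exactly", {
  labs <- c(rep("fast", 1516), rep("slow", 2967))
  sp <- stratified_split(labs, 0.35, seed = 1)
  expect_equal(sum(labs[sp$train] == "fast"), 531)
  expect_equal(sum(labs[sp$train] == "slow"), 1038)
  expect_equal(sum(labs[sp$test] == "fast"), 985)
  expect_equal(sum(labs[sp$test] == "slow"), 1929)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labs))
  sp2 <- stratified_split(rep(c("a", "b"), each = 10), 0.5, seed = 2)
  expect_equal(length(sp2$train), 10)
})

test_that("patch extraction is deterministic, in-lung and contract-complete", {
  ph <- fixture_phantom()
  tm <- tprm_maps(classify_voxels(ph$ct), classes = c("Norm", "fSAD"))
  p1 <- extract_patches(tm, n_patches = 100, patch_edge_vox = 7, seed = 5)
  p2 <- extract_patches(tm, n_patches = 100, patch_edge_vox = 7, seed = 5)
  expect_identical(p1$X, p2$X)
  expect_identical(p1$locations, p2$locations)
  expect_equal(ncol(p1$X), 100)
  expect_equal(nrow(p1$X), 4 * 7^3)
  # every patch >= 50% in lung
  lung <- tm$lung_mask
  for (i in seq_len(nrow(p1$locations))) {
    ctr <- p1$locations[i, ]
    blk <- lung[(ctr[1] - 3):(ctr[1] + 3), (ctr[2] - 3):(ctr[2] + 3),
                (ctr[3] - 3):(ctr[3] + 3)]
    expect_gte(mean(blk), 0.5)
  }
  # constant fields give identical patch vectors
  flds <- list(a = array(2, dim(lung)), b = array(-1, dim(lung)))
  pc <- extract_patches(flds, lung, n_patches = 10, patch_edge_vox = 5, seed = 1)
  expect_equal(max(apply(pc$X, 1, stats::sd)), 0)
  expect_error(extract_patches(flds, array(1L, c(4, 4, 4)), patch_edge_vox = 21),
               "too small")
})

test_that("dictionaries reconstruct representable data and honour n_iter = 0", {
  set.seed(3)
  Q <- qr.Q(qr(matrix(rnorm(64 * 4), 64, 4))) # 4 orthonormal atoms
  X <- Q %*% matrix(rnorm(4 * 60), 4, 60)     # spanned exactly
  fit <- tprm:::learn_dictionary(X, n_atoms = 4, sparsity = 4, n_iter = 15,
                                 seed = 1)
  code <- tprm:::omp_code(fit$D, X, 4)
  expect_lt(sum(code$err) / sum(X^2), 1e-3)
  # n_iter = 0: dictionary is made of unit-normalised training patches
  fit0 <- tprm:::learn_dictionary(X, n_atoms = 4, sparsity = 2, n_iter = 0,
                                  seed = 9)
  expect_equal(colSums(fit0$D^2), rep(1, 4), tolerance = 1e-12)
  expect_length(fit0$objective, 0)
  expect_error(tprm:::learn_dictionary(X, n_atoms = 100, sparsity = 2,
                                       n_iter = 1, seed = 1), "exceed")
})

test_that("dictionary-learning objective is non-increasing over iterations", {
  set.seed(11)
  X <- matrix(rnorm(80 * 200), 80, 200) +
    outer(rnorm(80), rep(1, 200)) # shared structure plus noise
  fit <- tprm:::learn_dictionary(X, n_atoms = 20, sparsity = 3, n_iter = 12,
                                 seed = 4)
  expect_true(all(diff(fit$objective) <= 1e-8 * fit$objective[1]))
})

test_that("well-separated patch populations are classified by residual", {
  set.seed(21)
  p <- 40
  # the classes live in different low-dimensional subspaces (sparse coding is
  # sign-invariant, so a mean shift alone would not separate them)
  A <- qr.Q(qr(matrix(rnorm(p * 3), p, 3)))
  B <- qr.Q(qr(matrix(rnorm(p * 3), p, 3)))
  mk <- function(basis, n) basis %*% matrix(rnorm(3 * n, sd = 3), 3, n) +
    matrix(rnorm(p * n, 0, 0.1), p, n)
  Xf <- mk(A, 150); Xs <- mk(B, 150)
  model <- train_dictionaries(Xf[, 1:100], Xs[, 1:100], n_atoms = 20,
                              sparsity = 3, n_iter = 10, seed = 5)
  held <- classify_patches(model, cbind(Xf[, 101:150], Xs[, 101:150]))
  truth <- rep(c("fast", "slow"), each = 50)
  expect_gte(mean(held$label == truth), 0.9)
})

test_that("patch classification ties break toward slow and exact atoms give zero residual", {
  set.seed(2)
  D <- matrix(rnorm(30 * 8), 30, 8)
  D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
  model <- structure(
    list(D_fast = D, D_slow = D, sparsity = 2L,
         moments = list(mean = 0, sd = 1),
         aggregation_threshold = 0.5, channels = "feature"),
    class = "tprm_dictionary_model")
  res <- classify_patches(model, D[, 3, drop = FALSE] * 2)
  expect_lt(res$residual_fast, 1e-20)
  expect_identical(res$label, "slow") # equal residuals -> slow
  expect_error(classify_patches(model, matrix(0, 10, 1)), "dimension")
})

test_that("case aggregation thresholds the fast-patch fraction", {
  model <- structure(list(aggregation_threshold = 0.5),
                     class = "tprm_dictionary_model")
  expect_identical(classify_case(model, rep("fast", 8))$label, "fast")
  expect_identical(classify_case(model, rep("slow", 8))$label, "slow")
  expect_equal(classify_case(model, c("fast", "slow", "fast", "fast"))$score, 0.75)
  expect_error(classify_case(model, character(0)), "at least one")
})

test_that("classifier evaluation matches hand-enumerated and degenerate cases", {
  ev <- evaluate_classifier(c("fast", "fast", "slow", "slow"),
                            c(0.9, 0.4, 0.6, 0.1))
  expect_equal(ev$auc, 0.75)
  perfect <- evaluate_classifier(rep(c("fast", "slow"), each = 10),
                                 c(rnorm(10, 5), rnorm(10, -5)))
  expect_equal(perfect$auc, 1)
  set.seed(8)
  null <- evaluate_classifier(sample(rep(c("fast", "slow"), each = 5000)),
                              runif(10000))
  expect_lt(abs(null$auc - 0.5), 0.02)
  expect_error(evaluate_classifier(rep("fast", 5), runif(5)), "single class")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  truth <- sample(c("fast", "slow"), 200, TRUE)
  scores <- rnorm(200) + (truth == "fast") * 0.8
  ours <- evaluate_classifier(truth, scores)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = truth, predictor = scores,
                                        levels = c("slow", "fast"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("mRMR ranks informative first, duplicates penalized, noise and constants last", {
  set.seed(31)
  n <- 600
  lab <- rep(c("fast", "slow"), n / 2)
  strong <- ifelse(lab == "fast", rnorm(n, 1.5), rnorm(n, -1.5))
  weak <- ifelse(lab == "fast", rnorm(n, 0.4), rnorm(n, -0.4))
  noise <- rnorm(n)
  dup <- strong + rnorm(n, 0, 1e-3)
  rk <- mrmr_rank(data.frame(noise, weak, strong, dup), lab)
  expect_identical(rk$feature[1], "strong")
  # the duplicate of the top feature falls below the independent weak feature
  expect_gt(which(rk$feature == "dup"), which(rk$feature == "weak"))
  rk2 <- mrmr_rank(data.frame(strong, weak, noise), lab)
  expect_identical(rk2$feature[3], "noise")
  cst <- mrmr_rank(data.frame(strong, flat = rep(1, n)), lab)
  expect_equal(cst$relevance[cst$feature == "flat"], 0)
  expect_identical(cst$feature[2], "flat")
})

test_that("logistic baseline hits the separable and null extremes", {
  set.seed(17)
  n <- 200
  labs <- rep(c("fast", "slow"), each = n / 2)
  sp <- stratified_split(labs, 0.5, seed = 3)
  sep <- data.frame(v = ifelse(labs == "fast", 1, -1) + rnorm(n, 0, 0.01))
  bs <- logistic_baseline(sep, labs, sp)
  expect_gt(bs$eval$auc, 0.99)
  nul <- data.frame(v = rnorm(n), w = rnorm(n))
  bn <- logistic_baseline(nul, labs, sp)
  expect_lt(abs(bn$eval$auc - 0.5), 0.15)
})

test_that("stability analysis returns the contracted number of runs per input", {
  set.seed(5)
  d <- c(45, 45, 45)
  mk_case <- function(mu) {
    lung <- array(TRUE, d)
    list(V_Norm = array(rnorm(prod(d), mu, 0.1), d),
         V_fSAD = array(rnorm(prod(d), -mu, 0.1), d),
         chi_Norm = array(rnorm(prod(d), 0, 0.01), d),
         chi_fSAD = array(rnorm(prod(d), mu / 50, 0.01), d),
         lung_mask = lung)
  }
  fields <- c(lapply(1:6, function(i) mk_case(0.5)),
              lapply(1:6, function(i) mk_case(-0.5)))
  labels <- rep(c("fast", "slow"), each = 6)
  sp <- stratified_split(labels, 0.5, seed = 1)
  st <- stability_analysis(fields, labels, sp, n_runs = 3, n_patches = 8,
                           patch_edge_vox = 5, n_atoms = 6, sparsity = 2,
                           n_iter = 3, seed = 2)
  expect_equal(nrow(st$runs), 3 * 4)
  expect_true(all(table(st$runs$channel) == 3))
  expect_equal(nrow(st$summary), 4)
  expect_true(all(st$runs$accuracy >= 0 & st$runs$accuracy <= 1))
})

test_that("patch probability maps localise abnormal labels and Dice behaves", {
  ph <- fixture_phantom()
  tm <- tprm_maps(classify_voxels(ph$ct), classes = c("Norm", "fSAD"))
  ps <- extract_patches(tm, n_patches = 60, patch_edge_vox = 7, seed = 9)
  labels <- rep("slow", 60)
  hot <- ps$locations[, 1] > 24 # call everything in one half abnormal
  labels[hot] <- "fast"
  pm <- patch_probability_map(ps, labels)
  covered <- !is.na(pm)
  expect_true(all(pm[covered] >= 0 & pm[covered] <= 1))
  expect_equal(dice_coefficient(array(TRUE, c(2, 2, 2)), array(TRUE, c(2, 2, 2))), 1)
  expect_equal(dice_coefficient(array(c(TRUE, FALSE), c(2, 1, 1)),
                                array(c(FALSE, TRUE), c(2, 1, 1))), 0)
})
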