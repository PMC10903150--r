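test_that("spirometric grading matches the GOLD/PRISm definitions", {
  expect_identical(
    gold_classify(c(97.4, 70.6, 90.8, 65.0, 40.2, 22.6),
                  c(0.79, 0.77, 0.65, 0.58, 0.44, 0.31)),
    c("GOLD0", "PRISm", "GOLD1", "GOLD2", "GOLD3", "GOLD4"))
  # boundaries are inclusive on the lower side
  expect_identical(gold_classify(c(80, 80, 50, 30), c(0.70, 0.69, 0.6, 0.6)),
                   c("GOLD0", "GOLD1", "GOLD2", "GOLD3"))
  expect_error(gold_classify(NA, 0.8), "missing")
})

test_that("grading partitions the (ratio, %predicted) plane", {
  grid <- expand.grid(pp = seq(5, 130, by = 2.5),
                      ratio = seq(0.2, 0.95, by = 0.025))
  g <- gold_classify(grid$pp, grid$ratio)
  expect_true(all(g %in% c("GOLD0", "PRISm", "GOLD1", "GOLD2", "GOLD3", "GOLD4")))
  expect_false(any(g == ""))
})

test_that("delta FEV1 boundary is inclusive for fast and antisymmetric", {
  d <- delta_fev1(c(2.5, 2.0, 3.745), c(2.2, 2.0, 2.5))
  expect_equal(d$delta_ml_yr, c(-60, 0, -249))
  expect_identical(d$progressor, c("fast", "slow", "fast"))
  fwd <- delta_fev1(2.8, 2.3)$delta_ml_yr
  rev <- delta_fev1(2.3, 2.8)$delta_ml_yr
  expect_equal(fwd, -rev)
  expect_identical(delta_fev1(2.5, NA)$progressor, NA_character_)
})

test_that("spearman correlation handles monotone, hand-ranked and null cases", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6)
  set.seed(1)
  big <- spearman_cor(rnorm(1e4), rnorm(1e4))
  expect_lt(abs(big$rho), 0.05)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("stepwise regression recovers planted standardized coefficients", {
  set.seed(42)
  n <- 5000
  x1 <- rnorm(n); x2 <- rnorm(n)
  age <- rnorm(n, 60, 8); sex <- sample(c("M", "F"), n, TRUE)
  bmi <- rnorm(n, 28, 5)
  y <- 0.7 * x1 + 0.1 * x2 + 0.03 * as.numeric(scale(age)) +
    rnorm(n, 0, sqrt(1 - 0.7^2 - 0.1^2))
  d <- data.frame(y, x1, x2, age, sex, bmi)
  sw <- stepwise_regression(d, "y", c("x1", "x2"), c("age", "sex", "bmi"))
  td <- tidy(sw)
  expect_setequal(sw$retained, c("x1", "x2"))
  expect_lt(abs(td$beta_std[td$term == "x1"] - 0.7), 0.05)
  expect_lt(abs(td$beta_std[td$term == "x2"] - 0.1), 0.05)
  # compulsory covariates present even when irrelevant
  expect_true(all(c("age", "bmi") %in% td$term))
  expect_true(any(grepl("^sex", td$term)))
})

test_that("stepwise regression with a dominant predictor keeps only it", {
  set.seed(7)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n)
  age <- rnorm(n)
  y <- 2 * x1 + rnorm(n, 0, 0.01)
  d <- data.frame(y, x1, x2, age)
  sw <- stepwise_regression(d, "y", c("x1", "x2"), "age")
  expect_identical(sw$retained, "x1")
  expect_lt(abs(tidy(sw)$beta_std[tidy(sw)$term == "x1"] - 1), 0.01)
  # outcome unrelated to candidates: none retained, compulsory reported
  y2 <- rnorm(n)
  sw2 <- stepwise_regression(data.frame(y = y2, x1, x2, age),
                             "y", c("x1", "x2"), "age")
  expect_length(sw2$retained, 0)
  expect_true("age" %in% tidy(sw2)$term)
})

test_that("stepwise regression signals collinear designs", {
  set.seed(1)
  x1 <- rnorm(100)
  d <- data.frame(y = x1 + rnorm(100, 0, 0.1), x1 = x1, x2 = x1)
  expect_error(stepwise_regression(d, "y", c("x1", "x2")), "collinear")
})

test_that("exclusion accounting subtracts per-reason counts", {
  es <- exclusion_summary(120, c(missing_scan = 10, failed_qc = 5))
  tot <- exclusion_totals(es)
  expect_equal(tot$n_excluded, 15L)
  expect_equal(tot$n_analysed, 105L)
  expect_error(exclusion_summary(10, c(a = 11)), "exceed")
  expect_error(exclusion_summary(10, c(5)), "named")
})

test_that("line profiles have a cm distance axis and inclusive sampling", {
  f <- array(0.5, c(20, 20, 20))
  lp <- line_profile(f, f, c(2, 2, 2), c(11, 2, 2), c(1, 1, 1),
                     check_bounds = FALSE)
  expect_equal(nrow(lp), 10L)
  expect_equal(max(lp$distance_cm), 0.9)
  expect_true(all(lp$value_a == 0.5))
  expect_error(line_profile(f, f, c(0, 1, 1), c(5, 5, 5), c(1, 1, 1)),
               "outside")
})

test_that("emphysema-core/fSAD-shell geometry yields crossing profiles", {
  d <- c(30, 30, 30)
  ctr <- c(15.5, 15.5, 15.5)
  co <- arrayInd(seq_len(prod(d)), d)
  r <- sqrt(rowSums(sweep(co, 2, ctr)^2))
  v_emph <- array(pmax(0, 1 - r / 8), d)    # high at core, 0 beyond 8 vox
  v_fsad <- array(pmax(0, pmin(1, (r - 4) / 6)), d) # rises with distance
  lp <- line_profile(v_emph, v_fsad, ctr, c(28, 15.5, 15.5), c(1, 1, 1))
  expect_lt(stats::cor(lp$distance_cm, lp$value_a), 0)
  expect_gt(stats::cor(lp$distance_cm, lp$value_b), 0)
  crossing <- which(diff(sign(lp$value_a - lp$value_b)) != 0)
  expect_gte(length(crossing), 1)
  # endpoints violating the selection rule only warn
  expect_warning(
    line_profile(v_emph, v_fsad, c(28, 15.5, 15.5), ctr, c(1, 1, 1)),
    "0.6")
})
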