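#' Per-grade reference moments for the cohort generator
#'
#' Mean (sd) of demographics, spirometry and PRM percent volumes by
#' spirometric grade, matching the published clinical characterisation of a
#' large multi-centre ever-smoker cohort enrolled across GOLD 0, PRISm and
#' GOLD 1-4. These moments are the generator's defaults; they make synthetic
#' subjects spirometrically consistent with their grade.
#'
#' @return Tibble with one row per grade.
#' @export
gold_reference_moments <- function() {
  tibble::tibble(
    gold_class = c("GOLD0", "PRISm", "GOLD1", "GOLD2", "GOLD3", "GOLD4"),
    n = c(3867L, 1088L, 699L, 1732L, 1041L, 529L),
    age_mean = c(56.7, 57.1, 61.6, 62.6, 64.3, 64.1),
    age_sd = c(8.36, 8.20, 8.96, 8.86, 8.27, 7.53),
    p_male = c(2048, 496, 399, 933, 604, 314) /
      c(3867, 1088, 699, 1732, 1041, 529),
    bmi_mean = c(29.0, 31.9, 27.1, 28.7, 28.1, 25.3),
    bmi_sd = c(5.79, 7.31, 4.89, 6.06, 6.33, 5.56),
    pack_years_mean = c(37.2, 42.6, 45.0, 50.9, 55.1, 56.7),
    pack_years_sd = c(20.0, 24.2, 24.4, 26.8, 27.1, 28.7),
    fev1_pp_mean = c(97.4, 70.6, 90.8, 65.0, 40.2, 22.6),
    fev1_pp_sd = c(11.4, 7.89, 8.70, 8.51, 5.69, 4.84),
    ratio_mean = c(0.79, 0.77, 0.65, 0.58, 0.44, 0.31),
    ratio_sd = c(0.05, 0.05, 0.04, 0.08, 0.09, 0.07),
    fef_mean = c(2.81, 1.79, 1.31, 0.80, 0.39, 0.21),
    fef_sd = c(1.00, 0.66, 0.50, 0.35, 0.16, 0.08),
    fsad_pct_mean = c(9.90, 8.88, 17.0, 21.3, 30.9, 36.0),
    fsad_pct_sd = c(9.31, 8.25, 10.8, 11.5, 11.0, 8.94),
    emph_pct_mean = c(0.80, 0.73, 3.00, 5.40, 14.7, 26.0),
    emph_pct_sd = c(1.42, 2.29, 3.49, 6.95, 12.2, 14.0),
    pd_pct_mean = c(26.3, 35.8, 20.8, 22.2, 19.6, 15.7),
    pd_pct_sd = c(12.8, 16.4, 8.44, 9.04, 9.29, 5.43))
}

#' Specification of a synthetic cohort
#'
#' @param n_subjects number of subjects (>= 2).
#' @param gold_distribution named probabilities over
#'   GOLD0/PRISm/GOLD1..GOLD4 (default: the reference cohort's proportions);
#'   must sum to 1.
#' @param effect_size separation, in pooled within-class SD units, of the
#'   phantom topology parameters (fSAD fraction, sd 0.05; coalescence,
#'   sd 0.15) between fast and slow progressors. 0 makes the two classes'
#'   phantom distributions identical.
#' @param fast_fraction fraction of fast progressors
#'   (delta FEV1/yr <= -60 ml/yr); the fast count is exactly
#'   `round(fast_fraction * n_subjects)`.
#' @param signal `"global"` shifts fSAD fraction and coalescence between
#'   classes; `"local"` keeps whole-lung summaries identical and moves only
#'   the spatial arrangement (clustered vs spread pockets), the regime where
#'   a patch-based model should beat a whole-lung-mean classifier.
#' @param grid_shape phantom grid per subject.
#' @param hu_noise_sd HU noise for the phantoms.
#' @param seed integer master seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects,
                        gold_distribution = NULL,
                        effect_size = 1,
                        fast_fraction = 0.34,
                        signal = c("global", "local"),
                        grid_shape = c(48L, 48L, 48L),
                        hu_noise_sd = 5,
                        seed = 1L) {
  signal <- match.arg(signal)
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    stop("n_subjects must be >= 2", call. = FALSE)
  }
  ref <- gold_reference_moments()
  if (is.null(gold_distribution)) {
    gold_distribution <- setNames(ref$n / sum(ref$n), ref$gold_class)
  }
  if (!setequal(names(gold_distribution), ref$gold_class) ||
      abs(sum(gold_distribution) - 1) > 1e-6 || any(gold_distribution < 0)) {
    stop("gold_distribution must be probabilities over GOLD0/PRISm/GOLD1..4 summing to 1",
         call. = FALSE)
  }
  stopifnot_scalar(effect_size, "effect_size", lo = 0)
  stopifnot_scalar(fast_fraction, "fast_fraction", lo = 0, hi = 1)
  structure(
    list(n_subjects = as.integer(n_subjects),
         gold_distribution = gold_distribution[ref$gold_class],
         effect_size = as.numeric(effect_size),
         fast_fraction = as.numeric(fast_fraction),
         signal = signal,
         grid_shape = as.integer(grid_shape),
         hu_noise_sd = as.numeric(hu_noise_sd),
         seed = as.integer(seed)),
    class = "cohort_spec")
}

# truncated normal draw by inverse-CDF
rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# spirometric band per grade used to keep draws grade-consistent
grade_bands <- function(grade) {
  switch(grade,
    GOLD0 = list(pp = c(80, 140), ratio = c(0.70, 0.95)),
    PRISm = list(pp = c(35, 79.9), ratio = c(0.70, 0.95)),
    GOLD1 = list(pp = c(80, 130), ratio = c(0.40, 0.699)),
    GOLD2 = list(pp = c(50, 79.9), ratio = c(0.30, 0.699)),
    GOLD3 = list(pp = c(30, 49.9), ratio = c(0.25, 0.699)),
    GOLD4 = list(pp = c(8, 29.9), ratio = c(0.15, 0.699)))
}

#' Generate a synthetic cohort with paired-CT phantom specifications
#'
#' Draws per-subject spirometry, demographics and 5-year FEV1 follow-up
#' consistent with an assigned GOLD grade and fast/slow progressor label, and
#' builds one [phantom_spec()] per subject whose fSAD topology parameters are
#' linked to grade and (via `effect_size` or the local-signal construction)
#' to the progressor label.
#'
#' @param spec a [cohort_spec()].
#' @return List of class `tprm_cohort` with `cohort` (tibble, one row per
#'   subject) and `phantom_specs` (list of [phantom_spec()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  ref <- gold_reference_moments()
  grades <- sample(ref$gold_class, n, replace = TRUE,
                   prob = spec$gold_distribution)
  n_fast <- round(spec$fast_fraction * n)
  progressor <- rep("slow", n)
  progressor[sample.int(n, n_fast)] <- "fast"

  rows <- vector("list", n)
  phantoms <- vector("list", n)
  sub_seeds <- child_seeds(spec$seed, n + 1L)
  set.seed(sub_seeds[n + 1L]) # stream for the subject-level draws below

  for (i in seq_len(n)) {
    g <- grades[i]
    m <- ref[ref$gold_class == g, ]
    band <- grade_bands(g)
    pp <- rtnorm(1, m$fev1_pp_mean, m$fev1_pp_sd, band$pp[1], band$pp[2])
    ratio <- rtnorm(1, m$ratio_mean, m$ratio_sd, band$ratio[1], band$ratio[2])
    pred_fev1 <- rtnorm(1, 3.0, 0.4, 2.0, 4.5)
    fev1 <- max(0.5, pp / 100 * pred_fev1)
    fvc <- fev1 / ratio
    fef <- max(0.05, rnorm(1, m$fef_mean, m$fef_sd))
    age <- rtnorm(1, m$age_mean, m$age_sd, 45, 85)
    sex <- if (runif(1) < m$p_male) "M" else "F"
    bmi <- rtnorm(1, m$bmi_mean, m$bmi_sd, 16, 50)
    pack_years <- rtnorm(1, m$pack_years_mean, m$pack_years_sd, 10, 150)
    race <- sample(c("NHW", "AA"), 1, prob = c(2 / 3, 1 / 3))
    vendor <- sample(c("VendorA", "VendorB", "VendorC"), 1,
                     prob = c(0.5, 0.3, 0.2))

    # follow-up consistent with the progressor label; the floor keeps the
    # 5-year FEV1 physiological for low baselines
    lo <- max(-250, -(fev1 - 0.15) * 200)
    delta <- if (progressor[i] == "fast") {
      if (lo >= -60) -60 else runif(1, lo, -60)
    } else {
      runif(1, max(-55, lo), 80)
    }
    fev1_y5 <- fev1 + 5 * delta / 1000

    exp_vol <- runif(1, 2.2, 4.2)
    insp_vol <- exp_vol * runif(1, 1.45, 1.8)

    # phantom topology parameters linked to grade and progressor label
    sd_f <- 0.05; sd_c <- 0.15
    shift <- if (progressor[i] == "fast") 0.5 else -0.5
    if (spec$signal == "global") {
      fsad_frac <- rnorm(1, m$fsad_pct_mean / 100 + spec$effect_size * shift * sd_f, sd_f)
      coal <- rnorm(1, 0.30 + spec$effect_size * shift * sd_c, sd_c)
      placement <- "clustered"
    } else {
      fsad_frac <- rnorm(1, m$fsad_pct_mean / 100 + 0.1, sd_f)
      coal <- 0.1
      placement <- if (progressor[i] == "fast") "clustered" else "spread"
    }
    fsad_frac <- min(max(fsad_frac, 0.03), 0.45)
    coal <- min(max(coal, 0.05), 0.95)
    emph_frac <- min(max(rnorm(1, m$emph_pct_mean / 100, m$emph_pct_sd / 100), 0), 0.40)
    pd_frac <- min(max(rnorm(1, m$pd_pct_mean / 100, m$pd_pct_sd / 100), 0.02), 0.40)
    tot <- fsad_frac + emph_frac + pd_frac
    if (tot > 0.85) {
      sc <- 0.85 / tot
      fsad_frac <- fsad_frac * sc; emph_frac <- emph_frac * sc
      pd_frac <- pd_frac * sc
    }
    cfr <- c(fSAD = fsad_frac)
    if (emph_frac > 0.005) cfr <- c(cfr, Emph = emph_frac)
    cfr <- c(cfr, PD = pd_frac)
    phantoms[[i]] <- phantom_spec(
      grid_shape = spec$grid_shape,
      class_fractions = as.list(cfr),
      n_fsad_pockets = 12L, n_emph_pockets = 3L, n_pd_pockets = 3L,
      coalescence = coal, pocket_placement = placement,
      hu_noise_sd = spec$hu_noise_sd, seed = sub_seeds[i])

    rows[[i]] <- tibble::tibble(
      case_id = sprintf("S%04d", i), gold_class = g,
      age = age, sex = sex, race = race, bmi = bmi,
      pack_years = pack_years, ct_vendor = vendor,
      fev1_pct_pred = pp, fev1_fvc_ratio = ratio,
      fev1_l = fev1, fvc_l = fvc, fef2575_lps = fef,
      fev1_y5_l = fev1_y5,
      insp_volume_l = insp_vol, exp_volume_l = exp_vol,
      fsad_fraction = fsad_frac, coalescence = coal,
      phantom_seed = sub_seeds[i])
  }
  cohort <- dplyr::bind_rows(rows)
  dfl <- delta_fev1(cohort$fev1_l, cohort$fev1_y5_l)
  cohort$delta_fev1_ml_yr <- dfl$delta_ml_yr
  cohort$progressor <- dfl$progressor
  stopifnot(identical(cohort$progressor, progressor))
  structure(list(cohort = cohort, phantom_specs = phantoms, spec = spec),
            class = "tprm_cohort")
}

#' @export
print.tprm_cohort <- function(x, ...) {
  cat(sprintf("<tprm_cohort> %d subjects (%d fast / %d slow), effect size %.1f (%s signal)\n",
              nrow(x$cohort), sum(x$cohort$progressor == "fast"),
              sum(x$cohort$progressor == "slow"),
              x$spec$effect_size, x$spec$signal))
  print(table(x$cohort$gold_class))
  invisible(x)
}

#' Serialise/deserialise a cohort spec as JSON
#' @param spec a [cohort_spec()].
#' @param json JSON string.
#' @return JSON string / `cohort_spec`.
#' @export
cohort_spec_to_json <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  x <- unclass(spec)
  x$gold_distribution <- as.list(x$gold_distribution)
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname cohort_spec_to_json
#' @export
cohort_spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  x$gold_distribution <- unlist(x$gold_distribution)
  do.call(cohort_spec, x)
}
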