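#' Spirometric grading (GOLD 0 / PRISm / GOLD 1-4)
#'
#' Post-bronchodilator staging: a FEV1/FVC ratio >= 0.7 with FEV1%
#' predicted >= 80 is GOLD 0 ("at-risk"), with FEV1% predicted < 80 it is
#' PRISm (preserved ratio impaired spirometry). A ratio < 0.7 defines COPD,
#' graded by FEV1% predicted: GOLD 1 (>= 80), GOLD 2 (50-80), GOLD 3
#' (30-50), GOLD 4 (< 30). Lower bounds are inclusive.
#'
#' @param fev1_pct_pred FEV1 percent predicted.
#' @param ratio FEV1/FVC ratio.
#' @return Character vector over
#'   `c("GOLD0","PRISm","GOLD1","GOLD2","GOLD3","GOLD4")`.
#' @export
gold_classify <- function(fev1_pct_pred, ratio) {
  if (length(fev1_pct_pred) != length(ratio)) {
    stop("inputs must have equal length", call. = FALSE)
  }
  if (anyNA(fev1_pct_pred) || anyNA(ratio)) {
    stop("missing spirometry values", call. = FALSE)
  }
  out <- character(length(ratio))
  preserved <- ratio >= 0.7
  out[preserved & fev1_pct_pred >= 80] <- "GOLD0"
  out[preserved & fev1_pct_pred < 80] <- "PRISm"
  out[!preserved & fev1_pct_pred >= 80] <- "GOLD1"
  out[!preserved & fev1_pct_pred >= 50 & fev1_pct_pred < 80] <- "GOLD2"
  out[!preserved & fev1_pct_pred >= 30 & fev1_pct_pred < 50] <- "GOLD3"
  out[!preserved & fev1_pct_pred < 30] <- "GOLD4"
  out
}

#' Annualised FEV1 decline and progressor label
#'
#' `delta = 1000 * (FEV1 at year 5 - FEV1 at year 0) / 5` ml/yr. Fast
#' progressors decline by at least 60 ml/yr (`delta <= -60`, boundary
#' inclusive); everyone else is a slow progressor. A missing follow-up gives
#' an NA label.
#'
#' @param fev1_y0_l,fev1_y5_l baseline and 5-year FEV1 in litres.
#' @return Tibble with `delta_ml_yr` and `progressor` (`"fast"`/`"slow"`).
#' @export
delta_fev1 <- function(fev1_y0_l, fev1_y5_l) {
  if (length(fev1_y0_l) != length(fev1_y5_l)) {
    stop("inputs must have equal length", call. = FALSE)
  }
  delta <- 1000 * (fev1_y5_l - fev1_y0_l) / 5
  # the -60 boundary is inclusive for fast; the epsilon absorbs the floating
  # point error of the litre arithmetic (e.g. 2.2 - 2.5)
  tibble::tibble(
    delta_ml_yr = delta,
    progressor = ifelse(is.na(delta), NA_character_,
                        ifelse(delta <= -60 + 1e-9, "fast", "slow")))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and a two-sided p value
#' (asymptotic t approximation, appropriate at cohort sizes).
#'
#' @param x,y paired numeric vectors, n >= 3, no missing values.
#' @return Tibble with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("rank correlation undefined for constant input", call. = FALSE)
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

#' Stepwise multivariable linear regression with a compulsory block
#'
#' Ordinary least squares with forward selection of the candidate tPRM
#' readouts (entry p < 0.05, removal p > 0.10 after each entry) while a
#' compulsory covariate block (demographics, smoking, scanner vendor) stays
#' in every model. Continuous variables are z-scored for the standardized
#' coefficients; model fit (adjusted R-squared, SE of the estimate) is
#' reported on the original outcome scale.
#'
#' @param data data frame / tibble of complete cases.
#' @param outcome outcome column name.
#' @param candidates candidate predictor names entered stepwise.
#' @param compulsory covariate names always retained.
#' @param entry_p,removal_p stepwise thresholds.
#' @return Object of class `tprm_stepwise`; see [tidy.tprm_stepwise()] and
#'   [glance.tprm_stepwise()].
#' @export
stepwise_regression <- function(data, outcome, candidates,
                                compulsory = character(0),
                                entry_p = 0.05, removal_p = 0.10) {
  vars <- c(outcome, candidates, compulsory)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    stop("missing columns: ", paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  df <- data[vars]
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < length(vars) + 2) stop("too few complete cases", call. = FALSE)

  # z-score continuous variables (categorical covariates stay factors)
  zdf <- df
  for (v in vars) {
    if (is.numeric(zdf[[v]])) {
      if (sd(zdf[[v]]) == 0) stop(sprintf("`%s` is constant", v), call. = FALSE)
      zdf[[v]] <- as.numeric(scale(zdf[[v]]))
    } else {
      zdf[[v]] <- factor(zdf[[v]])
    }
  }

  fit_with <- function(cands, frame) {
    rhs <- c(sprintf("`%s`", compulsory), sprintf("`%s`", cands))
    if (!length(rhs)) rhs <- "1"
    lm(as.formula(paste(sprintf("`%s`", outcome), "~",
                        paste(rhs, collapse = " + "))), data = frame)
  }
  term_p <- function(fit, term) {
    sm <- summary(fit)$coefficients
    row <- grep(sprintf("^`?%s`?$", term), rownames(sm))
    if (!length(row)) return(NA_real_)
    sm[row[1], 4]
  }

  selected <- character(0)
  repeat {
    changed <- FALSE
    remaining <- setdiff(candidates, selected)
    if (length(remaining)) {
      ps <- vapply(remaining, function(cd) {
        fit <- fit_with(c(selected, cd), zdf)
        if (any(is.na(coef(fit)))) {
          stop("collinear design: ", cd, " is aliased", call. = FALSE)
        }
        term_p(fit, cd)
      }, numeric(1))
      if (any(!is.na(ps) & ps < entry_p)) {
        selected <- c(selected, remaining[which.min(ps)])
        changed <- TRUE
      }
    }
    if (length(selected)) {
      fit <- fit_with(selected, zdf)
      ps <- vapply(selected, function(cd) term_p(fit, cd), numeric(1))
      if (any(ps > removal_p)) {
        selected <- setdiff(selected, selected[which.max(ps)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  zfit <- fit_with(selected, zdf)
  rawfit <- fit_with(selected, df)
  if (any(is.na(coef(zfit)))) stop("collinear design in final model", call. = FALSE)
  sm <- summary(zfit)$coefficients
  terms_tbl <- tibble::tibble(
    term = rownames(sm),
    beta_std = sm[, 1], se = sm[, 2], p_value = sm[, 4],
    role = ifelse(gsub("`", "", rownames(sm)) %in% selected, "candidate",
                  ifelse(rownames(sm) == "(Intercept)", "intercept", "compulsory")))
  structure(
    list(outcome = outcome, retained = selected, candidates = candidates,
         compulsory = compulsory, terms = terms_tbl,
         adj_r_squared = summary(rawfit)$adj.r.squared,
         sigma = sigma(rawfit), n = nrow(df),
         fit = rawfit, fit_std = zfit),
    class = "tprm_stepwise")
}

#' @describeIn stepwise_regression standardized coefficients of the final
#'   model, one row per term.
#' @param x,... a `tprm_stepwise` object; unused.
#' @method tidy tprm_stepwise
#' @export
tidy.tprm_stepwise <- function(x, ...) x$terms

#' @describeIn stepwise_regression one-row model summary (adjusted
#'   R-squared, SE of the estimate, n, retained candidates).
#' @method glance tprm_stepwise
#' @export
glance.tprm_stepwise <- function(x, ...) {
  tibble::tibble(adj_r_squared = x$adj_r_squared, sigma = x$sigma,
                 n = x$n, n_retained = length(x$retained),
                 retained = paste(x$retained, collapse = "+"))
}

#' @export
print.tprm_stepwise <- function(x, ...) {
  cat(sprintf("<tprm_stepwise> outcome: %s\n", x$outcome))
  cat(sprintf("  retained candidates: %s\n",
              if (length(x$retained)) paste(x$retained, collapse = ", ") else "(none)"))
  cat(sprintf("  adj R^2 %.3f, SE %.3f, n %d\n",
              x$adj_r_squared, x$sigma, x$n))
  invisible(x)
}

#' Cohort accounting: exclusions and analysed subset
#'
#' Book-keeping of how an enrolled cohort shrinks to the analysed subset:
#' subtracts the per-reason exclusion counts from the enrolled total.
#'
#' @param n_enrolled enrolled participant count.
#' @param exclusions named integer vector of per-reason exclusion counts.
#' @return Tibble with one row per reason plus attributes-free summary
#'   columns: `n_enrolled`, `n_excluded`, `n_analysed` repeated on each row
#'   are avoided; instead the tibble has reasons and counts and the totals
#'   are in the `summary` attribute accessed via [exclusion_totals()].
#' @export
exclusion_summary <- function(n_enrolled, exclusions) {
  if (is.null(names(exclusions)) || any(names(exclusions) == "")) {
    stop("exclusions must be a named vector", call. = FALSE)
  }
  if (any(exclusions < 0) || sum(exclusions) > n_enrolled) {
    stop("exclusions must be non-negative and not exceed enrolment", call. = FALSE)
  }
  out <- tibble::tibble(reason = names(exclusions),
                        n = as.integer(exclusions))
  attr(out, "n_enrolled") <- as.integer(n_enrolled)
  attr(out, "n_excluded") <- as.integer(sum(exclusions))
  attr(out, "n_analysed") <- as.integer(n_enrolled - sum(exclusions))
  out
}

#' @rdname exclusion_summary
#' @param summary an [exclusion_summary()] result.
#' @export
exclusion_totals <- function(summary) {
  tibble::tibble(n_enrolled = attr(summary, "n_enrolled"),
                 n_excluded = attr(summary, "n_excluded"),
                 n_analysed = attr(summary, "n_analysed"))
}
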