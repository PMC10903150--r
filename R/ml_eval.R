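#' Stratified train/test split
#'
#' Draws `round(train_fraction * n_class)` training cases per class, so a
#' 35% split of 1516 fast / 2967 slow progressors yields exactly 531/1038
#' training and 985/1929 testing cases. The split is disjoint and
#' exhaustive.
#'
#' @param case_labels per-case labels (character/factor), optionally named
#'   with case ids.
#' @param train_fraction fraction per class used for training (default 0.35).
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(case_labels, train_fraction = 0.35, seed = 1L) {
  labs <- as.character(case_labels)
  if (anyNA(labs)) stop("case labels must be complete", call. = FALSE)
  classes <- unique(labs)
  if (any(table(labs) < 1)) stop("every class needs at least one case", call. = FALSE)
  stopifnot_scalar(train_fraction, "train_fraction", lo = 0, hi = 1)
  set.seed(as.integer(seed))
  train <- integer(0)
  for (cl in classes) {
    idx <- which(labs == cl)
    n_tr <- round(train_fraction * length(idx))
    train <- c(train, sort(sample(idx, n_tr)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labs), train))
}

#' Classifier evaluation: confusion matrix, accuracy and ROC/AUC
#'
#' AUC is computed in the rank (Mann-Whitney) form, which equals the area
#' under the trapezoidal ROC curve with tie handling; the confusion matrix
#' is taken at `threshold` (score >= threshold calls the positive class).
#'
#' @param truth true labels.
#' @param scores numeric scores, higher = more positive.
#' @param threshold decision threshold (default 0.5).
#' @param positive positive-class label (default `"fast"`).
#' @return Object of class `tprm_eval` with `auc`, `accuracy`,
#'   `sensitivity`, `specificity`, `confusion`, and the ROC curve; see
#'   [tidy.tprm_eval()] / [glance.tprm_eval()].
#' @export
evaluate_classifier <- function(truth, scores, threshold = 0.5,
                                positive = "fast") {
  truth <- as.character(truth)
  if (length(truth) != length(scores)) {
    stop("labels and scores must align", call. = FALSE)
  }
  ok <- !is.na(truth) & !is.na(scores)
  truth <- truth[ok]; scores <- scores[ok]
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: truth contains a single class", call. = FALSE)
  }
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  pred_pos <- scores >= threshold
  tp <- sum(pred_pos & pos); fn <- sum(!pred_pos & pos)
  fp <- sum(pred_pos & !pos); tn <- sum(!pred_pos & !pos)
  confusion <- matrix(c(tp, fn, fp, tn), 2, 2,
                      dimnames = list(predicted = c("positive", "negative"),
                                      truth = c("positive", "negative")))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) sum(scores >= t & pos) / n1, numeric(1)),
    fpr = vapply(thr, function(t) sum(scores >= t & !pos) / n0, numeric(1)))
  structure(
    list(auc = auc, accuracy = (tp + tn) / length(truth),
         sensitivity = tp / n1, specificity = tn / n0,
         confusion = confusion, roc = roc, threshold = threshold,
         n = length(truth), positive = positive),
    class = "tprm_eval")
}

#' @describeIn evaluate_classifier ROC curve points (threshold, TPR, FPR).
#' @param x,... a `tprm_eval`; unused.
#' @method tidy tprm_eval
#' @export
tidy.tprm_eval <- function(x, ...) x$roc

#' @describeIn evaluate_classifier one-row summary (AUC, accuracy,
#'   sensitivity, specificity, n).
#' @method glance tprm_eval
#' @export
glance.tprm_eval <- function(x, ...) {
  tibble::tibble(auc = x$auc, accuracy = x$accuracy,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 threshold = x$threshold, n = x$n)
}

#' @export
print.tprm_eval <- function(x, ...) {
  cat(sprintf("<tprm_eval> AUC %.3f, accuracy %.1f%% (n = %d, threshold %.2f)\n",
              x$auc, 100 * x$accuracy, x$n, x$threshold))
  cat(sprintf("  sensitivity %.3f, specificity %.3f\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

# mutual information between two variables after quantile discretisation of
# numeric inputs; natural-log units
discretize_quantile <- function(x, n_bins) {
  if (!is.numeric(x)) return(as.factor(x))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        na.rm = TRUE, type = 7))
  if (length(br) < 2) return(factor(rep("bin1", length(x))))
  cut(x, breaks = br, include.lowest = TRUE)
}

mutual_information <- function(x, y, n_bins = 8L) {
  fx <- discretize_quantile(x, n_bins)
  fy <- discretize_quantile(y, n_bins)
  tab <- table(fx, fy)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy ranking that maximises mutual information with the class label
#' (relevance) minus the mean mutual information with already-selected
#' features (redundancy). Mutual information is estimated on
#' quantile-binned variables (8 bins by default, recorded in the output).
#'
#' @param features data frame / matrix of candidate features (>= 2).
#' @param labels class labels.
#' @param n_bins quantile bins for MI estimation.
#' @return Tibble with `feature`, `rank`, `score`, `relevance`,
#'   `redundancy`; attribute `n_bins` records the discretisation.
#' @export
mrmr_rank <- function(features, labels, n_bins = 8L) {
  features <- as.data.frame(features)
  if (ncol(features) < 2) stop("need at least 2 features", call. = FALSE)
  if (nrow(features) != length(labels)) {
    stop("features and labels must align", call. = FALSE)
  }
  rel <- vapply(features, function(f) mutual_information(f, labels, n_bins),
                numeric(1))
  selected <- character(0)
  rows <- list()
  remaining <- names(features)
  while (length(remaining)) {
    if (!length(selected)) {
      scores <- rel[remaining]
      red <- setNames(rep(0, length(remaining)), remaining)
    } else {
      red <- vapply(remaining, function(f) {
        mean(vapply(selected, function(s)
          mutual_information(features[[f]], features[[s]], n_bins),
          numeric(1)))
      }, numeric(1))
      scores <- rel[remaining] - red
    }
    pick <- remaining[which.max(scores)]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      feature = pick, rank = length(rows) + 1L,
      score = unname(scores[pick]), relevance = unname(rel[pick]),
      redundancy = unname(red[pick]))
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_bins") <- as.integer(n_bins)
  out
}

#' Logistic-regression baseline on whole-lung tPRM means
#'
#' The comparison model for the patch-based classifier: a logistic
#' regression of the progressor label on the four whole-lung mean readouts,
#' fitted on the training partition and evaluated on the test partition. If
#' the training data are separable the model falls back to a lightly
#' ridge-regularised fit (flagged in the result).
#'
#' @param features case-level tibble of numeric predictors (e.g. columns
#'   `V_Norm`, `V_fSAD`, `chi_Norm`, `chi_fSAD`).
#' @param labels per-case labels (`"fast"`/`"slow"`).
#' @param split a [stratified_split()] result.
#' @param positive positive class (default `"fast"`).
#' @return List with `eval` (a `tprm_eval` on the test cases), `scores`,
#'   `regularized` flag and the fitted model.
#' @export
logistic_baseline <- function(features, labels, split, positive = "fast") {
  features <- as.data.frame(features)
  num <- vapply(features, is.numeric, logical(1))
  features <- features[num]
  y <- as.integer(as.character(labels) == positive)
  tr <- split$train; te <- split$test
  df <- cbind(y = y, features)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = df[tr, , drop = FALSE], family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if ((separated || !fit$converged) && ncol(features) >= 2) {
    xm <- as.matrix(features)
    fit <- glmnet::glmnet(xm[tr, , drop = FALSE], y[tr], family = "binomial",
                          alpha = 0, lambda = 1e-3)
    scores <- as.numeric(predict(fit, newx = xm[te, , drop = FALSE],
                                 type = "response"))
  } else {
    scores <- as.numeric(predict(fit, newdata = df[te, , drop = FALSE],
                                 type = "response"))
  }
  ev <- evaluate_classifier(labels[te], scores, threshold = 0.5,
                            positive = positive)
  list(eval = ev, scores = scores, regularized = separated, model = fit)
}

#' Per-channel stability of the patch classifier over training-patch draws
#'
#' Re-extracts training patches `n_runs` times (new random patch locations
#' each run, same case split), trains a single-channel dictionary model per
#' tPRM input and records the test accuracy, then fits a Gaussian to each
#' channel's accuracy sample (mean and sd). Channels whose accuracy
#' distribution is tight are robust to the choice of training patches.
#'
#' @param fields_by_case list (one element per case) of named field lists
#'   (`V_Norm`, `V_fSAD`, `chi_Norm`, `chi_fSAD`) plus `lung_mask`.
#' @param labels per-case progressor labels.
#' @param split a [stratified_split()] result.
#' @param channels channels to assess.
#' @param n_runs training-patch draws per channel (default 10).
#' @param n_patches,patch_edge_vox patch sampling settings.
#' @param n_atoms,sparsity,n_iter dictionary settings.
#' @param seed integer master seed.
#' @return List with `runs` (tibble: channel, run, accuracy) and `summary`
#'   (tibble: channel, mean, sd of the fitted Gaussian).
#' @export
stability_analysis <- function(fields_by_case, labels, split,
                               channels = c("V_Norm", "V_fSAD",
                                            "chi_Norm", "chi_fSAD"),
                               n_runs = 10L, n_patches = 40L,
                               patch_edge_vox = 7L, n_atoms = 16L,
                               sparsity = 3L, n_iter = 5L, seed = 1L) {
  n_case <- length(fields_by_case)
  if (n_case != length(labels)) stop("one label per case required", call. = FALSE)
  run_seeds <- child_seeds(seed, n_runs)
  rows <- list()
  for (r in seq_len(n_runs)) {
    patch_sets <- lapply(seq_len(n_case), function(i) {
      f <- fields_by_case[[i]]
      extract_patches(f[channels], f$lung_mask, n_patches = n_patches,
                      patch_edge_vox = patch_edge_vox,
                      seed = (run_seeds[r] + i) %% .Machine$integer.max,
                      channels = channels)
    })
    for (ch in channels) {
      sub <- lapply(patch_sets, function(ps) {
        rows_idx <- channel_rows(ps, ch)
        ps2 <- ps
        ps2$X <- ps$X[rows_idx, , drop = FALSE]
        ps2$channels <- ch
        ps2
      })
      acc <- run_patch_model(sub, labels, split, n_atoms = n_atoms,
                             sparsity = sparsity, n_iter = n_iter,
                             seed = run_seeds[r])$eval$accuracy
      rows[[length(rows) + 1L]] <- tibble::tibble(
        channel = ch, run = r, accuracy = acc)
    }
  }
  runs <- dplyr::bind_rows(rows)
  summary <- runs |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(mean = mean(.data$accuracy),
                     sd = stats::sd(.data$accuracy), .groups = "drop")
  list(runs = runs, summary = summary)
}

# rows of the patch feature matrix belonging to one channel
channel_rows <- function(patch_set, channel) {
  p_per <- nrow(patch_set$X) / length(patch_set$channels)
  ci <- match(channel, patch_set$channels)
  if (is.na(ci)) stop("unknown channel: ", channel, call. = FALSE)
  (ci - 1) * p_per + seq_len(p_per)
}

# train on the split's training cases and evaluate case-level scores on the
# test cases; shared by run_pipeline() and stability_analysis()
run_patch_model <- function(patch_sets, labels, split, n_atoms, sparsity,
                            n_iter, aggregation_threshold = 0.5, seed = 1L) {
  labs <- as.character(labels)
  tr_fast <- intersect(split$train, which(labs == "fast"))
  tr_slow <- intersect(split$train, which(labs == "slow"))
  if (!length(tr_fast) || !length(tr_slow)) {
    stop("training partition must contain both classes", call. = FALSE)
  }
  Xf <- do.call(cbind, lapply(patch_sets[tr_fast], function(p) p$X))
  Xs <- do.call(cbind, lapply(patch_sets[tr_slow], function(p) p$X))
  proto <- patch_sets[[1]]
  psf <- proto; psf$X <- Xf
  pss <- proto; pss$X <- Xs
  model <- train_dictionaries(psf, pss, n_atoms = n_atoms,
                              sparsity = sparsity, n_iter = n_iter,
                              aggregation_threshold = aggregation_threshold,
                              seed = seed)
  scores <- vapply(split$test, function(i) {
    pl <- classify_patches(model, patch_sets[[i]])
    classify_case(model, pl$label)$score
  }, numeric(1))
  ev <- evaluate_classifier(labs[split$test], scores,
                            threshold = aggregation_threshold)
  list(model = model, scores = scores, eval = ev)
}
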