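# Orthogonal matching pursuit against a fixed dictionary, Gram-matrix form.
# Returns the dense code matrix and per-column squared reconstruction error.
# All inner products live in atom space (K x K Gram), so cost per column is
# O(sparsity * K) regardless of the patch dimension.
omp_code <- function(D, X, sparsity) {
  K <- ncol(D)
  n <- ncol(X)
  sparsity <- min(sparsity, K)
  G <- crossprod(D)
  DtX <- crossprod(D, X)
  xnorm2 <- colSums(X^2)
  C <- matrix(0, K, n)
  err <- numeric(n)
  for (i in seq_len(n)) {
    dtx <- DtX[, i]
    corr <- dtx
    s <- integer(0)
    cf <- numeric(0)
    for (t in seq_len(sparsity)) {
      j <- which.max(abs(corr))
      if (abs(corr[j]) < 1e-12) break
      s <- c(s, j)
      Gs <- G[s, s, drop = FALSE]
      cf <- tryCatch(solve(Gs + diag(1e-12, length(s)), dtx[s]),
                     error = function(e) NULL)
      if (is.null(cf)) { s <- s[-length(s)]; break }
      corr <- dtx - G[, s, drop = FALSE] %*% cf
      corr[s] <- 0
    }
    if (length(s)) {
      C[s, i] <- cf
      err[i] <- max(0, xnorm2[i] - 2 * sum(cf * dtx[s]) +
                      sum(cf * (G[s, s, drop = FALSE] %*% cf)))
    } else {
      err[i] <- xnorm2[i]
    }
  }
  list(C = C, err = err)
}

# one dictionary-learning pass for a single class: alternate OMP sparse
# coding and atom-wise (approximate K-SVD) updates; returns the dictionary
# and the objective trace recorded after each coding step
learn_dictionary <- function(X, n_atoms, sparsity, n_iter, seed) {
  n <- ncol(X)
  if (n_atoms > n) stop("n_atoms must not exceed the number of training patches",
                        call. = FALSE)
  set.seed(as.integer(seed))
  init_idx <- sample.int(n, n_atoms)
  D <- X[, init_idx, drop = FALSE]
  nrm <- sqrt(colSums(D^2))
  nrm[nrm < 1e-12] <- 1
  D <- sweep(D, 2, nrm, "/")
  # degenerate all-zero atoms replaced by random unit vectors
  zero <- colSums(D^2) < 1e-12
  if (any(zero)) {
    D[, zero] <- matrix(rnorm(nrow(D) * sum(zero)), nrow(D))
    D[, zero] <- sweep(D[, zero, drop = FALSE], 2,
                       sqrt(colSums(D[, zero, drop = FALSE]^2)), "/")
  }
  objective <- numeric(0)
  if (n_iter > 0) {
    for (it in seq_len(n_iter)) {
      code <- omp_code(D, X, sparsity)
      objective <- c(objective, sum(code$err))
      C <- code$C
      Rfull <- X - D %*% C
      recon_err <- colSums(Rfull^2)
      for (k in seq_len(n_atoms)) {
        users <- which(C[k, ] != 0)
        if (!length(users)) {
          # dead atom: reseed on the worst-reconstructed patch
          w <- which.max(recon_err)
          v <- X[, w]
          if (sum(v^2) < 1e-12) v <- rnorm(nrow(D))
          D[, k] <- v / sqrt(sum(v^2))
          next
        }
        E <- Rfull[, users, drop = FALSE] +
          outer(D[, k], C[k, users])
        d_new <- E %*% C[k, users]
        nd <- sqrt(sum(d_new^2))
        if (nd < 1e-12) next
        d_new <- d_new / nd
        c_new <- crossprod(E, d_new)
        Rfull[, users] <- E - d_new %*% t(c_new)
        D[, k] <- d_new
        C[k, users] <- c_new
      }
    }
  }
  list(D = D, objective = objective)
}

# channel-block standardisation moments of a training patch matrix
channel_moments <- function(X, n_channels) {
  p_per <- nrow(X) / n_channels
  mu <- numeric(n_channels); sdv <- numeric(n_channels)
  for (ci in seq_len(n_channels)) {
    rows <- (ci - 1) * p_per + seq_len(p_per)
    v <- X[rows, ]
    mu[ci] <- mean(v)
    sdv[ci] <- stats::sd(as.vector(v))
    if (!is.finite(sdv[ci]) || sdv[ci] < 1e-12) sdv[ci] <- 1
  }
  list(mean = mu, sd = sdv)
}

apply_channel_scaling <- function(X, moments) {
  n_channels <- length(moments$mean)
  p_per <- nrow(X) / n_channels
  for (ci in seq_len(n_channels)) {
    rows <- (ci - 1) * p_per + seq_len(p_per)
    X[rows, ] <- (X[rows, ] - moments$mean[ci]) / moments$sd[ci]
  }
  X
}

#' Train per-class sparse dictionaries on tPRM patches
#'
#' Learns one overcomplete dictionary per progressor class by alternating
#' (i) orthogonal matching pursuit sparse coding of the training patches
#' with at most `sparsity` atoms per code and (ii) atom-wise dictionary
#' updates that minimise the residual reconstruction error (approximate
#' K-SVD), with atoms kept at unit norm. Patch channels are z-standardised
#' with moments estimated on the pooled training patches (V and chi live on
#' scales two orders of magnitude apart) and the moments are stored in the
#' model. A held-out patch is later attributed to the class whose dictionary
#' reconstructs it with the smaller sparse-coding residual.
#'
#' @param patches_fast,patches_slow `tprm_patch_set`s (or bare feature
#'   matrices) of training patches from fast/slow progressor cases.
#' @param n_atoms atoms per class dictionary (default 64).
#' @param sparsity maximum atoms per sparse code (default 5).
#' @param n_iter coding/update iterations (default 10); `0` returns the
#'   seeded initial dictionaries (randomly selected unit-normalised
#'   patches).
#' @param aggregation_threshold case-level decision threshold on the
#'   fraction of fast-labelled patches (default 0.5).
#' @param seed integer seed.
#' @return Object of class `tprm_dictionary_model`.
#' @export
train_dictionaries <- function(patches_fast, patches_slow,
                               n_atoms = 64L, sparsity = 5L, n_iter = 10L,
                               aggregation_threshold = 0.5, seed = 1L) {
  get_X <- function(p) if (inherits(p, "tprm_patch_set")) p$X else p
  Xf <- get_X(patches_fast); Xs <- get_X(patches_slow)
  if (!ncol(Xf) || !ncol(Xs)) stop("both classes need training patches", call. = FALSE)
  if (nrow(Xf) != nrow(Xs)) stop("patch feature dimensions differ", call. = FALSE)
  if (sparsity < 1) stop("sparsity must be >= 1", call. = FALSE)
  channels <- if (inherits(patches_fast, "tprm_patch_set")) {
    patches_fast$channels
  } else "feature"
  moments <- channel_moments(cbind(Xf, Xs), length(channels))
  Xf <- apply_channel_scaling(Xf, moments)
  Xs <- apply_channel_scaling(Xs, moments)
  seeds <- child_seeds(seed, 2L)
  fit_f <- learn_dictionary(Xf, n_atoms, sparsity, n_iter, seeds[1])
  fit_s <- learn_dictionary(Xs, n_atoms, sparsity, n_iter, seeds[2])
  structure(
    list(D_fast = fit_f$D, D_slow = fit_s$D,
         n_atoms = as.integer(n_atoms), sparsity = as.integer(sparsity),
         n_iter = as.integer(n_iter),
         aggregation_threshold = aggregation_threshold,
         channels = channels, moments = moments,
         objective_fast = fit_f$objective, objective_slow = fit_s$objective,
         n_train = c(fast = ncol(Xf), slow = ncol(Xs)),
         seed = as.integer(seed)),
    class = "tprm_dictionary_model")
}

#' @export
print.tprm_dictionary_model <- function(x, ...) {
  cat(sprintf("<tprm_dictionary_model> %d atoms/class, sparsity %d, %d iterations\n",
              x$n_atoms, x$sparsity, x$n_iter))
  cat(sprintf("  trained on %d fast / %d slow patches; channels: %s\n",
              x$n_train["fast"], x$n_train["slow"],
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' @describeIn train_dictionaries one-row model summary.
#' @param x,... a `tprm_dictionary_model`; unused.
#' @method glance tprm_dictionary_model
#' @export
glance.tprm_dictionary_model <- function(x, ...) {
  tibble::tibble(
    n_atoms = x$n_atoms, sparsity = x$sparsity, n_iter = x$n_iter,
    n_train_fast = unname(x$n_train["fast"]),
    n_train_slow = unname(x$n_train["slow"]),
    final_objective_fast = if (length(x$objective_fast))
      x$objective_fast[length(x$objective_fast)] else NA_real_,
    final_objective_slow = if (length(x$objective_slow))
      x$objective_slow[length(x$objective_slow)] else NA_real_)
}

#' Classify patches by dictionary reconstruction residual
#'
#' Sparse-codes each patch against both class dictionaries and assigns the
#' class with the smaller residual; ties go to slow (the conservative,
#' majority-class choice).
#'
#' @param model a [train_dictionaries()] model.
#' @param patches a `tprm_patch_set` or feature matrix.
#' @return Tibble with `residual_fast`, `residual_slow`, `label`.
#' @export
classify_patches <- function(model, patches) {
  stopifnot(inherits(model, "tprm_dictionary_model"))
  X <- if (inherits(patches, "tprm_patch_set")) patches$X else patches
  if (nrow(X) != nrow(model$D_fast)) {
    stop("patch feature dimension does not match the model", call. = FALSE)
  }
  X <- apply_channel_scaling(X, model$moments)
  ef <- omp_code(model$D_fast, X, model$sparsity)$err
  es <- omp_code(model$D_slow, X, model$sparsity)$err
  tibble::tibble(
    residual_fast = ef, residual_slow = es,
    label = ifelse(ef < es, "fast", "slow"))
}

#' Aggregate patch labels into a case-level call
#'
#' The case score is the fraction of its patches labelled fast/abnormal; the
#' case is called fast when the score reaches the model's aggregation
#' threshold. The score is the ROC ordinate used by [evaluate_classifier()].
#'
#' @param model a [train_dictionaries()] model (supplies the threshold).
#' @param patch_labels per-patch labels for one case.
#' @return Tibble with `score`, `label`.
#' @export
classify_case <- function(model, patch_labels) {
  stopifnot(inherits(model, "tprm_dictionary_model"))
  if (!length(patch_labels)) stop("at least one patch required", call. = FALSE)
  score <- mean(patch_labels == "fast")
  tibble::tibble(
    score = score,
    label = ifelse(score >= model$aggregation_threshold, "fast", "slow"))
}
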