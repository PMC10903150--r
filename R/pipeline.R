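#' Pipeline run configuration
#'
#' Bundles every knob of the synthetic end-to-end run (cohort, tPRM, patch
#' and dictionary settings) into one serialisable object; [run_pipeline()]
#' writes the resolved configuration next to its outputs so a run can be
#' reproduced exactly.
#'
#' @param output_dir directory for all artifacts.
#' @param n_subjects,effect_size,fast_fraction,signal,grid_shape,hu_noise_sd
#'   cohort settings, see [cohort_spec()].
#' @param window_vox,stride_vox tPRM window and grid stride.
#' @param classes PRM classes mapped (Norm and fSAD feed the classifier).
#' @param n_patches,patch_edge_vox patches per case and patch edge.
#' @param n_atoms,sparsity,n_iter dictionary-learning settings.
#' @param train_fraction stratified split fraction.
#' @param aggregation_threshold case-level decision threshold.
#' @param qc apply [qc_flag()] to each case and exclude failures.
#' @param seed master seed for the whole run.
#' @return Object of class `tprm_config`.
#' @export
tprm_config <- function(output_dir = tempfile("tprm_run_"),
                        n_subjects = 40L,
                        effect_size = 1,
                        fast_fraction = 0.34,
                        signal = "global",
                        grid_shape = c(48L, 48L, 48L),
                        hu_noise_sd = 5,
                        window_vox = 21L,
                        stride_vox = 5L,
                        classes = c("Norm", "fSAD"),
                        n_patches = 40L,
                        patch_edge_vox = 7L,
                        n_atoms = 32L,
                        sparsity = 3L,
                        n_iter = 8L,
                        train_fraction = 0.35,
                        aggregation_threshold = 0.5,
                        qc = FALSE,
                        seed = 1L) {
  structure(
    list(output_dir = output_dir, n_subjects = as.integer(n_subjects),
         effect_size = effect_size, fast_fraction = fast_fraction,
         signal = signal, grid_shape = as.integer(grid_shape),
         hu_noise_sd = hu_noise_sd,
         window_vox = as.integer(window_vox),
         stride_vox = as.integer(stride_vox), classes = classes,
         n_patches = as.integer(n_patches),
         patch_edge_vox = as.integer(patch_edge_vox),
         n_atoms = as.integer(n_atoms), sparsity = as.integer(sparsity),
         n_iter = as.integer(n_iter), train_fraction = train_fraction,
         aggregation_threshold = aggregation_threshold,
         qc = isTRUE(qc), seed = as.integer(seed)),
    class = "tprm_config")
}

#' Serialise/deserialise a run configuration as JSON
#' @param config a [tprm_config()].
#' @param json JSON string.
#' @return JSON string / `tprm_config`.
#' @export
tprm_config_to_json <- function(config) {
  stopifnot(inherits(config, "tprm_config"))
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
}

#' @rdname tprm_config_to_json
#' @export
tprm_config_from_json <- function(json) {
  do.call(tprm_config, jsonlite::fromJSON(json))
}

#' Per-case tPRM feature extraction
#'
#' One subject's slice of the pipeline: classify the paired CT, map the
#' requested classes, and return whole-lung means plus a seeded patch set.
#'
#' @param ct a [paired_ct()].
#' @param config a [tprm_config()].
#' @param patch_seed seed for the patch draw.
#' @param keep_fields also return the interpolated full-grid fields (memory
#'   heavy; needed for probability maps and stability analyses).
#' @return List with `means` (one-row tibble), `patches`, and optionally
#'   `fields` and the `prm` map.
#' @export
tprm_case_features <- function(ct, config, patch_seed = config$seed,
                               keep_fields = FALSE) {
  prm <- classify_voxels(ct)
  maps <- tprm_maps(prm, classes = config$classes,
                    window_vox = config$window_vox,
                    stride_vox = config$stride_vox)
  means <- maps$whole_lung_means
  wide <- stats::setNames(
    c(means$V_mean, means$chi_mean),
    c(paste0("V_", means$class), paste0("chi_", means$class)))
  patches <- extract_patches(maps, n_patches = config$n_patches,
                             patch_edge_vox = config$patch_edge_vox,
                             seed = patch_seed)
  out <- list(means = tibble::as_tibble(as.list(wide)), patches = patches)
  if (keep_fields) {
    fields <- list()
    for (cl in maps$classes) {
      fields[[paste0("V_", cl)]] <- maps$V[[cl]]
      fields[[paste0("chi_", cl)]] <- maps$chi[[cl]]
    }
    fields$lung_mask <- maps$lung_mask
    out$fields <- fields
    out$prm <- prm
  }
  out
}

#' Run the full synthetic pipeline
#'
#' Simulate a cohort, build each subject's phantom, classify it, map its
#' topology, extract patches, train the dictionary model on the stratified
#' training partition, and evaluate the patch model and the whole-lung-mean
#' logistic baseline on the test partition. All tabular artifacts (cohort,
#' whole-lung means, metrics, exclusions, resolved configuration) are
#' written under `config$output_dir`; a rerun with the same configuration
#' reproduces them byte for byte.
#'
#' @param config a [tprm_config()].
#' @return List of class `tprm_run` with the cohort, case means, split,
#'   model, `eval` (patch model), `baseline` (logistic), exclusions and
#'   artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "tprm_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(tprm_config_to_json(config),
             file.path(config$output_dir, "config.json"))

  cs <- cohort_spec(n_subjects = config$n_subjects,
                    effect_size = config$effect_size,
                    fast_fraction = config$fast_fraction,
                    signal = config$signal,
                    grid_shape = config$grid_shape,
                    hu_noise_sd = config$hu_noise_sd,
                    seed = config$seed)
  sim <- generate_cohort(cs)
  cohort <- sim$cohort

  message(sprintf("[cohort] %d subjects simulated (%d fast)",
                  nrow(cohort), sum(cohort$progressor == "fast")))

  excluded <- tibble::tibble(case_id = character(0), reason = character(0))
  keep <- rep(TRUE, nrow(cohort))
  if (config$qc) {
    for (i in seq_len(nrow(cohort))) {
      flag <- if (cohort$exp_volume_l[i] >= cohort$insp_volume_l[i]) {
        list(pass = FALSE, reason = "erroneous volume change")
      } else if (cohort$insp_volume_l[i] < 1 || cohort$insp_volume_l[i] > 10 ||
                 cohort$exp_volume_l[i] < 1 || cohort$exp_volume_l[i] > 10) {
        list(pass = FALSE, reason = "implausible lung volume")
      } else list(pass = TRUE, reason = "")
      if (!flag$pass) {
        keep[i] <- FALSE
        excluded <- dplyr::bind_rows(
          excluded, tibble::tibble(case_id = cohort$case_id[i],
                                   reason = flag$reason))
      }
    }
    message(sprintf("[qc] %d case(s) excluded", sum(!keep)))
  }
  included <- which(keep)

  patch_seeds <- child_seeds(config$seed + 1L, nrow(cohort))
  feats <- vector("list", nrow(cohort))
  for (i in included) {
    ph <- generate_phantom(sim$phantom_specs[[i]])
    feats[[i]] <- tprm_case_features(ph$ct, config,
                                     patch_seed = patch_seeds[i])
    if (i %% 50 == 0) message(sprintf("[cases] %d/%d mapped", i, nrow(cohort)))
  }

  labs <- cohort$progressor[included]
  split <- stratified_split(labs, train_fraction = config$train_fraction,
                            seed = config$seed + 2L)
  patch_sets <- lapply(feats[included], function(f) f$patches)
  fit <- run_patch_model(patch_sets, labs, split,
                         n_atoms = config$n_atoms,
                         sparsity = config$sparsity,
                         n_iter = config$n_iter,
                         aggregation_threshold = config$aggregation_threshold,
                         seed = config$seed + 3L)

  means <- dplyr::bind_cols(
    tibble::tibble(case_id = cohort$case_id[included]),
    dplyr::bind_rows(lapply(feats[included], function(f) f$means)))
  base <- logistic_baseline(means[-1], labs, split)

  message(sprintf("[eval] patch model AUC %.3f, logistic baseline AUC %.3f",
                  fit$eval$auc, base$eval$auc))

  paths <- c(
    cohort = file.path(config$output_dir, "cohort.csv"),
    means = file.path(config$output_dir, "whole_lung_means.csv"),
    exclusions = file.path(config$output_dir, "exclusions.csv"),
    metrics = file.path(config$output_dir, "metrics.json"),
    roc = file.path(config$output_dir, "roc.csv"))
  write.csv(cohort, paths["cohort"], row.names = FALSE)
  write.csv(means, paths["means"], row.names = FALSE)
  write.csv(excluded, paths["exclusions"], row.names = FALSE)
  write.csv(fit$eval$roc, paths["roc"], row.names = FALSE)
  jsonlite::write_json(
    list(patch_model = as.list(glance(fit$eval)),
         logistic_baseline = as.list(glance(base$eval)),
         n_train = length(split$train), n_test = length(split$test),
         seed = config$seed),
    paths["metrics"], auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(
    list(cohort = cohort, means = means, split = split, model = fit$model,
         eval = fit$eval, scores = fit$scores, baseline = base,
         exclusions = excluded, included = included, config = config,
         paths = paths),
    class = "tprm_run")
}

#' @export
print.tprm_run <- function(x, ...) {
  cat(sprintf("<tprm_run> %d subjects (%d excluded), patch AUC %.3f, baseline AUC %.3f\n",
              nrow(x$cohort), nrow(x$exclusions), x$eval$auc,
              x$baseline$eval$auc))
  cat(sprintf("  artifacts: %s\n", x$config$output_dir))
  invisible(x)
}
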