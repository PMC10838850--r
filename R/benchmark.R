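#' Assemble the instance dataset of a phantom cohort (streaming)
#'
#' Renders one phantom at a time, extracts its `2N` instances with the given
#' sampling scheme and patch size, converts them to classifier features and
#' discards the volume — so cohort-scale extraction runs in bounded memory.
#' In gaussian mode each patient draws from an independent substream of
#' `scheme$seed`.
#'
#' @param truths cohort geometry from [generate_phantom_truths()].
#' @param spec the [phantom_spec()] that produced it.
#' @param scheme a [sampling_scheme()].
#' @param patch_size crop side `P` (in voxels of the phantom grid).
#' @return A [sinus_dataset()] covering all patients.
#' @export
assemble_instance_dataset <- function(truths, spec, scheme, patch_size) {
  labels <- truth_table(truths)
  n_inst <- 2L * scheme$n
  x <- matrix(0, length(truths) * n_inst, 4096L)
  metas <- vector("list", length(truths))
  for (i in seq_along(truths)) {
    vol <- render_phantom_volume(truths[[i]], spec, i)
    sch <- scheme
    if (sch$mode == "gaussian")
      sch$seed <- derive_seed(if (is.null(scheme$seed)) 0L else scheme$seed,
                              200000L + i)
    inst <- extract_instances(vol, spec$centroid_model, sch, patch_size)
    rows <- (i - 1L) * n_inst + seq_len(n_inst)
    x[rows, ] <- t(vapply(inst, instance_features, numeric(4096L)))
    m <- build_labeled_instances(inst, labels)
    m$instance <- rows
    metas[[i]] <- m
  }
  new_sinus_dataset(x, do.call(rbind, metas))
}

# train on one fold's train/val partitions and evaluate its test partition
# with and without MIE
run_one_fold <- function(ds, fold, config, fold_seed) {
  cfg <- config
  cfg$seed <- fold_seed
  pick <- function(p) fold$patient_id[fold$partition == p]
  train <- subset_dataset(ds, dataset_rows_for(ds, pick("train")))
  val <- subset_dataset(ds, dataset_rows_for(ds, pick("val")))
  test <- subset_dataset(ds, dataset_rows_for(ds, pick("test")))
  model <- train_classifier(train, val, cfg)
  list(model = model,
       mie = evaluate_fold(model, test, use_mie = TRUE),
       single = evaluate_fold(model, test, use_mie = FALSE))
}

#' Run the synthetic end-to-end benchmark
#'
#' The package's self-contained analogue of the study design: generate a
#' phantom cohort with ~32% anomalous sinuses, extract Gaussian-sampled
#' instances, train the tiny3d classifier under threefold patient-level
#' cross-validation, and evaluate each test fold both with MIE and with the
#' single-instance ablation. Defaults run on the half-scale geometry
#' (86 x 160 x 160 grid, `P = 18`, the half-scale counterpart of the
#' full-resolution optimum `P = 35`) with `N = 5` instances per sinus.
#'
#' @param n_patients cohort size (default 120).
#' @param prevalence per-sinus anomaly probability (default 0.32).
#' @param n_instances sample size `N` per sinus (default 5).
#' @param patch_size crop side in phantom-grid voxels (default 18).
#' @param scale phantom geometry scale (default 0.5).
#' @param k number of cross-validation folds (default 3).
#' @param epochs,learning_rate tiny3d training protocol for the benchmark;
#'   the phantom task separates quickly, so the default is a short schedule
#'   (12 epochs at 1e-3) rather than the full study protocol.
#' @param seed master seed; every stage derives its stream from it.
#' @param verbose print fold-level progress.
#' @return List with `per_fold` (fold, auprc_mie, f1_mie, auprc_single,
#'   f1_single), `summary` (per-metric mean and sd across folds), and
#'   `settings`.
#' @export
run_mie_benchmark <- function(n_patients = 120L, prevalence = 0.32,
                              n_instances = 5L, patch_size = 18L, scale = 0.5,
                              k = 3L, epochs = 12L, learning_rate = 1e-3,
                              seed = 1L, verbose = FALSE) {
  spec <- phantom_spec(n_patients, anomaly_prevalence_sinus = prevalence,
                       scale = scale, seed = derive_seed(seed, 1L))
  truths <- generate_phantom_truths(spec)
  labels <- truth_table(truths)
  scheme <- sampling_scheme("gaussian", n = n_instances,
                            seed = derive_seed(seed, 3L))
  ds <- assemble_instance_dataset(truths, spec, scheme, patch_size)
  folds <- make_folds(labels, k = k, seed = derive_seed(seed, 2L))
  config <- classifier_config("tiny3d", epochs = epochs,
                              learning_rate = learning_rate)
  per_fold <- do.call(rbind, lapply(seq_len(k), function(fi) {
    r <- run_one_fold(ds, folds[[fi]], config,
                      fold_seed = derive_seed(seed, 10L + fi))
    if (verbose)
      message(sprintf("fold %d: MIE AUPRC %.3f (F1 %.3f) | single AUPRC %.3f (F1 %.3f)",
                      fi, r$mie$auprc, r$mie$f1, r$single$auprc, r$single$f1))
    data.frame(fold = fi, auprc_mie = r$mie$auprc, f1_mie = r$mie$f1,
               auprc_single = r$single$auprc, f1_single = r$single$f1,
               n_test_sinuses = r$mie$n_sinuses)
  }))
  list(per_fold = per_fold,
       summary = cross_fold_summary(per_fold[, c("auprc_mie", "f1_mie",
                                                 "auprc_single", "f1_single")]),
       settings = list(n_patients = n_patients, prevalence = prevalence,
                       n_instances = n_instances, patch_size = patch_size,
                       scale = scale, k = k, epochs = epochs,
                       learning_rate = learning_rate, seed = seed))
}
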