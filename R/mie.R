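#' Multiple Instance Ensembling over the instances of one sinus
#'
#' The MIE prediction rule: the sinus-level probability vector is the
#' arithmetic mean of the instance-level softmax outputs,
#' `y_hat = (1/N) * sum_i softmax(f(x_i))`. With `N = 1` this reduces to the
#' single-instance prediction. Averaging over instances acts as implicit
#' test-time augmentation: the overlapping patches differ by small
#' translational offsets, and their consensus is more stable than any single
#' crop.
#'
#' @param model a `trained_classifier`, or a function mapping a
#'   [sinus_dataset()] to an n x 2 probability matrix (useful for stubs and
#'   ablations).
#' @param instances the instances of one sinus: a list of [sinus_instance()]
#'   objects or a [sinus_dataset()] whose rows all share one (patient, side).
#' @return An object of class `ensemble_prediction`: `patient_id`, `side`,
#'   `y_hat` (named probability pair), `n_instances`, and the per-instance
#'   probability matrix `instance_probs`.
#' @export
ensemble_predict <- function(model, instances) {
  ds <- if (inherits(instances, "sinus_dataset")) instances
  else {
    stopifnot(length(instances) >= 1L,
              all(vapply(instances, inherits, TRUE, "sinus_instance")))
    meta <- data.frame(
      instance = seq_along(instances),
      patient_id = vapply(instances, `[[`, "", "patient_id"),
      side = vapply(instances, `[[`, "", "side"),
      instance_index = vapply(instances, `[[`, 0L, "instance_index"),
      label = NA_integer_, stringsAsFactors = FALSE)
    new_sinus_dataset(t(vapply(instances, instance_features, numeric(4096L))),
                      meta)
  }
  if (nrow(ds$meta) < 1L) stop("need at least one instance", call. = FALSE)
  if (nrow(unique(ds$meta[, c("patient_id", "side")])) != 1L)
    stop("instances mix provenance: all must share one (patient, side)",
         call. = FALSE)
  probs <- model_probs(model, ds)
  y_hat <- colMeans(probs)
  structure(list(patient_id = ds$meta$patient_id[1], side = ds$meta$side[1],
                 y_hat = c(p_normal = y_hat[[1]], p_anomalous = y_hat[[2]]),
                 n_instances = nrow(probs), instance_probs = probs),
            class = "ensemble_prediction")
}

# instance probabilities from either a trained classifier or a stub function
model_probs <- function(model, ds) {
  probs <- if (is.function(model)) model(ds)
  else if (inherits(model, "trained_classifier")) predict_proba(model, ds)
  else stop("'model' must be a trained_classifier or a function", call. = FALSE)
  stopifnot(is.matrix(probs), nrow(probs) == nrow(ds$meta), ncol(probs) == 2L)
  probs
}

#' Evaluate one test fold, with or without MIE
#'
#' With `use_mie = TRUE` each sinus is scored by the MIE rule over all its
#' instances; with `use_mie = FALSE` by its first sampled instance only (the
#' single-volume ablation). Sinus-level AUPRC and F1 are computed with
#' anomalous as the positive class; the F1 decision threshold is 0.5 on the
#' anomalous probability, with exact ties classified positive.
#'
#' @param model a `trained_classifier` or stub function (see
#'   [ensemble_predict()]).
#' @param test_set a [sinus_dataset()] of extracted test instances with
#'   labels.
#' @param use_mie logical.
#' @return One-row data frame: `auprc`, `f1`, `n_sinuses`, `unit`.
#' @export
evaluate_fold <- function(model, test_set, use_mie = TRUE) {
  stopifnot(inherits(test_set, "sinus_dataset"))
  probs <- model_probs(model, test_set)
  meta <- test_set$meta
  key <- paste(meta$patient_id, meta$side)
  groups <- split(seq_len(nrow(meta)), key)
  score <- vapply(groups, function(rows) {
    if (use_mie) mean(probs[rows, 2])
    else probs[rows[which.min(meta$instance_index[rows])], 2]
  }, 0)
  label <- vapply(groups, function(rows) meta$label[rows[1]], 0L)
  predicted <- as.integer(score >= 0.5)
  data.frame(auprc = auprc(label, score), f1 = f1(label, predicted),
             n_sinuses = length(groups),
             unit = if (use_mie) "per_sinus_MIE" else "per_instance",
             stringsAsFactors = FALSE)
}
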