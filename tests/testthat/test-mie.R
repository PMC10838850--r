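# a minimal dataset of k instances of one sinus (features are irrelevant when
# probabilities come from a stub)
one_sinus_ds <- function(k, patient = "pA", side = "left", label = 1L) {
  meta <- data.frame(instance = seq_len(k), patient_id = patient, side = side,
                     instance_index = seq_len(k), label = label,
                     stringsAsFactors = FALSE)
  sinusmie:::new_sinus_dataset(matrix(0, k, 4096), meta)
}

test_that("the ensemble probability is exactly the instance mean", {
  probs <- rbind(c(0.2, 0.8), c(0.6, 0.4))
  ep <- ensemble_predict(stub_model(probs), one_sinus_ds(2))
  expect_equal(unname(ep$y_hat), c(0.4, 0.6))
  expect_equal(sum(ep$y_hat), 1)
  expect_equal(ep$n_instances, 2L)

  # N = 1 reduces to the single instance's probabilities
  ep1 <- ensemble_predict(stub_model(probs[1, , drop = FALSE]), one_sinus_ds(1))
  expect_equal(unname(ep1$y_hat), c(0.2, 0.8))

  # identical instances: mean equals the common pair
  same <- matrix(rep(c(0.3, 0.7), each = 5), 5)
  expect_equal(unname(ensemble_predict(stub_model(same), one_sinus_ds(5))$y_hat),
               c(0.3, 0.7))

  # linearity: duplicating the instance list leaves the ensemble unchanged
  dup <- rbind(probs, probs)
  expect_equal(ensemble_predict(stub_model(dup), one_sinus_ds(4))$y_hat,
               ep$y_hat)
})

test_that("mixed provenance and empty input are rejected", {
  meta <- data.frame(instance = 1:2, patient_id = c("pA", "pB"),
                     side = "left", instance_index = 1L, label = 0L,
                     stringsAsFactors = FALSE)
  ds <- sinusmie:::new_sinus_dataset(matrix(0, 2, 4096), meta)
  expect_error(ensemble_predict(stub_model(matrix(0.5, 2, 2)), ds),
               "provenance")
})

test_that("ensemble_predict accepts raw instance lists and a real model", {
  fix <- tiny_cohort()
  rows <- which(fix$ds$meta$patient_id %in% sprintf("phantom%04d", 1:12))
  cfg <- classifier_config("tiny3d", epochs = 2, learning_rate = 1e-3,
                           conv_channels = c(2L, 4L), seed = 3)
  model <- train_classifier(
    sinusmie:::subset_dataset(fix$ds, rows),
    sinusmie:::subset_dataset(fix$ds, setdiff(seq_len(nrow(fix$ds$meta)), rows)),
    cfg)
  vol <- render_phantom_volume(fix$truths[[1]], fix$spec, 1)
  inst <- extract_instances(vol, fix$spec$centroid_model,
                            sampling_scheme("gaussian", n = 3, seed = 5), 11)
  left <- inst[1:3]
  ep <- ensemble_predict(model, left)
  per_inst <- t(vapply(left, function(i) predict_proba(model, i), numeric(2)))
  expect_equal(unname(ep$y_hat), unname(colMeans(per_inst)), tolerance = 1e-12)
})

test_that("fold evaluation scores per sinus, honoring the MIE flag", {
  fix <- tiny_cohort()
  test_ds <- fix$ds
  # oracle stub: perfect either way
  r_mie <- evaluate_fold(truth_stub, test_ds, use_mie = TRUE)
  r_one <- evaluate_fold(truth_stub, test_ds, use_mie = FALSE)
  expect_equal(r_mie$auprc, 1); expect_equal(r_mie$f1, 1)
  expect_equal(r_one$auprc, 1); expect_equal(r_one$f1, 1)
  expect_equal(r_mie$unit, "per_sinus_MIE")
  expect_equal(r_one$unit, "per_instance")
  expect_equal(r_mie$n_sinuses, nrow(fix$labels))

  # constant 0.5 stub: ties classify positive, so every sinus is predicted
  # anomalous -> F1 = 2P / (2P + Neg)
  const <- function(ds) matrix(0.5, nrow(ds$meta), 2)
  r <- evaluate_fold(const, test_ds, use_mie = TRUE)
  P <- sum(fix$labels$label == 1); Neg <- sum(fix$labels$label == 0)
  expect_equal(r$f1, 2 * P / (2 * P + Neg))
  # constant score AUPRC equals prevalence
  expect_equal(r$auprc, P / (P + Neg))
})

test_that("single-instance mode uses the first sampled instance only", {
  # stub scoring instance 1 with the truth and later instances with noise:
  # single-instance evaluation must be perfect, regardless of the noise
  fix <- tiny_cohort()
  meta <- fix$ds$meta
  set.seed(31)
  p_anom <- ifelse(meta$instance_index == 1L, meta$label, runif(nrow(meta)))
  stub <- stub_model(cbind(1 - p_anom, p_anom))
  r <- evaluate_fold(stub, fix$ds, use_mie = FALSE)
  expect_equal(r$auprc, 1); expect_equal(r$f1, 1)
})
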