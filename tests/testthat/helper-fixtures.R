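# shared fixtures, built once per test run

.fixture_env <- new.env()

# small rendered cohort shared by dataset / classifier / mie tests
tiny_cohort <- function() {
  if (is.null(.fixture_env$tiny)) {
    spec <- phantom_spec(16, anomaly_prevalence_sinus = 0.35, scale = 0.3,
                         seed = 402L)
    truths <- generate_phantom_truths(spec)
    scheme <- sampling_scheme("gaussian", n = 2, seed = 11L)
    ds <- assemble_instance_dataset(truths, spec, scheme, patch_size = 11)
    .fixture_env$tiny <- list(spec = spec, truths = truths, scheme = scheme,
                              labels = truth_table(truths), ds = ds)
  }
  .fixture_env$tiny
}

# a 64^3 instance cube: mid background plus optional bright central blob
synthetic_cube <- function(anomalous, seed) {
  set.seed(seed)
  arr <- array(0.5 + rnorm(64^3, 0, 0.05), c(64, 64, 64))
  if (anomalous) {
    idx <- as.matrix(expand.grid(1:64, 1:64, 1:64))
    d2 <- rowSums((idx - 32)^2)
    arr[d2 <= 8^2] <- 0.9
  }
  arr
}

# label table for a hand-built patient set: one row per sinus
hand_labels <- function(pos_per_patient) {
  do.call(rbind, lapply(seq_along(pos_per_patient), function(i) {
    k <- pos_per_patient[i]
    data.frame(patient_id = sprintf("p%03d", i), side = c("left", "right"),
               label = c(as.integer(k >= 1), as.integer(k >= 2)),
               stringsAsFactors = FALSE)
  }))
}

# brute-force average precision: explicit precision/recall sweep over every
# distinct threshold, written independently of the package implementation
ap_oracle <- function(labels, scores) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0; ap <- 0
  n_pos <- sum(labels == 1)
  for (t in ths) {
    pred <- as.integer(scores >= t)
    tp <- sum(pred == 1 & labels == 1)
    fp <- sum(pred == 1 & labels == 0)
    precision <- tp / (tp + fp)
    recall <- tp / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# stub "model": returns a fixed probability matrix regardless of weights
stub_model <- function(prob_matrix) {
  force(prob_matrix)
  function(ds) {
    stopifnot(nrow(ds$meta) == nrow(prob_matrix))
    prob_matrix
  }
}

# stub that scores every instance with its sinus's true label
truth_stub <- function(ds) cbind(1 - ds$meta$label, ds$meta$label)
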