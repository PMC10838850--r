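#' Attach per-sinus labels to extracted instances
#'
#' Every instance of a sinus inherits that sinus's label (anomalous = 1 is the
#' positive class). Labels come as one record per (patient, side), e.g. the
#' phantom [truth_table()] or a user-supplied table with the same columns.
#'
#' @param instances list of [sinus_instance()] objects.
#' @param labels data frame with columns `patient_id`, `side`, `label`.
#' @return Data frame with one row per instance: `instance` (index into
#'   `instances`), `patient_id`, `side`, `instance_index`, `label`.
#' @export
build_labeled_instances <- function(instances, labels) {
  stopifnot(is.data.frame(labels),
            all(c("patient_id", "side", "label") %in% names(labels)))
  if (length(instances) == 0L)
    return(data.frame(instance = integer(0), patient_id = character(0),
                      side = character(0), instance_index = integer(0),
                      label = integer(0), stringsAsFactors = FALSE))
  key <- paste(labels$patient_id, labels$side)
  if (anyDuplicated(key))
    stop("labels must have one record per (patient, side)", call. = FALSE)
  meta <- data.frame(
    instance = seq_along(instances),
    patient_id = vapply(instances, `[[`, "", "patient_id"),
    side = vapply(instances, `[[`, "", "side"),
    instance_index = vapply(instances, `[[`, 0L, "instance_index"),
    stringsAsFactors = FALSE)
  ikey <- paste(meta$patient_id, meta$side)
  hit <- match(ikey, key)
  if (anyNA(hit)) {
    missing <- sort(unique(ikey[is.na(hit)]))
    stop("no label for sinus(es): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  meta$label <- as.integer(labels$label[hit])
  meta
}

# --- instance features -------------------------------------------------------

# per-instance min-max normalization to [0, 1]; constant inputs map to 0
normalize_minmax <- function(arr) {
  r <- range(arr)
  if (r[2] - r[1] <= 0) return(arr * 0)
  (arr - r[1]) / (r[2] - r[1])
}

# fixed 4x average pool of a 64^3 array -> length-4096 vector (16^3, x fastest)
pool4_features <- function(arr64) {
  a <- array(arr64, c(4L, 16L, 4L, 16L, 4L, 16L))
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  colMeans(matrix(a, 64L, 4096L))
}

instance_features <- function(x) {
  arr <- if (inherits(x, "sinus_instance")) x$data else x
  pool4_features(normalize_minmax(arr))
}

#' Assemble a classifier-ready dataset from instances and labels
#'
#' Pairs the instance metadata from [build_labeled_instances()] with the
#' classifier's input representation. The tiny3d network's first stage is a
#' fixed (parameter-free) 4x average pool of the min-max-normalized 64^3
#' cube; it is precomputed here, once per instance, so a cohort's worth of
#' instances fits comfortably in memory.
#'
#' @param instances list of [sinus_instance()] objects.
#' @param labels per-sinus label table (see [build_labeled_instances()]).
#' @return An object of class `sinus_dataset`: list with `x` (numeric matrix,
#'   one row of 4096 pooled features per instance) and `meta` (the labeled
#'   instance table).
#' @export
sinus_dataset <- function(instances, labels) {
  meta <- build_labeled_instances(instances, labels)
  x <- t(vapply(instances, instance_features, numeric(4096L)))
  new_sinus_dataset(x, meta)
}

new_sinus_dataset <- function(x, meta) {
  stopifnot(is.matrix(x), nrow(x) == nrow(meta))
  structure(list(x = x, meta = meta), class = "sinus_dataset")
}

#' @export
print.sinus_dataset <- function(x, ...) {
  cat(sprintf("sinus_dataset: %d instances, %d sinuses, %.1f%% anomalous\n",
              nrow(x$meta),
              nrow(unique(x$meta[, c("patient_id", "side")])),
              100 * mean(x$meta$label)))
  invisible(x)
}

subset_dataset <- function(ds, rows) {
  new_sinus_dataset(ds$x[rows, , drop = FALSE], ds$meta[rows, , drop = FALSE])
}

# rows of `ds` belonging to the given patients
dataset_rows_for <- function(ds, patient_ids) {
  which(ds$meta$patient_id %in% patient_ids)
}

# --- cross-validation folds --------------------------------------------------

# deterministic per-stratum partition counts via largest remainder
largest_remainder <- function(n, frac) {
  raw <- n * frac
  base <- floor(raw)
  short <- round(sum(raw)) - sum(base)
  if (short > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(short)]] <- base[order_rem[seq_len(short)]] + 1L
  }
  as.integer(base)
}

#' Patient-level stratified train/validation/test folds
#'
#' Builds `k` independent patient-level splits. Assignment is at patient level
#' (both sinuses and all their sampled instances follow the patient, so no
#' patient leaks across partitions) while stratification targets the
#' sinus-level positive fraction: patients are grouped by their number of
#' anomalous sinuses (0, 1 or 2) and each partition receives a deterministic,
#' largest-remainder share of every stratum; a greedy repair pass then swaps
#' patients between train and the smaller partitions until each partition's
#' anomalous-sinus fraction is within `tolerance` of `positive_frac_target`.
#' Partition size profiles depend only on the label table and the fractions,
#' so two seeds give identical profiles with different memberships.
#'
#' @param labels per-sinus label table (`patient_id`, `side`, `label`).
#' @param k number of folds (default 3).
#' @param val_frac,test_frac patient fractions for validation and test;
#'   defaults follow the study's 327/37/41 sinus split proportions.
#' @param positive_frac_target target anomalous-sinus fraction per partition;
#'   `NULL` (default) targets the cohort's realized fraction.
#' @param tolerance maximum absolute deviation from the target (default 0.03).
#' @param seed integer seed.
#' @return List of `k` fold splits, each a data frame
#'   (`fold`, `patient_id`, `partition`).
#' @export
make_folds <- function(labels, k = 3L, val_frac = 37 / 405, test_frac = 41 / 405,
                       positive_frac_target = NULL, tolerance = 0.03,
                       seed = 1L) {
  stopifnot(is.data.frame(labels),
            all(c("patient_id", "side", "label") %in% names(labels)))
  if (val_frac < 0 || test_frac < 0 || val_frac + test_frac >= 1)
    stop("'val_frac' and 'test_frac' must be non-negative and sum below 1",
         call. = FALSE)
  per_pat <- tapply(labels$label, labels$patient_id, sum)
  pats <- names(per_pat)
  n <- length(pats)
  strata <- as.integer(per_pat)                  # anomalous sinuses per patient
  sinuses_per_pat <- as.integer(table(labels$patient_id)[pats])
  if (is.null(positive_frac_target))
    positive_frac_target <- mean(labels$label)
  lapply(seq_len(k), function(fold) {
    part <- with_seed(derive_seed(seed, fold), {
      assign_partitions(pats, strata, sinuses_per_pat, val_frac, test_frac,
                        positive_frac_target, tolerance)
    })
    data.frame(fold = fold, patient_id = pats, partition = part,
               stringsAsFactors = FALSE)
  })
}

assign_partitions <- function(pats, strata, sinuses_per_pat, val_frac,
                              test_frac, target, tolerance) {
  n <- length(pats)
  # strata are (anomalous sinuses, total sinuses) pairs so that partition
  # composition determines the positive fraction exactly at count level
  key <- paste(strata, sinuses_per_pat)
  lev <- sort(unique(key))
  anom_j <- as.integer(sub(" .*", "", lev))
  sin_j <- as.integer(sub(".* ", "", lev))
  n_s <- vapply(lev, function(s) sum(key == s), 0L)
  counts <- list(test = largest_remainder(n_s, test_frac),
                 val = largest_remainder(n_s, val_frac))
  counts$train <- n_s - counts$test - counts$val
  if (any(counts$train < 0))
    stop("infeasible stratification: a stratum is too small for the requested fractions",
         call. = FALSE)
  # greedy count-level repair: swap one patient between train and the smaller
  # partitions while it brings the partition's positive fraction closer to
  # the target (partition patient counts are preserved)
  objective <- function(cnt) {
    s <- sum(cnt * sin_j)
    if (s == 0) return(0)
    abs(sum(cnt * anom_j) / s - target)
  }
  for (p in c("test", "val")) {
    for (iter in 1:200) {
      best <- objective(counts[[p]]); move <- NULL
      for (a in seq_along(lev)) for (b in seq_along(lev)) {
        if (a == b || counts$train[a] == 0L || counts[[p]][b] == 0L) next
        cand <- counts[[p]]; cand[a] <- cand[a] + 1L; cand[b] <- cand[b] - 1L
        if (objective(cand) < best - 1e-12) { best <- objective(cand); move <- c(a, b) }
      }
      if (is.null(move)) break
      counts[[p]][move[1]] <- counts[[p]][move[1]] + 1L
      counts[[p]][move[2]] <- counts[[p]][move[2]] - 1L
      counts$train[move[1]] <- counts$train[move[1]] - 1L
      counts$train[move[2]] <- counts$train[move[2]] + 1L
    }
    if (sum(counts[[p]]) > 0 && objective(counts[[p]]) > tolerance)
      stop(sprintf(
        "infeasible stratification: %s positive fraction %.3f outside %.2f +/- %.2f",
        p, sum(counts[[p]] * anom_j) / sum(counts[[p]] * sin_j), target,
        tolerance), call. = FALSE)
  }
  part <- rep("train", n)
  for (j in seq_along(lev)) {
    w <- which(key == lev[j])
    members <- w[sample.int(length(w))]          # shuffled within stratum
    n_t <- counts$test[j]; n_v <- counts$val[j]
    if (n_t > 0) part[members[seq_len(n_t)]] <- "test"
    if (n_v > 0) part[members[n_t + seq_len(n_v)]] <- "val"
  }
  part
}

#' Write / read fold assignments
#'
#' Serializes folds as a tab-delimited table (`fold`, `patient_id`,
#' `partition`).
#'
#' @param folds result of [make_folds()].
#' @param path file path.
#' @return `read_folds` returns the list of fold data frames.
#' @export
write_folds <- function(folds, path) {
  utils::write.table(do.call(rbind, folds), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_folds
#' @export
read_folds <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  lapply(split(tab, tab$fold), function(d) { rownames(d) <- NULL; d })
}
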