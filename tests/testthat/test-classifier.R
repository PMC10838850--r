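test_that("softmax outputs are distributions with closed-form values", {
  sm <- sinusmie:::softmax_rows
  expect_equal(sm(matrix(c(0, 0), 1)), matrix(c(0.5, 0.5), 1))
  expect_equal(sm(matrix(c(log(3), 0), 1)), matrix(c(0.75, 0.25), 1))
  set.seed(2)
  z <- matrix(rnorm(40), 20)
  p <- sm(z)
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 20), tolerance = 1e-12)
})

test_that("the plateau schedule obeys the patience/factor contract", {
  # flat validation loss: reductions after epochs 6 and 11 -> initial/100
  lr <- plateau_schedule(rep(1, 11), lr0 = 1e-4, patience = 5, factor = 10)
  expect_equal(lr[11], 1e-6)
  expect_equal(lr[5], 1e-4); expect_equal(lr[6], 1e-5); expect_equal(lr[10], 1e-5)

  # improving loss never reduces
  expect_equal(plateau_schedule(seq(1, 0.1, length.out = 20), 1e-3),
               rep(1e-3, 20))

  # property: agree with an independent step-by-step simulation
  set.seed(10)
  for (rep in 1:20) {
    losses <- round(runif(30), 2)
    got <- plateau_schedule(losses, lr0 = 0.01, patience = 3, factor = 2)
    lr <- 0.01; best <- Inf; bad <- 0; want <- numeric(30)
    for (e in 1:30) {
      if (losses[e] < best) { best <- losses[e]; bad <- 0 }
      else if ((bad <- bad + 1) >= 3) { lr <- lr / 2; bad <- 0 }
      want[e] <- lr
    }
    expect_equal(got, want)
  }
})

test_that("fast average pooling matches the reference accumulation loop", {
  set.seed(3)
  n <- 5L; D <- 8L; C <- 4L
  A <- matrix(rnorm(n * D^3 * C), n * D^3, C)
  expect_equal(sinusmie:::avgpool2_fast(A, n, D, C),
               sinusmie:::avgpool2_fwd(A, n, D, C), tolerance = 1e-12)
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(14)
  par <- sinusmie:::tiny3d_init(2L, 3L, seed = 5)
  X <- matrix(runif(3 * 4096), 3, 4096)
  y <- c(0L, 1L, 1L)
  cache <- sinusmie:::tiny3d_forward(par, X, keep = TRUE)
  grads <- sinusmie:::tiny3d_backward(par, cache, y)$grads
  eps <- 1e-5
  for (nm in names(grads)) {
    w <- par[[nm]]
    for (flat in sample(length(w), min(5, length(w)))) {
      pp <- par; pp[[nm]][flat] <- w[flat] + eps
      pm <- par; pm[[nm]][flat] <- w[flat] - eps
      num <- (sinusmie:::tiny3d_loss(pp, X, y) -
                sinusmie:::tiny3d_loss(pm, X, y)) / (2 * eps)
      expect_equal(grads[[nm]][flat], num, tolerance = 1e-4,
                   label = sprintf("d%s[%d]", nm, flat))
    }
  }
})

test_that("training separates blob-bearing cubes as well as a threshold oracle", {
  cubes <- lapply(1:40, function(i) synthetic_cube(i %% 2 == 0, seed = i))
  labels <- rep(c(0L, 1L), 20)
  inst <- lapply(1:40, function(i)
    sinus_instance(cubes[[i]], c(32, 32, 32), 35, "left",
                   sprintf("p%02d", i), 1L))
  lab_tab <- data.frame(patient_id = sprintf("p%02d", 1:40), side = "left",
                        label = labels)
  ds <- sinus_dataset(inst, lab_tab)
  tr <- sinusmie:::subset_dataset(ds, 1:32)
  va <- sinusmie:::subset_dataset(ds, 33:40)

  # intensity-threshold oracle: the classes are separable by the mean of the
  # normalized features (direction-agnostic threshold at the class midpoint)
  m <- rowMeans(tr$x)
  thr <- mean(tapply(m, tr$meta$label, mean))
  pred <- as.integer(m > thr)
  oracle_acc <- max(mean(pred == tr$meta$label),
                    mean((1L - pred) == tr$meta$label))
  expect_gt(oracle_acc, 0.95)

  cfg <- classifier_config("tiny3d", epochs = 60, learning_rate = 3e-3,
                           conv_channels = c(4L, 8L), seed = 2)
  model <- train_classifier(tr, va, cfg)
  p <- predict_proba(model, tr)
  acc <- mean(as.integer(p[, 2] >= 0.5) == tr$meta$label)
  expect_gt(acc, 0.95)

  # probabilities are distributions; single-instance prediction agrees
  expect_equal(rowSums(p), rep(1, 32), tolerance = 1e-6)
  p1 <- predict_proba(model, inst[[1]])
  expect_equal(unname(p1), unname(p[1, ]), tolerance = 1e-12)

  # learning-rate column follows the plateau policy replayed on the history
  replay <- plateau_schedule(model$history$val_loss, cfg$learning_rate,
                             cfg$plateau_patience, cfg$plateau_factor)
  expect_equal(model$history$lr, c(cfg$learning_rate, replay[-length(replay)]))
  expect_true(all(diff(model$history$lr) <= 0))

  # checkpoints survive a plain-text round trip
  path <- withr::local_tempfile(fileext = ".txt")
  save_classifier(model, path)
  model2 <- load_classifier(path)
  expect_equal(predict_proba(model2, tr), p, tolerance = 1e-12)
})

test_that("training is reproducible and rejects invalid inputs", {
  fix <- tiny_cohort()
  rows <- which(fix$ds$meta$patient_id %in% sprintf("phantom%04d", 1:12))
  tr <- sinusmie:::subset_dataset(fix$ds, rows)
  va <- sinusmie:::subset_dataset(fix$ds, setdiff(seq_len(nrow(fix$ds$meta)), rows))
  cfg <- classifier_config("tiny3d", epochs = 2, learning_rate = 1e-3,
                           conv_channels = c(2L, 4L), seed = 7)
  m1 <- train_classifier(tr, va, cfg)
  m2 <- train_classifier(tr, va, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$par, m2$par)

  only_norm <- sinusmie:::subset_dataset(tr, which(tr$meta$label == 0))
  expect_error(train_classifier(only_norm, va, cfg), "both classes")

  expect_error(classifier_config("resnet3d", depth = 19), "depth")
  cfg_rn <- classifier_config("resnet3d", depth = 200)
  expect_error(train_classifier(tr, va, cfg_rn), "tiny3d")
  expect_error(predict_proba(m1, array(0, c(32, 32, 32))), "64x64x64")
})
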