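test_that("phantom cohorts are bit-identical under a fixed spec", {
  spec <- phantom_spec(3, scale = 0.25, seed = 99)
  a <- generate_phantom_cohort(spec)
  b <- generate_phantom_cohort(spec)
  expect_identical(a$truths, b$truths)
  for (i in 1:3) expect_identical(a$volumes[[i]]$data, b$volumes[[i]]$data)

  # streaming render equals batch render
  v2 <- render_phantom_volume(a$truths[[2]], spec, 2)
  expect_identical(v2$data, a$volumes[[2]]$data)
})

test_that("zero prevalence yields an all-normal cohort", {
  spec <- phantom_spec(10, anomaly_prevalence_sinus = 0, scale = 0.25, seed = 4)
  tab <- truth_table(generate_phantom_truths(spec))
  expect_equal(nrow(tab), 20L)
  expect_true(all(tab$label == 0L))
})

test_that("realized prevalence matches the configured rate at cohort scale", {
  spec <- phantom_spec(3000, anomaly_prevalence_sinus = 0.32, seed = 12)
  tab <- truth_table(generate_phantom_truths(spec))
  expect_equal(nrow(tab), 6000L)
  expect_lt(abs(mean(tab$label) - 0.32), 0.02)
})

test_that("true centroids follow the configured per-axis law", {
  spec <- phantom_spec(10000, seed = 55)
  truths <- generate_phantom_truths(spec)
  n <- length(truths)
  for (side in c("left", "right")) {
    st <- empirical_centroid_stats(truths, side)
    mu <- spec$centroid_model[[side]]$mu
    sigma <- spec$centroid_model[[side]]$sigma
    expect_true(all(abs(st$mean - mu) < 3 * sigma / sqrt(n)))
    expect_true(all(abs(st$sd - sigma) < 0.1 * sigma))
  }
})

test_that("empirical centroid statistics match hand arithmetic", {
  mk <- function(cent) structure(list(
    patient_id = "p", left = list(centroid = cent, radii = c(3, 3, 3),
                                  label = 0L, anomaly = NULL),
    right = list(centroid = cent + 10, radii = c(3, 3, 3), label = 0L,
                 anomaly = NULL)), class = "phantom_truth")
  c0 <- c(30, 40, 50)
  truths <- list(mk(c0), mk(c0 + c(2, 0, 0)))
  st <- empirical_centroid_stats(truths, "left")
  expect_equal(st$mean, c0 + c(1, 0, 0))
  expect_equal(st$sd, c(sqrt(2), 0, 0))   # sample (n-1) convention

  same <- list(mk(c0), mk(c0), mk(c0))
  st <- empirical_centroid_stats(same, "left")
  expect_equal(st$mean, c0); expect_equal(st$sd, c(0, 0, 0))

  expect_error(empirical_centroid_stats(list(mk(c0)), "left"), "two")
})

test_that("anomalous cavities are brighter inside than normal cavities", {
  spec <- phantom_spec(12, anomaly_prevalence_sinus = 0.5, scale = 0.3,
                       seed = 21)
  truths <- generate_phantom_truths(spec)
  cavity_mean <- function(vol, s) {
    dims <- dim(vol$data)
    idx <- as.matrix(expand.grid(x = 0:(dims[1] - 1), y = 0:(dims[2] - 1),
                                 z = 0:(dims[3] - 1)))
    inside <- rowSums(sweep(sweep(idx, 2, s$centroid), 2, s$radii, "/")^2) <= 1
    mean(vol$data[inside])
  }
  means <- list(normal = c(), anomalous = c())
  for (i in seq_along(truths)) {
    vol <- render_phantom_volume(truths[[i]], spec, i)
    for (side in c("left", "right")) {
      s <- truths[[i]][[side]]
      cls <- if (s$label == 1) "anomalous" else "normal"
      means[[cls]] <- c(means[[cls]], cavity_mean(vol, s))
    }
  }
  expect_gt(length(means$normal), 0); expect_gt(length(means$anomalous), 0)
  expect_gt(mean(means$anomalous), mean(means$normal) + 0.05)
})

test_that("impossible or invalid geometry is rejected up front", {
  expect_error(phantom_spec(2, scale = 0.1, cavity_radius_range = c(50, 60)),
               "impossible geometry")
  expect_error(phantom_spec(2, anomaly_prevalence_sinus = 1.5), "prevalence")
  expect_error(phantom_spec(2, noise_sd = -1), "noise_sd")
})

test_that("cohorts round-trip through NIfTI and the truth table", {
  dir <- withr::local_tempdir()
  spec <- phantom_spec(2, scale = 0.25, seed = 17)
  tab <- write_phantom_cohort(spec, dir)
  expect_setequal(list.files(dir),
                  c("phantom0001.nii.gz", "phantom0002.nii.gz", "truth.tsv"))
  vol <- read_volume(file.path(dir, "phantom0001.nii.gz"))
  ref <- generate_phantom_cohort(spec)$volumes[[1]]
  expect_equal(vol$data, ref$data, tolerance = 1e-6)
  expect_equal(vol$voxel_size_mm, ref$voxel_size_mm, tolerance = 1e-5)
  tab2 <- utils::read.table(file.path(dir, "truth.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  expect_equal(tab2$label, tab$label)
  expect_equal(tab2$cx, tab$cx, tolerance = 1e-9)
})
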