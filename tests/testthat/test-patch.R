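test_that("patch extraction centers the crop and zero-pads outside the volume", {
  # constant volume -> constant patch
  v <- array(3.5, c(20, 20, 20))
  expect_equal(extract_patch(v, c(10, 10, 10), 7), array(3.5, c(7, 7, 7)))

  # marker volume: value 1 at 0-based voxel (8, 9, 10); extracting at that
  # centroid with P = 5 puts the marker at the patch center (0-based (2,2,2))
  v <- array(0, c(20, 20, 20)); v[9, 10, 11] <- 1
  p <- extract_patch(v, c(8, 9, 10), 5)
  expect_equal(dim(p), c(5, 5, 5))
  expect_equal(which(p == 1), 2 + 2 * 5 + 2 * 25 + 1)

  # centroid near the boundary: padded voxels agree with a brute-force
  # per-voxel bounds check
  v <- array(1, c(30, 30, 30))
  P <- 25L; cen <- c(1, 15, 15)
  p <- extract_patch(v, cen, P)
  start <- round(cen + 0.5 - 0.5) - floor(P / 2)  # round-half-up then offset
  oracle <- array(0, c(P, P, P))
  for (i in 0:(P - 1)) for (j in 0:(P - 1)) for (k in 0:(P - 1)) {
    src <- start + c(i, j, k)
    if (all(src >= 0) && all(src <= 29)) oracle[i + 1, j + 1, k + 1] <- 1
  }
  expect_equal(p, oracle)
  expect_gt(sum(p == 0), 0)

  # fully outside -> localization failure
  expect_error(extract_patch(v, c(200, 200, 200), 5), "localization")
})

test_that("round-half-up is used when snapping centroids to the grid", {
  v <- array(0, c(11, 11, 11)); v[7, 6, 6] <- 1  # 0-based (6, 5, 5)
  p <- extract_patch(v, c(5.5, 5.2, 5.2), 3)     # x rounds up to 6
  expect_equal(p[2, 2, 2], 1)
})

test_that("the coronal flip mirrors x, is an involution, and fixes symmetric cubes", {
  set.seed(5)
  c1 <- array(rnorm(4^3), c(4, 4, 4))
  expect_equal(flip_right_sinus(flip_right_sinus(c1)), c1)

  sym <- c1 + flip_right_sinus(c1)               # symmetric in x by construction
  expect_equal(flip_right_sinus(sym), sym)

  m <- array(0, c(3, 3, 3)); m[1, 2, 2] <- 1
  expect_equal(which(flip_right_sinus(m)[, 2, 2] == 1), 3L)
})

test_that("trilinear resampling fixes constants, identity grids and linear ramps", {
  expect_equal(resample_to_input(array(2.25, c(25, 25, 25))),
               array(2.25, c(64, 64, 64)))

  set.seed(8)
  c64 <- array(rnorm(64^3), c(64, 64, 64))
  expect_lt(max(abs(resample_to_input(c64) - c64)), 1e-6)

  # linear functions are fixed points of trilinear interpolation: a ramp along
  # x resamples to the ramp on the rescaled coordinate
  P <- 35L
  ramp <- array(rep(0:(P - 1), times = P^2), c(P, P, P))
  out <- resample_to_input(ramp)
  expected <- array(rep((0:63) * (P - 1) / 63, times = 64^2), c(64, 64, 64))
  expect_lt(max(abs(out - expected)), 1e-6)

  # output range never exceeds input range
  p <- array(runif(9^3), c(9, 9, 9))
  out <- resample_to_input(p)
  expect_gte(min(out), min(p)); expect_lte(max(out), max(p))

  expect_error(resample_to_input(array(1, c(1, 1, 1))), "smaller")
})

test_that("extract_instances yields 2N 64-cube instances preserving order", {
  spec <- phantom_spec(1, scale = 0.3, seed = 31)
  vol <- render_phantom_volume(generate_phantom_truths(spec)[[1]], spec, 1)
  for (n in c(1L, 15L)) {
    inst <- extract_instances(vol, spec$centroid_model,
                              sampling_scheme("gaussian", n = n, seed = 2), 11)
    expect_length(inst, 2L * n)
    expect_true(all(vapply(inst, function(i)
      identical(dim(i$data), c(64L, 64L, 64L)), TRUE)))
    expect_equal(vapply(inst, `[[`, 0L, "instance_index"), rep(seq_len(n), 2))
    expect_equal(vapply(inst, `[[`, "", "side"),
                 rep(c("left", "right"), each = n))
  }
})

test_that("mirrored volumes with swapped sides give identical instances", {
  # extracting the right sinus of a volume equals extracting the left sinus
  # of its x-mirror at the mirrored centroid (flip applied per convention)
  spec <- phantom_spec(1, scale = 0.3, seed = 77)
  vol <- render_phantom_volume(generate_phantom_truths(spec)[[1]], spec, 1)
  dims <- dim(vol$data)
  mirrored <- volume_image(flip_right_sinus(vol$data), vol$voxel_size_mm, "m")

  right_mu <- round(spec$centroid_model$right$mu)
  left_mu_mirror <- c(dims[1] - 1 - right_mu[1], right_mu[2:3])
  m1 <- centroid_model(left_mu = left_mu_mirror, right_mu = right_mu,
                       right_sigma = c(1, 1, 1), reference_shape = dims)
  m2 <- centroid_model(left_mu = left_mu_mirror, right_mu = right_mu,
                       left_sigma = c(1, 1, 1), reference_shape = dims)
  sch <- sampling_scheme("equidistant", n = 1)
  i_right <- extract_instances(vol, m1, sch, 15)[[2]]       # right of original
  i_left <- extract_instances(mirrored, m2, sch, 15)[[1]]   # left of mirror
  expect_lt(max(abs(i_right$data - i_left$data)), 1e-9)
})
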