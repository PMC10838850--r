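#' One extracted maxillary-sinus instance
#'
#' A `sinus_instance` is one candidate view of a sinus: a cubic patch of side
#' `P` cropped around a sampled centroid, mirrored to left-sinus orientation
#' if it came from the right side, and trilinearly resampled to the fixed
#' 64 x 64 x 64 classifier input. Right-side instances are stored post-flip.
#'
#' @param data numeric 64 x 64 x 64 array (post-flip, post-resample).
#' @param centroid numeric length-3 continuous centroid (0-based voxels).
#' @param patch_size side length `P` of the crop before resampling.
#' @param side `"left"` or `"right"`.
#' @param patient_id character scalar.
#' @param instance_index position `i` in the sampling order, `1..N`.
#' @return An object of class `sinus_instance`.
#' @export
sinus_instance <- function(data, centroid, patch_size, side, patient_id,
                           instance_index) {
  if (!is.array(data) || !identical(dim(data), c(64L, 64L, 64L)))
    stop("instance data must be a 64x64x64 array", call. = FALSE)
  if (any(!is.finite(data)))
    stop("instance data must be finite", call. = FALSE)
  structure(list(data = data, centroid = as.numeric(centroid),
                 patch_size = as.integer(patch_size), side = check_side(side),
                 patient_id = as.character(patient_id),
                 instance_index = as.integer(instance_index)),
            class = "sinus_instance")
}

#' Crop a cubic patch around a centroid, zero-padding outside the volume
#'
#' The continuous centroid is rounded half-up to the voxel grid; the patch
#' covers 0-based indices `c - floor(P/2)` to `c - floor(P/2) + P - 1` on each
#' axis. Voxels falling outside the volume are zero — zero-padding rather than
#' clamping preserves the geometry of sinuses near the volume border.
#'
#' @param volume a [volume_image()] or 3D array.
#' @param centroid numeric length-3, continuous 0-based voxel coordinates.
#' @param patch_size side length `P >= 1` in voxels.
#' @return `P x P x P` numeric array.
#' @examples
#' v <- array(0, c(9, 9, 9)); v[5, 5, 5] <- 1
#' p <- extract_patch(v, c(4, 4, 4), 5)   # marker lands at the patch center
#' which(p == 1)
#' @export
extract_patch <- function(volume, centroid, patch_size) {
  arr <- if (inherits(volume, "volume_image")) volume$data else volume
  if (!is.array(arr) || length(dim(arr)) != 3L)
    stop("'volume' must be a 3D array or volume_image", call. = FALSE)
  if (!is.numeric(centroid) || length(centroid) != 3L || any(!is.finite(centroid)))
    stop("'centroid' must be a finite numeric triple", call. = FALSE)
  P <- as.integer(patch_size)
  if (P < 1L) stop("'patch_size' must be >= 1", call. = FALSE)
  dims <- dim(arr)
  c0 <- round_half_up(centroid)                    # 0-based voxel center
  start <- c0 - floor(P / 2)                       # 0-based first index
  if (any(start + P - 1 < 0) || any(start > dims - 1))
    stop(sprintf(
      "localization failure: patch at centroid (%s) lies fully outside the %s volume",
      paste(format(centroid, digits = 4), collapse = ", "),
      paste(dims, collapse = "x")), call. = FALSE)
  out <- array(0, c(P, P, P))
  # overlap of [start, start+P-1] with [0, dims-1] per axis (0-based)
  lo_src <- pmax(start, 0); hi_src <- pmin(start + P - 1, dims - 1)
  lo_dst <- lo_src - start; hi_dst <- hi_src - start
  out[(lo_dst[1] + 1):(hi_dst[1] + 1),
      (lo_dst[2] + 1):(hi_dst[2] + 1),
      (lo_dst[3] + 1):(hi_dst[3] + 1)] <-
    arr[(lo_src[1] + 1):(hi_src[1] + 1),
        (lo_src[2] + 1):(hi_src[2] + 1),
        (lo_src[3] + 1):(hi_src[3] + 1)]
  out
}

#' Mirror a patch along the left-right axis
#'
#' Right-sinus patches are flipped along x so both sinuses present the same
#' (left-sinus) appearance to the classifier; the flip is applied to the raw
#' crop before resampling, where it is exact. The operation is an involution.
#'
#' @param cube 3D numeric array.
#' @return Array of the same shape, mirrored along the first axis.
#' @export
flip_right_sinus <- function(cube) {
  if (!is.array(cube) || length(dim(cube)) != 3L)
    stop("'cube' must be a 3D array", call. = FALSE)
  cube[dim(cube)[1]:1, , , drop = FALSE]
}

#' Trilinearly resample a cubic patch to the classifier input grid
#'
#' The output grid spans the same extent as the input (corner-aligned): output
#' sample `i` of `n` maps to input coordinate `(i-1) * (P-1) / (n-1)`. With
#' `P = n` this is the identity; constants and linear ramps are reproduced
#' exactly (up to floating point), and every output value is a convex
#' combination of input values, so the output range never exceeds the input
#' range.
#'
#' @param cube `P x P x P` numeric array with `P >= 2`.
#' @param out_size output side length, default 64.
#' @return `out_size^3` numeric array.
#' @export
resample_to_input <- function(cube, out_size = 64L) {
  if (!is.array(cube) || length(dim(cube)) != 3L)
    stop("'cube' must be a 3D array", call. = FALSE)
  d <- dim(cube)
  if (!all(d == d[1])) stop("'cube' must be cubic", call. = FALSE)
  P <- d[1]
  if (P < 2L) stop("resampling undefined for patches smaller than 2 voxels", call. = FALSE)
  n <- as.integer(out_size)
  src <- (seq_len(n) - 1) * (P - 1) / (n - 1)      # 0-based source coords
  i0 <- pmin(floor(src), P - 2)                    # lower corner, 0-based
  f <- src - i0
  a <- as.integer(i0) + 1L                         # 1-based lower index
  w0 <- 1 - f; w1 <- f
  out <- array(0, c(n, n, n))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 0) w0 else w1
    wy <- if (dy == 0) w0 else w1
    wz <- if (dz == 0) w0 else w1
    w <- outer(outer(wx, wy), wz)
    out <- out + w * cube[a + dx, a + dy, a + dz]
  }
  out
}

#' Extract all 2N instance volumes of one scan
#'
#' Runs the full localization front-end for one registered volume: for each
#' side, `N` centroids are placed according to `scheme`, a `P^3` patch is
#' cropped around each (zero-padded at borders), right-side patches are
#' mirrored to left-sinus orientation, and every patch is resampled to
#' 64 x 64 x 64. In gaussian mode the left and right draws use independent
#' substreams derived from `scheme$seed`.
#'
#' @param volume a [volume_image()].
#' @param model a [centroid_model()] in the volume's registered frame.
#' @param scheme a [sampling_scheme()].
#' @param patch_size crop side `P`; the study grid searched 25, 30, 35, 40, 45
#'   and found 35 optimal at full resolution.
#' @return List of `2 * scheme$n` [sinus_instance()] objects (left block
#'   first, sampling order preserved).
#' @export
extract_instances <- function(volume, model, scheme, patch_size) {
  stopifnot(inherits(volume, "volume_image"), inherits(model, "centroid_model"),
            inherits(scheme, "sampling_scheme"))
  out <- vector("list", 2L * scheme$n)
  k <- 0L
  for (side in c("left", "right")) {
    sch <- scheme
    if (sch$mode == "gaussian" && !is.null(sch$seed))
      sch$seed <- derive_seed(sch$seed, if (side == "left") 1L else 2L)
    cents <- sample_centroids(model, side, sch)
    for (i in seq_len(scheme$n)) {
      patch <- extract_patch(volume, cents[i, ], patch_size)
      if (side == "right") patch <- flip_right_sinus(patch)
      k <- k + 1L
      out[[k]] <- sinus_instance(resample_to_input(patch), cents[i, ],
                                 patch_size, side, volume$patient_id, i)
    }
  }
  out
}
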