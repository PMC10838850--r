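#' Specification of a synthetic sinus-phantom cohort
#'
#' The phantom generator produces head-like scalar volumes that statistically
#' emulate a registered FLAIR cohort for pipeline development: mid-intensity
#' soft-tissue background, two dark (air-filled) ellipsoidal sinus cavities
#' whose centers follow the side-specific centroid Gaussians, and — in
#' anomalous sinuses — a bright mass attached to the cavity wall, mimicking
#' the fluid/mass hyperintensity of polyps and cysts on FLAIR. Additive
#' Gaussian noise is applied voxelwise. Each sinus is anomalous independently
#' with probability `anomaly_prevalence_sinus` (0.32 by default, the
#' prevalence observed in the study cohort of 299 patients).
#'
#' `scale` downsizes everything consistently (grid, centroid model, radii) so
#' the full pipeline can run on reduced geometry; `scale = 1` reproduces the
#' reference 173 x 319 x 319 grid.
#'
#' @param n_patients number of phantoms to generate.
#' @param anomaly_prevalence_sinus per-sinus anomaly probability in `[0, 1]`.
#' @param scale geometric scale factor in `(0, 1]`.
#' @param centroid_model a [centroid_model()]; default is the reference model
#'   rescaled by `scale`.
#' @param volume_shape integer triple; default reference shape times `scale`.
#' @param voxel_size_mm physical voxel size; default reference spacing
#'   divided by `scale` (the field of view is preserved).
#' @param cavity_radius_range range of ellipsoid semi-axes (voxels, at scale 1
#'   the default is 10-15; scaled automatically).
#' @param anomaly_radius_range range of anomaly blob radii (voxels at scale 1,
#'   default 4-8; scaled automatically).
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param intensities named list with `background`, `cavity`, `anomaly`
#'   intensity levels; anomaly must exceed cavity so the classes are
#'   separable in principle.
#' @param seed integer; the cohort is fully reproducible from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_patients,
                         anomaly_prevalence_sinus = 0.32,
                         scale = 1,
                         centroid_model = NULL,
                         volume_shape = NULL,
                         voxel_size_mm = NULL,
                         cavity_radius_range = c(10, 15) * scale,
                         anomaly_radius_range = c(4, 8) * scale,
                         noise_sd = 0.05,
                         intensities = list(background = 0.5, cavity = 0.1,
                                            anomaly = 0.9),
                         seed = 1L) {
  stopifnot_scalar_number(n_patients, "n_patients", positive = TRUE)
  stopifnot_scalar_number(scale, "scale", positive = TRUE)
  if (anomaly_prevalence_sinus < 0 || anomaly_prevalence_sinus > 1)
    stop("'anomaly_prevalence_sinus' must be in [0, 1]", call. = FALSE)
  if (is.null(centroid_model))
    centroid_model <- scale_centroid_model(sinusmie::centroid_model(), scale)
  if (is.null(volume_shape))
    volume_shape <- as.integer(round(c(173L, 319L, 319L) * scale))
  if (is.null(voxel_size_mm))
    voxel_size_mm <- c(0.53, 0.75, 0.75) / scale
  if (any(volume_shape < 1)) stop("'volume_shape' must be positive", call. = FALSE)
  if (any(cavity_radius_range <= 0) || diff(cavity_radius_range) < 0 ||
      any(anomaly_radius_range <= 0) || diff(anomaly_radius_range) < 0)
    stop("radius ranges must be positive and increasing", call. = FALSE)
  if (2 * max(cavity_radius_range) >= min(volume_shape))
    stop("impossible geometry: cavity larger than the volume", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (intensities$anomaly <= intensities$cavity)
    stop("anomaly intensity must exceed cavity intensity", call. = FALSE)
  structure(list(
    n_patients = as.integer(n_patients),
    anomaly_prevalence_sinus = anomaly_prevalence_sinus,
    scale = scale, centroid_model = centroid_model,
    volume_shape = as.integer(volume_shape),
    voxel_size_mm = as.numeric(voxel_size_mm),
    cavity_radius_range = as.numeric(cavity_radius_range),
    anomaly_radius_range = as.numeric(anomaly_radius_range),
    noise_sd = noise_sd, intensities = intensities,
    seed = as.integer(seed)), class = "phantom_spec")
}

# Geometry of one sinus: cavity ellipsoid plus (optionally) the anomaly,
# represented as a set of spheres clipped to the cavity so that rendering is a
# pure function of the truth record.
place_one_sinus <- function(spec, side) {
  p <- spec$centroid_model[[side]]
  dims <- spec$volume_shape
  for (try in 1:100) {
    centroid <- stats::rnorm(3, p$mu, p$sigma)
    radii <- stats::runif(3, spec$cavity_radius_range[1], spec$cavity_radius_range[2])
    if (all(centroid - radii >= 0) && all(centroid + radii <= dims - 1)) break
    if (try == 100)
      stop("could not place a cavity inside the volume after 100 attempts",
           call. = FALSE)
  }
  label <- stats::rbinom(1, 1, spec$anomaly_prevalence_sinus)
  anomaly <- NULL
  if (label == 1L) {
    r_anom <- stats::runif(1, spec$anomaly_radius_range[1], spec$anomaly_radius_range[2])
    r_anom <- min(r_anom, 0.9 * min(radii))
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    # distance to the cavity wall along u, then pull the blob center inwards
    # so it sits attached to the wall but inside the cavity
    t_wall <- 1 / sqrt(sum((u / radii)^2))
    center <- centroid + u * (t_wall - 0.8 * r_anom)
    shape <- sample(c("dome", "lobulated"), 1)
    spheres <- list(list(center = center, radius = r_anom))
    if (shape == "lobulated") {
      n_lobes <- sample(2:4, 1)
      for (l in seq_len(n_lobes)) {
        off <- stats::rnorm(3, 0, 0.45 * r_anom)
        spheres[[l + 1L]] <- list(center = center + off,
                                  radius = stats::runif(1, 0.4, 0.8) * r_anom)
      }
    }
    anomaly <- list(center = center, radius = r_anom, shape = shape,
                    spheres = spheres)
  }
  list(centroid = centroid, radii = radii, label = as.integer(label),
       anomaly = anomaly)
}

#' Generate the ground-truth geometry of a phantom cohort
#'
#' Places cavities and anomalies for `n_patients` phantoms without rendering
#' any voxel data. This is the exact geometry the renderer consumes, so
#' population statistics of the truths (label prevalence, centroid law) are
#' those of the rendered cohort; it is also the fast path for statistical
#' checks at large `n`.
#'
#' @param spec a [phantom_spec()].
#' @return List of `phantom_truth` records, one per patient, each with
#'   `patient_id` and per-side geometry (`centroid`, `radii`, `label`,
#'   `anomaly`).
#' @export
generate_phantom_truths <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_patients), function(i) {
      structure(list(
        patient_id = sprintf("phantom%04d", i),
        left = place_one_sinus(spec, "left"),
        right = place_one_sinus(spec, "right")), class = "phantom_truth")
    })
  })
}

# ellipsoid / sphere rasterization confined to a bounding box
fill_region <- function(arr, center, radii, value, mask_ellipsoid = NULL) {
  dims <- dim(arr)
  lo <- pmax(floor(center - radii), 0); hi <- pmin(ceiling(center + radii), dims - 1)
  if (any(lo > hi)) return(arr)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- ((xs - center[1]) / radii[1])^2
  dy2 <- ((ys - center[2]) / radii[2])^2
  dz2 <- ((zs - center[3]) / radii[3])^2
  inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
  if (!is.null(mask_ellipsoid)) {
    mx2 <- ((xs - mask_ellipsoid$center[1]) / mask_ellipsoid$radii[1])^2
    my2 <- ((ys - mask_ellipsoid$center[2]) / mask_ellipsoid$radii[2])^2
    mz2 <- ((zs - mask_ellipsoid$center[3]) / mask_ellipsoid$radii[3])^2
    inside <- inside & (outer(outer(mx2, my2, "+"), mz2, "+") <= 1)
  }
  sub <- arr[xs + 1, ys + 1, zs + 1, drop = FALSE]
  sub[inside] <- value
  arr[xs + 1, ys + 1, zs + 1] <- sub
  arr
}

#' Render one phantom volume from its truth record
#'
#' Pure function of (`truth`, `spec`): soft-tissue background, carved dark
#' cavities, bright anomaly spheres clipped to their cavity, then additive
#' Gaussian noise drawn from a per-patient substream of `spec$seed` — so
#' rendering patients one at a time (streaming) or all at once gives
#' voxelwise-identical results.
#'
#' @param truth one element of [generate_phantom_truths()].
#' @param spec the [phantom_spec()] that produced it.
#' @param patient_index 1-based index of the patient in the cohort (drives the
#'   noise substream).
#' @return A [volume_image()].
#' @export
render_phantom_volume <- function(truth, spec, patient_index) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(spec, "phantom_spec"))
  arr <- array(spec$intensities$background, spec$volume_shape)
  for (side in c("left", "right")) {
    s <- truth[[side]]
    arr <- fill_region(arr, s$centroid, s$radii, spec$intensities$cavity)
    if (!is.null(s$anomaly)) {
      cav <- list(center = s$centroid, radii = s$radii)
      for (sp in s$anomaly$spheres)
        arr <- fill_region(arr, sp$center, rep(sp$radius, 3),
                           spec$intensities$anomaly, mask_ellipsoid = cav)
    }
  }
  if (spec$noise_sd > 0) {
    arr <- with_seed(derive_seed(spec$seed, 100000L + patient_index),
                     arr + stats::rnorm(length(arr), 0, spec$noise_sd))
  }
  volume_image(arr, spec$voxel_size_mm, truth$patient_id)
}

#' Generate a synthetic phantom cohort
#'
#' Convenience wrapper returning both truths and rendered volumes. For large
#' cohorts prefer [generate_phantom_truths()] plus streaming
#' [render_phantom_volume()] calls so only one volume is in memory at a time.
#'
#' @param spec a [phantom_spec()].
#' @param render if `FALSE`, `volumes` is `NULL` (geometry only).
#' @return List with `volumes` (list of [volume_image()]) and `truths`.
#' @examples
#' cohort <- generate_phantom_cohort(phantom_spec(2, scale = 0.25, seed = 7))
#' cohort$volumes[[1]]
#' @export
generate_phantom_cohort <- function(spec, render = TRUE) {
  truths <- generate_phantom_truths(spec)
  volumes <- NULL
  if (render)
    volumes <- lapply(seq_along(truths), function(i)
      render_phantom_volume(truths[[i]], spec, i))
  list(volumes = volumes, truths = truths)
}

#' Per-axis mean and standard deviation of true sinus centroids
#'
#' Sample statistics (n-1 convention for the sd) of the realized centroids of
#' one side across a cohort — used to verify that generated cohorts follow
#' the configured centroid law.
#'
#' @param truths list of truth records from [generate_phantom_truths()].
#' @param side `"left"` or `"right"`.
#' @return List with numeric triples `mean` and `sd`.
#' @export
empirical_centroid_stats <- function(truths, side) {
  side <- check_side(side)
  if (length(truths) < 2L)
    stop("need at least two truth records", call. = FALSE)
  m <- t(vapply(truths, function(tr) tr[[side]]$centroid, numeric(3)))
  list(mean = colMeans(m), sd = apply(m, 2, stats::sd))
}

#' Truth table of a phantom cohort
#'
#' Flattens truth records to one row per sinus: `patient_id`, `side`,
#' `label` (1 = anomalous), and the true centroid `cx`, `cy`, `cz`.
#' This is the label schema consumed by [make_folds()] and
#' [build_labeled_instances()]; user-supplied cohorts provide the same table.
#'
#' @param truths list of truth records.
#' @return A data frame with one row per sinus.
#' @export
truth_table <- function(truths) {
  rows <- lapply(truths, function(tr) {
    do.call(rbind, lapply(c("left", "right"), function(side) {
      s <- tr[[side]]
      data.frame(patient_id = tr$patient_id, side = side, label = s$label,
                 cx = s$centroid[1], cy = s$centroid[2], cz = s$centroid[3],
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Write a phantom cohort to disk
#'
#' Writes each volume as compressed NIfTI (`<patient_id>.nii.gz`) plus a
#' tab-delimited `truth.tsv` with the [truth_table()] schema.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the truth table.
#' @export
write_phantom_cohort <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truths <- generate_phantom_truths(spec)
  for (i in seq_along(truths)) {
    vol <- render_phantom_volume(truths[[i]], spec, i)
    write_volume(vol, file.path(out_dir, paste0(vol$patient_id, ".nii.gz")))
  }
  tab <- truth_table(truths)
  utils::write.table(tab, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(tab)
}
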