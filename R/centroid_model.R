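#' Per-side Gaussian centroid model of the maxillary sinuses
#'
#' The localization step of the pipeline does not learn anything: in a cohort
#' registered to a common reference scan, the centroid of each maxillary sinus
#' (MS) occupies a tight, side-specific range of voxel coordinates. A
#' `centroid_model` holds, for each side, the per-axis mean `mu` and standard
#' deviation `sigma` (in voxels of the reference grid) of the MS centroid, i.e.
#' six independent Gaussians in total. Candidate patch centers are then drawn
#' from these distributions (see [sample_gaussian_centroids()]) or placed
#' deterministically along the `mu - sigma` to `mu + sigma` segment
#' (see [equidistant_centroids()]).
#'
#' The default parameters are centroid statistics measured on 20 manually
#' annotated scans in the reference geometry of 173 x 319 x 319 voxels
#' (axis 1 = left-right x, axis 2 = y, axis 3 = z, 0-based coordinates):
#' left `mu = (75, 231, 121)`, `sigma = (1.47, 1.56, 1.76)`; right
#' `mu = (149, 232, 118)`, `sigma = (1.90, 1.66, 6.47)`.
#'
#' @param left_mu,right_mu numeric length-3: per-axis centroid means (voxels).
#' @param left_sigma,right_sigma numeric length-3: per-axis centroid standard
#'   deviations (voxels), all strictly positive.
#' @param reference_shape integer length-3 voxel grid the coordinates refer to.
#' @return An object of class `centroid_model`.
#' @examples
#' m <- centroid_model()
#' m$left$mu
#' @export
centroid_model <- function(left_mu = c(75, 231, 121),
                           left_sigma = c(1.47, 1.56, 1.76),
                           right_mu = c(149, 232, 118),
                           right_sigma = c(1.90, 1.66, 6.47),
                           reference_shape = c(173L, 319L, 319L)) {
  for (v in list(left_mu, left_sigma, right_mu, right_sigma)) {
    if (!is.numeric(v) || length(v) != 3L || any(!is.finite(v)))
      stop("centroid model parameters must be finite numeric triples", call. = FALSE)
  }
  if (any(left_sigma <= 0) || any(right_sigma <= 0))
    stop("all sigma must be > 0", call. = FALSE)
  if (any(left_mu < 0) || any(left_mu >= reference_shape) ||
      any(right_mu < 0) || any(right_mu >= reference_shape))
    stop("mu must lie within the reference volume bounds", call. = FALSE)
  structure(list(
    left  = list(mu = as.numeric(left_mu),  sigma = as.numeric(left_sigma)),
    right = list(mu = as.numeric(right_mu), sigma = as.numeric(right_sigma)),
    reference_shape = as.integer(reference_shape)
  ), class = "centroid_model")
}

#' Rescale a centroid model to a downscaled reference grid
#'
#' Multiplies every `mu`, `sigma` and the reference shape by `factor`. Used by
#' the phantom generator to run the full pipeline on reduced grids (e.g.
#' `factor = 0.5` maps the reference geometry to 86 x 160 x 160).
#'
#' @param model a [centroid_model()].
#' @param factor positive scale factor.
#' @return A rescaled `centroid_model`.
#' @export
scale_centroid_model <- function(model, factor) {
  stopifnot(inherits(model, "centroid_model"))
  stopifnot_scalar_number(factor, "factor", positive = TRUE)
  centroid_model(
    left_mu = model$left$mu * factor,
    left_sigma = model$left$sigma * factor,
    right_mu = model$right$mu * factor,
    right_sigma = model$right$sigma * factor,
    reference_shape = as.integer(round(model$reference_shape * factor))
  )
}

#' @export
print.centroid_model <- function(x, ...) {
  cat("Maxillary-sinus centroid model (voxel coordinates,",
      paste(x$reference_shape, collapse = "x"), "grid)\n")
  for (s in c("left", "right")) {
    cat(sprintf("  %-5s mu = (%s)  sigma = (%s)\n", s,
                paste(format(x[[s]]$mu, digits = 4), collapse = ", "),
                paste(format(x[[s]]$sigma, digits = 4), collapse = ", ")))
  }
  invisible(x)
}

#' Read / write a centroid model as a YAML-like key file
#'
#' Plain-text serialization with one `side_axis: mu sigma` entry per line so a
#' site can supply its own measured centroid statistics to the CLI.
#'
#' @param model a [centroid_model()].
#' @param path file path.
#' @return `read_centroid_model` returns a `centroid_model`;
#'   `write_centroid_model` returns `path` invisibly.
#' @export
write_centroid_model <- function(model, path) {
  stopifnot(inherits(model, "centroid_model"))
  lines <- c(
    sprintf("reference_shape: %s", paste(model$reference_shape, collapse = " ")),
    sprintf("left_mu: %s", paste(model$left$mu, collapse = " ")),
    sprintf("left_sigma: %s", paste(model$left$sigma, collapse = " ")),
    sprintf("right_mu: %s", paste(model$right$mu, collapse = " ")),
    sprintf("right_sigma: %s", paste(model$right$sigma, collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_centroid_model
#' @export
read_centroid_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ":", fixed = TRUE)
  vals <- stats::setNames(
    lapply(kv, function(p) as.numeric(strsplit(trimws(p[2]), "\\s+")[[1]])),
    vapply(kv, function(p) trimws(p[1]), ""))
  centroid_model(left_mu = vals$left_mu, left_sigma = vals$left_sigma,
                 right_mu = vals$right_mu, right_sigma = vals$right_sigma,
                 reference_shape = vals$reference_shape)
}
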