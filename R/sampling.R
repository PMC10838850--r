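#' Centroid sampling scheme
#'
#' Describes how the `N` candidate centroids of one sinus are placed.
#' `mode = "gaussian"` draws every axis independently from the side-specific
#' normal distribution of the [centroid_model()]. `mode = "equidistant"`
#' places centroids deterministically: each axis flagged in `axes_vary` takes
#' the `N` evenly spaced values from `mu - sigma` to `mu + sigma`, while the
#' remaining axes are held at `mu`; the i-th centroid combines the i-th value
#' of every varying axis, so the centroids lie on a line segment in 3D.
#'
#' @param mode `"gaussian"` or `"equidistant"`.
#' @param n sample size `N >= 1`; typical study values are 1, 5, 10, 15, 20.
#' @param axes_vary logical length-3 (x, y, z); only used in equidistant mode.
#' @param seed integer seed for gaussian draws (ignored in equidistant mode).
#' @return An object of class `sampling_scheme`.
#' @examples
#' sampling_scheme("gaussian", n = 15, seed = 1)
#' sampling_scheme("equidistant", n = 5, axes_vary = c(FALSE, TRUE, TRUE))
#' @export
sampling_scheme <- function(mode = c("gaussian", "equidistant"), n = 15L,
                            axes_vary = c(TRUE, TRUE, TRUE), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != as.integer(n))
    stop("'n' must be a positive integer", call. = FALSE)
  if (!is.logical(axes_vary) || length(axes_vary) != 3L || any(is.na(axes_vary)))
    stop("'axes_vary' must be a logical triple", call. = FALSE)
  structure(list(mode = mode, n = as.integer(n),
                 axes_vary = axes_vary, seed = seed),
            class = "sampling_scheme")
}

#' Draw Gaussian centroid candidates for one sinus
#'
#' Each of the `scheme$n` centroids has its x, y, z coordinates drawn
#' independently from `N(mu_axis, sigma_axis^2)` of the requested side.
#' Coordinates are continuous (0-based voxel units); rounding to the voxel
#' grid is deferred to [extract_patch()].
#'
#' @param model a [centroid_model()].
#' @param side `"left"` or `"right"`.
#' @param scheme a [sampling_scheme()] with `mode = "gaussian"`.
#' @return Numeric matrix `n x 3` of centroid coordinates.
#' @examples
#' sample_gaussian_centroids(centroid_model(), "left",
#'                           sampling_scheme("gaussian", n = 5, seed = 7))
#' @export
sample_gaussian_centroids <- function(model, side, scheme) {
  stopifnot(inherits(model, "centroid_model"), inherits(scheme, "sampling_scheme"))
  side <- check_side(side)
  if (scheme$mode != "gaussian")
    stop("scheme mode must be \"gaussian\"", call. = FALSE)
  p <- model[[side]]
  with_seed(scheme$seed, {
    out <- matrix(0, scheme$n, 3L)
    for (a in 1:3) out[, a] <- stats::rnorm(scheme$n, p$mu[a], p$sigma[a])
    colnames(out) <- c("x", "y", "z")
    out
  })
}

#' Place equidistant centroid candidates for one sinus
#'
#' For every axis flagged in `scheme$axes_vary`, the i-th coordinate is
#' `mu - sigma + 2 * sigma * (i - 1) / (N - 1)` for `i = 1..N` (a single
#' centroid at `mu` when `N = 1`); fixed axes take `mu`. Deterministic.
#'
#' @inheritParams sample_gaussian_centroids
#' @param scheme a [sampling_scheme()] with `mode = "equidistant"`.
#' @return Numeric matrix `n x 3` of centroid coordinates.
#' @examples
#' equidistant_centroids(centroid_model(), "left",
#'                       sampling_scheme("equidistant", n = 3))
#' @export
equidistant_centroids <- function(model, side, scheme) {
  stopifnot(inherits(model, "centroid_model"), inherits(scheme, "sampling_scheme"))
  side <- check_side(side)
  if (scheme$mode != "equidistant")
    stop("scheme mode must be \"equidistant\"", call. = FALSE)
  p <- model[[side]]
  n <- scheme$n
  out <- matrix(rep(p$mu, each = n), n, 3L)
  if (n > 1L) {
    steps <- 2 * (seq_len(n) - 1) / (n - 1)   # 0 .. 2
    for (a in 1:3) if (scheme$axes_vary[a])
      out[, a] <- p$mu[a] - p$sigma[a] + p$sigma[a] * steps
  }
  colnames(out) <- c("x", "y", "z")
  out
}

# dispatch helper used by extract_instances and the strategy comparison
sample_centroids <- function(model, side, scheme) {
  if (scheme$mode == "gaussian") sample_gaussian_centroids(model, side, scheme)
  else equidistant_centroids(model, side, scheme)
}

#' The seven equidistant sampling variants plus Gaussian sampling
#'
#' Convenience constructor for the sampling-strategy ablation: all seven
#' non-trivial combinations of varying/fixed axes under equidistant placement
#' (x fixed; y fixed; z fixed; x,y fixed; x,z fixed; y,z fixed; none fixed)
#' followed by full Gaussian sampling. Row names encode the variant.
#'
#' @param n sample size per sinus.
#' @param seed seed applied to the Gaussian strategy.
#' @return Named list of [sampling_scheme()] objects of length 8.
#' @export
standard_sampling_strategies <- function(n = 15L, seed = NULL) {
  combos <- list(
    "x@mu"      = c(FALSE, TRUE,  TRUE),
    "y@mu"      = c(TRUE,  FALSE, TRUE),
    "z@mu"      = c(TRUE,  TRUE,  FALSE),
    "xy@mu"     = c(FALSE, FALSE, TRUE),
    "xz@mu"     = c(FALSE, TRUE,  FALSE),
    "yz@mu"     = c(TRUE,  FALSE, FALSE),
    "xyz-vary"  = c(TRUE,  TRUE,  TRUE))
  out <- lapply(combos, function(v) sampling_scheme("equidistant", n, v))
  out$gaussian <- sampling_scheme("gaussian", n, seed = seed)
  out
}
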