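#' 3D scalar volume with provenance
#'
#' Light container for one registered head-and-neck scan: a 3D numeric array
#' (axis 1 = left-right x, axis 2 = y, axis 3 = z), the voxel size in mm and a
#' patient identifier. All volumes entering the pipeline are assumed to be
#' rigidly registered to a common reference scan so that a single
#' [centroid_model()] applies to the whole cohort; registration itself happens
#' upstream (e.g. with any rigid-registration tool) and is not re-done here.
#'
#' @param data 3D numeric array of voxel intensities.
#' @param voxel_size_mm numeric length-3 voxel spacing, default reference
#'   spacing `c(0.53, 0.75, 0.75)`.
#' @param patient_id character scalar.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, voxel_size_mm = c(0.53, 0.75, 0.75),
                         patient_id = NA_character_) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array", call. = FALSE)
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 3L ||
      any(voxel_size_mm <= 0))
    stop("'voxel_size_mm' must be a positive numeric triple", call. = FALSE)
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 patient_id = as.character(patient_id)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("volume_image %s: %s voxels @ %s mm, intensity [%.3g, %.3g]\n",
              x$patient_id, paste(dim(x$data), collapse = "x"),
              paste(format(x$voxel_size_mm, digits = 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Read / write a volume as NIfTI
#'
#' Thin wrappers over \pkg{RNifti}. `write_volume` stores the voxel size in
#' the NIfTI header; `read_volume` recovers it (and takes the patient id from
#' the file name unless given).
#'
#' @param vol a [volume_image()].
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param patient_id optional id override on read.
#' @return `read_volume` returns a `volume_image`; `write_volume` returns
#'   `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, patient_id = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  volume_image(array(as.numeric(img), dim = dim(img)),
               voxel_size_mm = RNifti::pixdim(img)[1:3],
               patient_id = patient_id)
}
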