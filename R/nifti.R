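# NIfTI I/O via RNifti. The on-disk axis order is x = column, y = row,
# z = slice; in memory everything uses the canonical slice-row-column order.

.to_xyz   <- function(arr) aperm(arr, c(3, 2, 1))
.from_xyz <- function(arr) aperm(arr, c(3, 2, 1))

#' Read a NIfTI volume as a calibrated CT volume
#'
#' @param path a `.nii` or `.nii.gz` file holding a 3-D image whose voxel
#'   values are Hounsfield units.
#' @param patient_id identifier attached to the returned volume.
#' @return A [ct_volume] in canonical slice-row-column order, spacing taken
#'   from the image's pixel dimensions (mm).
#' @export
read_nifti <- function(path, patient_id = "anonymous") {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3-D image, got ", length(dim(img)), "-D")
  sp <- RNifti::pixdim(img)
  ct_volume(.from_xyz(as.array(img)), sp[c(3, 2, 1)],
            patient_id = patient_id)
}

#' Write a CT volume to NIfTI
#'
#' @param volume a [ct_volume].
#' @param path output `.nii` or `.nii.gz` file.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- RNifti::asNifti(.to_xyz(volume$voxels))
  RNifti::pixdim(img) <- volume$spacing_mm[c(3, 2, 1)]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a voxel mask to NIfTI
#'
#' Stores the mask as 0/1 values with the reference volume's geometry.
#'
#' @param mask a [voxel_mask].
#' @param ref the [ct_volume] the mask annotates (geometry source).
#' @param path output `.nii` or `.nii.gz` file.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, ref, path) {
  stopifnot(inherits(mask, "voxel_mask"), inherits(ref, "ct_volume"))
  check_aligned(mask, ref)
  arr <- array(as.integer(mask$flags), dim(mask$flags))
  img <- RNifti::asNifti(.to_xyz(arr))
  RNifti::pixdim(img) <- ref$spacing_mm[c(3, 2, 1)]
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a voxel mask from NIfTI
#'
#' @param path a 3-D NIfTI file with values in \{0, 1\}.
#' @param label label for the returned mask.
#' @return A [voxel_mask].
#' @export
read_mask <- function(path, label = "mask") {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3-D mask, got ", length(dim(img)), "-D")
  arr <- as.array(img)
  if (!all(arr %in% c(0, 1))) stop("mask file contains values outside {0,1}")
  voxel_mask(.from_xyz(arr) == 1, label = label)
}
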