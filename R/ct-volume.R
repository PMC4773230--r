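#' CT volume container
#'
#' A calibrated CT volume: a 3-D grid of Hounsfield units (HU) with physical
#' voxel spacing. The canonical dimension order is slice-row-column, with the
#' slice index increasing toward the head; every function in this package
#' assumes that order. HU values are clamped to the 12-bit CT range
#' \eqn{[-1024, 3071]} on construction, so padding or out-of-scan values below
#' \eqn{-1024} become exactly \eqn{-1024} (pure air) and cannot fall outside
#' a threshold unexpectedly.
#'
#' @param voxels numeric 3-D array of HU values, dimension order
#'   slice-row-column.
#' @param spacing_mm numeric length-3 vector of positive voxel spacings in mm
#'   (slice, row, column).
#' @param patient_id opaque identifier string.
#' @param meta optional named list of acquisition descriptors.
#' @return An object of class `ct_volume` with elements `voxels`,
#'   `spacing_mm`, `patient_id` and `meta`.
#' @examples
#' v <- ct_volume(array(-850, c(4, 8, 8)), c(1, 0.7, 0.7))
#' dim(v$voxels)
#' @export
ct_volume <- function(voxels, spacing_mm, patient_id = "anonymous",
                      meta = list()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3-D array (slice, row, column)")
  if (any(dim(voxels) < 1L)) stop("voxel grid must be non-empty")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("'spacing_mm' must be three positive values")
  storage.mode(voxels) <- "double"
  voxels[voxels < .hu_min] <- .hu_min
  voxels[voxels > .hu_max] <- .hu_max
  structure(
    list(voxels = voxels, spacing_mm = spacing_mm,
         patient_id = as.character(patient_id), meta = meta),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels (slice x row x col), spacing %s mm, patient '%s'\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing_mm, 4), collapse = " x "),
              x$patient_id))
  cat(sprintf("  HU range [%g, %g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Voxel volume of a CT grid
#'
#' @param volume a [ct_volume].
#' @return Volume of a single voxel in mm^3.
#' @export
voxel_volume_mm3 <- function(volume) {
  stopifnot(inherits(volume, "ct_volume"))
  prod(volume$spacing_mm)
}

#' Boolean voxel mask aligned to a CT volume
#'
#' @param flags logical 3-D array, same dimension order as the volume it
#'   annotates.
#' @param label short description, e.g. `"lung"` or `"fibrotic"`.
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(flags, label = "mask") {
  if (!is.array(flags) || length(dim(flags)) != 3L)
    stop("'flags' must be a logical 3-D array")
  storage.mode(flags) <- "logical"
  flags[is.na(flags)] <- FALSE
  structure(list(flags = flags, label = as.character(label)),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$flags)
  cat(sprintf("<voxel_mask> '%s' %d x %d x %d, %d flagged voxels\n",
              x$label, d[1], d[2], d[3], sum(x$flags)))
  invisible(x)
}

# internal: stop unless mask dims match volume dims
check_aligned <- function(mask, volume) {
  if (!identical(dim(mask$flags), dim(volume$voxels)))
    stop("mask dimensions do not match the volume")
  invisible(TRUE)
}
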