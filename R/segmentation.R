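#' Lung segmentation parameters
#'
#' Controls the threshold segmentation that isolates lung parenchyma. The
#' lung attenuation window defaults to \eqn{[-1024, -200]} HU, both ends
#' inclusive; everything downstream (tissue histogram, fibrosis fraction)
#' uses the same window.
#'
#' @param lung_hu_low,lung_hu_high closed HU interval defining candidate
#'   lung voxels.
#' @param min_component_voxels connected components smaller than this are
#'   discarded. `NULL` (default) means the number of voxels in 1 cm^3 at the
#'   volume's spacing, which suppresses airway and vessel fragments.
#' @param opening_radius_mm radius of the spherical structuring element for
#'   morphological opening, in mm; 0 disables opening.
#' @param exclude_airways drop residual air-like components (mean HU below
#'   -950) whose in-plane centroid lies in the central third of the grid —
#'   a deterministic stand-in for the manual exclusion of large bronchi
#'   near the hilum.
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(lung_hu_low = -1024, lung_hu_high = -200,
                                min_component_voxels = NULL,
                                opening_radius_mm = 1,
                                exclude_airways = TRUE) {
  if (lung_hu_low >= lung_hu_high)
    stop("'lung_hu_low' must be below 'lung_hu_high'")
  if (opening_radius_mm < 0) stop("'opening_radius_mm' must be >= 0")
  if (!is.null(min_component_voxels) && min_component_voxels < 1)
    stop("'min_component_voxels' must be a positive integer")
  structure(list(lung_hu_low = lung_hu_low, lung_hu_high = lung_hu_high,
                 min_component_voxels = min_component_voxels,
                 opening_radius_mm = opening_radius_mm,
                 exclude_airways = isTRUE(exclude_airways)),
            class = "segmentation_params")
}

#' Threshold candidate lung voxels
#'
#' Flags exactly the voxels whose HU lies in the closed interval
#' \eqn{[}`lung_hu_low`, `lung_hu_high`\eqn{]}. An empty result is legal.
#'
#' @param volume a [ct_volume].
#' @param params a [segmentation_params].
#' @return A [voxel_mask] labelled `"lung_candidates"`.
#' @export
threshold_lung_candidates <- function(volume,
                                      params = segmentation_params()) {
  stopifnot(inherits(volume, "ct_volume"),
            inherits(params, "segmentation_params"))
  flags <- volume$voxels >= params$lung_hu_low &
           volume$voxels <= params$lung_hu_high
  voxel_mask(array(flags, dim(volume$voxels)), "lung_candidates")
}

# label 26-connected components (integer array, 0 = background)
label_components <- function(flags) {
  .cc_label26(as.logical(flags), as.integer(dim(flags)))
}

# voxel offsets of a ball of physical radius `radius_mm` at `spacing_mm`
.ball_offsets <- function(radius_mm, spacing_mm) {
  r <- pmax(0L, as.integer(floor(radius_mm / spacing_mm)))
  g <- expand.grid(di = -r[1]:r[1], dj = -r[2]:r[2], dk = -r[3]:r[3])
  keep <- (g$di * spacing_mm[1] / radius_mm)^2 +
          (g$dj * spacing_mm[2] / radius_mm)^2 +
          (g$dk * spacing_mm[3] / radius_mm)^2 <= 1 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

# morphological opening of a logical array by a ball (erode then dilate)
.binary_open <- function(flags, radius_mm, spacing_mm) {
  off <- .ball_offsets(radius_mm, spacing_mm)
  if (nrow(off) <= 1L) return(flags)
  dims <- as.integer(dim(flags))
  er <- .morph_binary(as.logical(flags), dims, off, FALSE)
  array(.morph_binary(er, dims, off, TRUE), dim(flags))
}

#' Refine a candidate lung mask
#'
#' Deterministic replacement for the manual clean-up of a threshold mask:
#' \enumerate{
#'   \item delete connected components touching the grid boundary
#'     (exterior air is always border-connected, the lungs are enclosed by
#'     the body envelope);
#'   \item delete components smaller than `min_component_voxels`;
#'   \item apply morphological opening with a ball of
#'     `opening_radius_mm` to cut thin bridges (vessels, junctions);
#'   \item optionally delete residual air-like central components
#'     (trachea/main bronchi surrogate, see [segmentation_params]).
#' }
#' The result is always a subset of the candidate mask. Components are
#' 26-connected.
#'
#' @param candidates [voxel_mask] from [threshold_lung_candidates].
#' @param volume the [ct_volume] the candidates were derived from.
#' @param params a [segmentation_params].
#' @return A [voxel_mask] labelled `"lung"`.
#' @export
refine_lung_mask <- function(candidates, volume,
                             params = segmentation_params()) {
  stopifnot(inherits(candidates, "voxel_mask"), inherits(volume, "ct_volume"))
  check_aligned(candidates, volume)
  flags <- candidates$flags
  d <- dim(flags)

  lab <- label_components(flags)
  nlab <- max(lab)
  if (nlab > 0) {
    border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                       lab[, , c(1, d[3])]))
    border <- border[border > 0]
    sizes <- tabulate(lab, nbins = nlab)
    min_vox <- params$min_component_voxels
    if (is.null(min_vox))
      min_vox <- max(1, round(1000 / voxel_volume_mm3(volume)))
    keep <- setdiff(which(sizes >= min_vox), border)
    flags <- array(lab %in% keep, d)
  } else {
    flags <- array(FALSE, d)
  }

  if (params$opening_radius_mm > 0 && any(flags))
    flags <- .binary_open(flags, params$opening_radius_mm,
                          volume$spacing_mm) & candidates$flags

  if (params$exclude_airways && any(flags)) {
    lab <- label_components(flags)
    nlab <- max(lab)
    if (nlab > 1) {           # never remove the only remaining component
      idx <- which(lab > 0)
      comp <- lab[idx]
      mhu <- vapply(split(volume$voxels[idx], comp), mean, numeric(1))
      rc <- arrayInd(idx, d)
      cen_r <- vapply(split(rc[, 2], comp), mean, numeric(1))
      cen_c <- vapply(split(rc[, 3], comp), mean, numeric(1))
      central <- cen_r > d[2] / 3 & cen_r < 2 * d[2] / 3 &
                 cen_c > d[3] / 3 & cen_c < 2 * d[3] / 3
      airlike <- which(mhu < -950 & central)
      if (length(airlike) > 0 && length(airlike) < nlab)
        flags <- array(flags & !(lab %in% as.integer(names(mhu)[airlike])), d)
    }
  }

  if (!any(flags)) stop("no lung found")
  voxel_mask(array(flags, d), "lung")
}

#' Segment the lungs of a CT volume
#'
#' Convenience wrapper: [threshold_lung_candidates] followed by
#' [refine_lung_mask].
#'
#' @inheritParams refine_lung_mask
#' @param volume a [ct_volume].
#' @return A [voxel_mask] labelled `"lung"`.
#' @export
segment_lungs <- function(volume, params = segmentation_params()) {
  refine_lung_mask(threshold_lung_candidates(volume, params), volume, params)
}

#' Dice overlap between two masks
#'
#' @param a,b [voxel_mask] objects with identical dimensions.
#' @return Dice coefficient \eqn{2|A \cap B| / (|A| + |B|)}.
#' @export
dice_overlap <- function(a, b) {
  stopifnot(inherits(a, "voxel_mask"), inherits(b, "voxel_mask"))
  if (!identical(dim(a$flags), dim(b$flags)))
    stop("mask dimensions differ")
  2 * sum(a$flags & b$flags) / (sum(a$flags) + sum(b$flags))
}
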