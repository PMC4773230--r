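# Synthetic chest-CT phantoms: two ellipsoidal lungs inside a soft-tissue
# body envelope surrounded by air, with known fibrotic content. What the
# threshold densitometry sees is the HU distribution, so the phantom models
# attenuation distributions and coarse spatial weighting, not anatomy.

#' Phantom specification
#'
#' Normal parenchyma is drawn from N(-850, 40) HU — the middle of the
#' conventional -800 to -900 HU normal-lung range — and fibrotic tissue
#' from N(-600, 50) HU, centred in the ILD band (-700, -500]. The body
#' envelope sits at soft-tissue density and the exterior at pure air, so
#' threshold segmentation faces realistic competing structures.
#'
#' @param grid_shape voxel grid dimensions (slice, row, column).
#' @param spacing_mm voxel spacing in mm.
#' @param lung_geometry list of two ellipsoids, each
#'   `list(centre = <mm triple>, radii = <mm triple>)` in slice/row/column
#'   physical coordinates; `NULL` places two lungs automatically.
#' @param body_hu,air_hu soft-tissue and exterior attenuation (HU).
#' @param normal_hu_mean,normal_hu_sd normal parenchyma HU distribution.
#' @param fibrotic_hu_mean,fibrotic_hu_sd fibrotic tissue HU distribution.
#' @param design_fibrotic_fraction probability in `[0, 1]` that a lung
#'   voxel is drawn fibrotic (spatially weighted per `pattern`).
#' @param pattern `"uniform"`, `"subpleural"` (weight grows toward the
#'   pleural surface) or `"basal"` (weight grows toward the lung base).
#' @param seed integer seed; generation is fully reproducible.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(48, 64, 64), spacing_mm = c(1, 1, 1),
                         lung_geometry = NULL, body_hu = 40, air_hu = -1000,
                         normal_hu_mean = -850, normal_hu_sd = 40,
                         fibrotic_hu_mean = -600, fibrotic_hu_sd = 50,
                         design_fibrotic_fraction = 0.13,
                         pattern = c("uniform", "subpleural", "basal"),
                         seed = 1L) {
  pattern <- match.arg(pattern)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 4))
    stop("'grid_shape' must be three dimensions of at least 4 voxels")
  if (design_fibrotic_fraction < 0 || design_fibrotic_fraction > 1)
    stop("'design_fibrotic_fraction' must lie in [0, 1]")
  ext <- grid_shape * spacing_mm   # physical extent per axis
  if (is.null(lung_geometry)) {
    radii <- c(0.38 * ext[1], 0.30 * ext[2], 0.16 * ext[3])
    lung_geometry <- list(
      list(centre = c(0.5 * ext[1], 0.5 * ext[2], 0.30 * ext[3]),
           radii = radii),
      list(centre = c(0.5 * ext[1], 0.5 * ext[2], 0.70 * ext[3]),
           radii = radii))
  }
  spec <- structure(
    list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
         lung_geometry = lung_geometry, body_hu = body_hu, air_hu = air_hu,
         normal_hu_mean = normal_hu_mean, normal_hu_sd = normal_hu_sd,
         fibrotic_hu_mean = fibrotic_hu_mean, fibrotic_hu_sd = fibrotic_hu_sd,
         design_fibrotic_fraction = design_fibrotic_fraction,
         pattern = pattern, seed = as.integer(seed)),
    class = "phantom_spec")
  for (e in lung_geometry) {
    lo <- e$centre - e$radii; hi <- e$centre + e$radii
    if (any(lo < 0) || any(hi > ext)) stop("lung geometry outside the grid")
  }
  spec
}

# physical coordinates (mm) of every voxel centre, one vector per axis
.axis_mm <- function(n, sp) (seq_len(n) - 0.5) * sp

#' Generate a chest phantom with known ground truth
#'
#' Builds the body envelope (an elliptical cylinder along the slice axis),
#' carves two ellipsoidal lungs, draws each lung voxel fibrotic with the
#' design probability (spatially weighted per the pattern) and samples HU
#' from the corresponding normal distributions, clamped to the CT range.
#' The ground truth is then measured back from the emitted volume by
#' direct voxel counting, so it reflects what the volume actually
#' contains, including distributional tail leakage across the -700 HU
#' threshold.
#'
#' @param spec a [phantom_spec].
#' @return A list with `volume` (a [ct_volume]) and `truth`, where `truth`
#'   holds `lung_mask` ([voxel_mask] of the true ellipsoids),
#'   `fibrotic_voxel_count` (voxels drawn from the fibrotic distribution),
#'   `lung_voxel_count` (true-mask voxels inside the lung attenuation
#'   window) and `realized_fibrotic_fraction` (true-mask voxels measuring
#'   above the normal-lung cut, divided by `lung_voxel_count`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape; sp <- spec$spacing_mm
  s_mm <- .axis_mm(d[1], sp[1]); r_mm <- .axis_mm(d[2], sp[2])
  c_mm <- .axis_mm(d[3], sp[3])
  ext <- d * sp

  # body: elliptical cylinder spanning all slices, 90% of the in-plane extent
  rr <- ((r_mm - ext[2] / 2) / (0.45 * ext[2]))^2
  cc <- ((c_mm - ext[3] / 2) / (0.45 * ext[3]))^2
  body_plane <- outer(rr, cc, `+`) <= 1
  body <- aperm(array(body_plane, c(d[2], d[3], d[1])), c(3, 1, 2))

  lung <- array(FALSE, d)
  u2 <- array(Inf, d)   # squared normalized ellipsoid radius (0 centre, 1 surface)
  for (e in spec$lung_geometry) {
    q <- outer(outer(((s_mm - e$centre[1]) / e$radii[1])^2,
                     ((r_mm - e$centre[2]) / e$radii[2])^2, `+`),
               ((c_mm - e$centre[3]) / e$radii[3])^2, `+`)
    lung <- lung | q <= 1
    u2 <- pmin(u2, q)
  }
  if (!all(body[lung])) stop("lung geometry outside the body envelope")

  withr::with_seed(spec$seed, {
    vox <- array(spec$air_hu, d)
    vox[body] <- spec$body_hu
    idx <- which(lung)
    n_lung <- length(idx)
    f <- spec$design_fibrotic_fraction
    w <- switch(spec$pattern,
      uniform = rep(f, n_lung),
      subpleural = {
        u <- u2[idx]                       # grows toward the pleura
        if (f > 0) pmin(1, f * u / mean(u)) else rep(0, n_lung)
      },
      basal = {
        sidx <- arrayInd(idx, d)[, 1]
        u <- (d[1] - sidx) / d[1] + 0.1    # grows toward the base (low slice)
        if (f > 0) pmin(1, f * u / mean(u)) else rep(0, n_lung)
      })
    fib <- rbinom(n_lung, 1L, w) == 1L
    hu <- numeric(n_lung)
    hu[fib]  <- rnorm(sum(fib), spec$fibrotic_hu_mean, spec$fibrotic_hu_sd)
    hu[!fib] <- rnorm(sum(!fib), spec$normal_hu_mean, spec$normal_hu_sd)
    vox[idx] <- hu
  })

  volume <- ct_volume(vox, sp, patient_id = sprintf("phantom-%d", spec$seed),
                      meta = list(pattern = spec$pattern,
                                  design_fibrotic_fraction =
                                    spec$design_fibrotic_fraction))
  th <- cam_thresholds()
  hu_mask <- volume$voxels[lung]
  in_window <- hu_mask >= th$lung_low & hu_mask <= th$lung_high
  n_window <- sum(in_window)
  realized <- sum(hu_mask > th$normal_cut & in_window) / n_window
  truth <- list(lung_mask = voxel_mask(lung, "lung_truth"),
                fibrotic_voxel_count = sum(fib),
                lung_voxel_count = n_window,
                realized_fibrotic_fraction = realized)
  list(volume = volume, truth = truth)
}
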