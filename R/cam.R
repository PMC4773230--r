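#' Attenuation thresholds for tissue classification
#'
#' The densitometric score partitions the lung attenuation window
#' \eqn{[-1024, -200]} HU into three classes: normal parenchyma
#' \eqn{[-1024, -700]}, interstitial lung disease (ground glass +
#' reticulation) \eqn{(-700, -500]}, and consolidation \eqn{(-500, -200]}.
#' The cuts themselves are conventional; which side of each cut a boundary
#' voxel falls on is a choice, fixed here as a half-open partition so the
#' three class counts always sum exactly to the lung-window count.
#'
#' @param lung_low,lung_high bounds of the lung attenuation window (HU).
#' @param normal_cut upper bound of normal parenchyma (HU, inclusive).
#' @param ild_cut upper bound of the ILD range (HU, inclusive).
#' @return A `cam_thresholds` object.
#' @export
cam_thresholds <- function(lung_low = -1024, normal_cut = -700,
                           ild_cut = -500, lung_high = -200) {
  if (!(lung_low < normal_cut && normal_cut < ild_cut &&
        ild_cut < lung_high))
    stop("thresholds must satisfy lung_low < normal_cut < ild_cut < lung_high")
  structure(list(lung_low = lung_low, normal_cut = normal_cut,
                 ild_cut = ild_cut, lung_high = lung_high),
            class = "cam_thresholds")
}

#' Classify HU values into tissue classes
#'
#' @param hu numeric vector of calibrated HU values.
#' @param thresholds a [cam_thresholds].
#' @return A character vector over `{"non_lung", "normal", "ild",
#'   "consolidation"}`.
#' @examples
#' classify_voxel(c(-850, -600, -300, 0))
#' @export
classify_voxel <- function(hu, thresholds = cam_thresholds()) {
  stopifnot(inherits(thresholds, "cam_thresholds"))
  out <- rep("non_lung", length(hu))
  out[hu >= thresholds$lung_low   & hu <= thresholds$normal_cut] <- "normal"
  out[hu >  thresholds$normal_cut & hu <= thresholds$ild_cut]    <- "ild"
  out[hu >  thresholds$ild_cut    & hu <= thresholds$lung_high]  <- "consolidation"
  out
}

#' Tissue-class histogram over a lung mask
#'
#' Counts masked voxels per attenuation class. This histogram is the
#' sufficient statistic for the densitometric fibrosis score: the class
#' counts partition the lung-window count exactly.
#'
#' @param volume a [ct_volume].
#' @param lung_mask a [voxel_mask] aligned to `volume`.
#' @param thresholds a [cam_thresholds].
#' @return A `tissue_histogram` with counts `n_total_lung`,
#'   `n_nonfibrotic`, `n_ild`, `n_consolidation` and `voxel_volume_mm3`.
#' @export
build_histogram <- function(volume, lung_mask,
                            thresholds = cam_thresholds()) {
  stopifnot(inherits(volume, "ct_volume"), inherits(lung_mask, "voxel_mask"))
  check_aligned(lung_mask, volume)
  if (!any(lung_mask$flags)) stop("empty lung mask")
  hu <- volume$voxels[lung_mask$flags]
  n_norm <- sum(hu >= thresholds$lung_low   & hu <= thresholds$normal_cut)
  n_ild  <- sum(hu >  thresholds$normal_cut & hu <= thresholds$ild_cut)
  n_cons <- sum(hu >  thresholds$ild_cut    & hu <= thresholds$lung_high)
  structure(list(n_total_lung = n_norm + n_ild + n_cons,
                 n_nonfibrotic = n_norm, n_ild = n_ild,
                 n_consolidation = n_cons,
                 voxel_volume_mm3 = voxel_volume_mm3(volume),
                 thresholds = thresholds),
            class = "tissue_histogram")
}

#' Percent pulmonary fibrosis from a tissue histogram
#'
#' The fibrosis fraction is the lung-window volume minus the nonfibrotic
#' (normal-attenuation) volume, divided by the lung-window volume, times
#' 100. By the partition property this equals
#' \eqn{100 (n_{ild} + n_{consolidation}) / n_{total}}.
#'
#' @param hist a `tissue_histogram` with `n_total_lung > 0`.
#' @return A `cam_result` with `fibrosis_pct` (percent, full precision),
#'   `total_lung_volume_ml` and the input histogram.
#' @export
fibrosis_fraction <- function(hist) {
  stopifnot(inherits(hist, "tissue_histogram"))
  if (hist$n_total_lung <= 0) stop("no voxels in the lung attenuation window")
  pct <- 100 * (hist$n_total_lung - hist$n_nonfibrotic) / hist$n_total_lung
  structure(list(fibrosis_pct = pct, histogram = hist,
                 total_lung_volume_ml =
                   hist$n_total_lung * hist$voxel_volume_mm3 / 1000),
            class = "cam_result")
}

#' @export
print.cam_result <- function(x, ...) {
  cat(sprintf("<cam_result> pulmonary fibrosis %.1f %% of %.1f ml lung\n",
              x$fibrosis_pct, x$total_lung_volume_ml))
  h <- x$histogram
  cat(sprintf("  voxels: %d lung-window = %d normal + %d ILD + %d consolidation\n",
              h$n_total_lung, h$n_nonfibrotic, h$n_ild, h$n_consolidation))
  invisible(x)
}

#' Densitometric fibrosis score of a masked volume
#'
#' Convenience wrapper: [build_histogram] then [fibrosis_fraction].
#'
#' @inheritParams build_histogram
#' @return A `cam_result`.
#' @export
cam_score <- function(volume, lung_mask, thresholds = cam_thresholds()) {
  fibrosis_fraction(build_histogram(volume, lung_mask, thresholds))
}

#' Per-slice fibrosis profile
#'
#' Diagnostic output: the fibrosis percentage computed slice by slice. The
#' reported score is always the volumetric one; this profile only helps
#' locate where in the cranio-caudal axis the density sits.
#'
#' @inheritParams build_histogram
#' @return A data frame with columns `slice`, `n_total_lung`,
#'   `fibrosis_pct` (`NA` where a slice has no lung-window voxels).
#' @export
slice_profile <- function(volume, lung_mask,
                          thresholds = cam_thresholds()) {
  stopifnot(inherits(volume, "ct_volume"), inherits(lung_mask, "voxel_mask"))
  check_aligned(lung_mask, volume)
  ns <- dim(volume$voxels)[1]
  out <- data.frame(slice = seq_len(ns), n_total_lung = 0L,
                    fibrosis_pct = NA_real_)
  for (s in seq_len(ns)) {
    f <- lung_mask$flags[s, , ]
    if (!any(f)) next
    hu <- volume$voxels[s, , ][f]
    inwin <- hu >= thresholds$lung_low & hu <= thresholds$lung_high
    out$n_total_lung[s] <- sum(inwin)
    if (out$n_total_lung[s] > 0)
      out$fibrosis_pct[s] <-
        100 * sum(hu > thresholds$normal_cut & inwin) / out$n_total_lung[s]
  }
  out
}
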