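# The measurement stack: Hounsfield-interval artifact volumetry with
# prosthesis subtraction, pellet ROI density and deviation, SNR, paired
# comparisons and summary ratios.

#' Artifact segmentation thresholds
#'
#' Operational intervals on the extended HU scale: dark artifacts in
#' [-1042, -200] HU, bright artifacts in [400, 2500] HU. Both intervals are
#' closed on both sides. The gap between them brackets the background noise
#' of the noisiest images, so voxels outside it are attributed to streaks.
#'
#' @param dark,bright Two-element HU intervals; the dark maximum must lie
#'   below the bright minimum.
#' @export
artifact_thresholds <- function(dark = c(-1042, -200),
                                bright = c(400, 2500)) {
  stopifnot(length(dark) == 2, length(bright) == 2,
            dark[1] <= dark[2], bright[1] <= bright[2])
  if (dark[2] >= bright[1]) {
    stop("dark interval must end below the bright interval", call. = FALSE)
  }
  structure(list(dark = as.numeric(dark), bright = as.numeric(bright)),
            class = "artifact_thresholds")
}

#' Volumetric dark/bright artifact segmentation
#'
#' Dark volume counts every voxel inside the dark interval; bright volume
#' counts voxels inside the bright interval that are outside the implant
#' mask -- the prosthesis volume is subtracted so the metal itself is not
#' booked as a bright artifact. Volumes are voxel counts times voxel volume.
#'
#' @param ct A `ct_volume`.
#' @param implant Logical array congruent with `ct` (TRUE on the prosthesis),
#'   or NULL for no subtraction.
#' @param thresholds An [artifact_thresholds()].
#' @return One-row data frame of class `artifact_report`: provenance, dark,
#'   bright and total volumes in cm^3.
#' @export
segment_artifacts <- function(ct, implant = NULL,
                              thresholds = artifact_thresholds()) {
  stopifnot(inherits(ct, "ct_volume"),
            inherits(thresholds, "artifact_thresholds"))
  if (is.null(implant)) implant <- array(FALSE, dim = dim(ct$hu))
  if (!identical(dim(implant), dim(ct$hu))) {
    stop("implant mask grid mismatch", call. = FALSE)
  }
  vv <- voxel_volume_cm3(ct$spacing_mm)
  hu <- ct$hu
  dark <- sum(hu >= thresholds$dark[1] & hu <= thresholds$dark[2]) * vv
  bright <- sum(!implant & hu >= thresholds$bright[1] &
                  hu <= thresholds$bright[2]) * vv
  out <- data.frame(provenance = provenance_label(ct$provenance),
                    dark_cm3 = dark, bright_cm3 = bright,
                    total_cm3 = dark + bright)
  class(out) <- c("artifact_report", "data.frame")
  out
}

#' ROI density statistics
#'
#' Arithmetic mean HU (the "density"), sample standard deviation with n - 1
#' denominator (the "density deviation"), and the voxel count over a mask.
#'
#' @param ct A `ct_volume`.
#' @param roi Logical array congruent with `ct`; must select at least one
#'   voxel.
#' @param pellet_id Optional pellet identifier carried into the report.
#' @return One-row data frame of class `roi_report`.
#' @export
roi_statistics <- function(ct, roi, pellet_id = NA_integer_) {
  stopifnot(inherits(ct, "ct_volume"))
  if (!identical(dim(roi), dim(ct$hu))) stop("ROI grid mismatch",
                                             call. = FALSE)
  v <- ct$hu[roi]
  if (length(v) == 0) stop("empty ROI mask", call. = FALSE)
  out <- data.frame(pellet = pellet_id,
                    provenance = provenance_label(ct$provenance),
                    mean_hu = mean(v),
                    sd_hu = if (length(v) > 1) stats::sd(v) else 0,
                    n_voxels = length(v))
  class(out) <- c("roi_report", "data.frame")
  out
}

#' Signal-to-noise ratio of an ROI report
#'
#' Mean HU divided by the standard deviation (as measured on the reference
#' pellet). Undefined for zero deviation.
#'
#' @param report A `roi_report` row (or anything with `mean_hu`, `sd_hu`).
#' @export
snr <- function(report) {
  if (any(report$sd_hu <= 0)) stop("SNR undefined for SD = 0", call. = FALSE)
  report$mean_hu / report$sd_hu
}

#' Paired-sample t test
#'
#' Classical paired t on the differences, df = n - 1, two-sided p. Delegates
#' to [stats::t.test()]; identical samples (zero difference variance with
#' zero mean) return t = 0, p = 1 rather than erroring on constant data.
#'
#' @param a,b Paired numeric samples of equal length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stop("need paired samples of equal length >= 2", call. = FALSE)
  }
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = length(d) - 1, p = 1))
    stop("degenerate difference variance with nonzero mean", call. = FALSE)
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Percent reduction between two volumes
#'
#' `100 (1 - v_end / v_start)`, e.g. the dark-artifact reduction between the
#' 40 keV and 190 keV stations.
#'
#' @param v_start,v_end Volumes (same units); `v_start > 0`.
#' @export
reduction_fraction <- function(v_start, v_end) {
  if (any(v_start <= 0)) stop("non-positive start volume", call. = FALSE)
  100 * (1 - v_end / v_start)
}

#' Fold ratio between two volumes
#'
#' @param v_a,v_b Volumes; `v_b > 0`.
#' @param rounded Round to the nearest integer fold?
#' @export
fold_ratio <- function(v_a, v_b, rounded = FALSE) {
  if (any(v_b <= 0)) stop("zero denominator", call. = FALSE)
  r <- v_a / v_b
  if (rounded) round(r) else r
}

#' Background-noise range diagnostic
#'
#' Scans a metal-free region of the noisiest image (40 keV / 80 kVp in the
#' protocol) and reports its central HU range and mean -- the diagnostic
#' from which fixed dark/bright intervals are justified. The operational
#' thresholds remain the fixed intervals in [artifact_thresholds()].
#'
#' @param ct A `ct_volume`.
#' @param region Logical array congruent with `ct` selecting the metal-free
#'   background.
#' @param probs Lower/upper quantiles of the reported range.
#' @return List with `low`, `high`, `mean`.
#' @export
background_range <- function(ct, region, probs = c(0.005, 0.995)) {
  stopifnot(inherits(ct, "ct_volume"))
  v <- ct$hu[region]
  if (length(v) == 0) stop("empty background region", call. = FALSE)
  q <- stats::quantile(v, probs, names = FALSE)
  list(low = q[1], high = q[2], mean = mean(v))
}
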