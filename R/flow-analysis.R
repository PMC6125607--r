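# Transmitral inflow quantification from in-plane phase contrast:
# stationary-tissue phase-offset estimation, per-frame maximum velocity in
# a static circular ROI, inflow-angle correction, and E/A peak detection.

#' Estimate the phase-offset error from stationary tissue
#'
#' The offset is the median velocity over the masked voxels across all
#' frames; downstream it is subtracted from the whole velocity field.  A
#' mask placed over moving tissue is detected via the temporal SD of the
#' masked region and flagged.
#'
#' @param pc a \linkS4class{PCSeries}.
#' @param stationaryMask logical (rows x cols) mask of stationary tissue.
#' @param sdThreshold temporal-SD flag threshold, cm/sec.
#' @return list \code{offset} (cm/sec) and \code{flag} (character).
#' @export
estimatePhaseOffset <- function(pc, stationaryMask, sdThreshold = 2) {
  stopifnot(is(pc, "PCSeries"))
  stationaryMask <- stationaryMask != 0
  if (!any(stationaryMask)) stop("stationary mask is empty")
  v <- phaseToVelocity(pc)
  nf <- dim(v)[3L]
  vals <- vapply(seq_len(nf), function(k) {
    frame <- v[, , k]
    mean(frame[stationaryMask])
  }, numeric(1))
  allVals <- apply(v, 3L, function(frame) frame[stationaryMask])
  flag <- character()
  if (stats::sd(vals) > sdThreshold)
    flag <- "stationary mask shows temporal variation: offset may be biased"
  list(offset = stats::median(allVals), flag = flag)
}

#' Per-frame maximum velocity in a static circular ROI
#'
#' The ROI is a circle of the given area (default 10 cm^2, the standard
#' static inflow-tract region) centered on the mitral inflow; its radius in
#' pixels follows from r = sqrt(area / pi) and the pixel spacing.  Per
#' frame, Vmax is the signed velocity of largest magnitude among the
#' offset-corrected voxels inside the ROI.
#'
#' @param pc a \linkS4class{PCSeries}.
#' @param center ROI center, (row, col) px.
#' @param areaCm2 ROI area, cm^2.
#' @param offset phase offset to subtract, cm/sec.
#' @return a \linkS4class{VelocityCurve} (label "flow", cm/sec).
#' @export
roiVmaxCurve <- function(pc, center, areaCm2 = 10, offset = 0) {
  stopifnot(is(pc, "PCSeries"), areaCm2 > 0)
  sp <- pixelSpacing(pc)
  radiusMm <- sqrt(areaCm2 * 100 / pi)
  d <- dim(phaseData(pc))
  if (center[1L] - radiusMm / sp[1L] < 1 ||
      center[1L] + radiusMm / sp[1L] > d[1L] ||
      center[2L] - radiusMm / sp[2L] < 1 ||
      center[2L] + radiusMm / sp[2L] > d[2L])
    stop("ROI extends outside the image")
  rIdx <- seq_len(d[1L]); cIdx <- seq_len(d[2L])
  dist2 <- outer(((rIdx - center[1L]) * sp[1L])^2,
                 ((cIdx - center[2L]) * sp[2L])^2, `+`)
  inRoi <- dist2 <= radiusMm^2
  v <- phaseToVelocity(pc) - offset
  vmax <- vapply(seq_len(d[3L]), function(k) {
    vals <- v[, , k][inRoi]
    vals[which.max(abs(vals))]
  }, numeric(1))
  VelocityCurve(frameTimes(pc), vmax, label = "flow")
}

#' Correct an ROI velocity curve for the inflow angle
#'
#' The encode axis sees only the component of the inflow velocity along it.
#' In the default \code{"component_to_true"} mode the measured component is
#' back-projected onto the inflow direction, v = Vmax / cos(alpha).  The
#' \code{"as_printed"} mode applies v = Vmax * cos(alpha) instead; the two
#' modes satisfy v_printed = v_true * cos^2(alpha) for the same input.
#'
#' @param vmax a \linkS4class{VelocityCurve} of encoded-component maxima.
#' @param alpha angle between encode direction and inflow direction,
#'   degrees (0 <= alpha < 90).
#' @param mode \code{"component_to_true"} (default) or \code{"as_printed"}.
#' @return a \linkS4class{VelocityCurve}.
#' @export
angleCorrect <- function(vmax, alpha,
                         mode = c("component_to_true", "as_printed")) {
  stopifnot(is(vmax, "VelocityCurve"))
  mode <- match.arg(mode)
  if (alpha < 0 || alpha >= 90)
    stop("alpha must be in [0, 90) degrees: correction undefined at 90")
  ca <- cos(alpha * pi / 180)
  f <- if (mode == "component_to_true") 1 / ca else ca
  VelocityCurve(curveTimes(vmax), curveValues(vmax) * f, label = "flow")
}

#' Detect the E and A peaks of a transmitral velocity curve
#'
#' Within the diastolic window (from the end-systole hint to cycle end),
#' local maxima of |v| above a prominence threshold are identified; the
#' first is E and the last is A.  A single peak leaves A missing (fused or
#' absent atrial wave, e.g. atrial fibrillation), and E/A is then missing
#' too.
#'
#' @param v a \linkS4class{VelocityCurve} spanning one cycle (cm/sec).
#' @param systoleEndHint start of the diastolic window, sec; default 40
#'   percent of the cycle.
#' @param prominence fraction of the window maximum below which peaks are
#'   ignored.
#' @return list \code{E}, \code{A} (m/sec; A may be NA), \code{EoverA},
#'   \code{flag}.
#' @export
detectEA <- function(v, systoleEndHint = NULL, prominence = 0.1) {
  stopifnot(is(v, "VelocityCurve"))
  t <- curveTimes(v); val <- curveValues(v)
  period <- max(t) + stats::median(diff(t))
  if (is.null(systoleEndHint)) systoleEndHint <- 0.4 * period
  inWin <- t >= systoleEndHint
  if (sum(inWin) < 3L)
    return(list(E = NA_real_, A = NA_real_, EoverA = NA_real_,
                flag = "no inflow detected"))
  av <- abs(val[inWin])
  peaks <- findLocalPeaks(av, frac = prominence)
  if (!length(peaks))
    return(list(E = NA_real_, A = NA_real_, EoverA = NA_real_,
                flag = "no inflow detected"))
  E <- av[peaks[1L]] / 100
  A <- if (length(peaks) > 1L) av[peaks[length(peaks)]] / 100 else NA_real_
  list(E = E, A = A,
       EoverA = if (is.na(A)) NA_real_ else E / A,
       flag = character())
}

#' E/e' filling-pressure surrogate
#'
#' Ratio of the transmitral E peak to the mean of septal and lateral e',
#' with E converted to cm/sec so the ratio is dimensionless.
#'
#' @param E transmitral early peak, m/sec.
#' @param ePrimeSeptal,ePrimeLateral annular velocities, cm/sec.
#' @return E/e' (dimensionless).
#' @export
eOverEprime <- function(E, ePrimeSeptal, ePrimeLateral) {
  if (!all(is.finite(c(E, ePrimeSeptal, ePrimeLateral))) ||
      E <= 0 || ePrimeSeptal <= 0 || ePrimeLateral <= 0)
    stop("E and both e-prime values must be positive")
  (E * 100) / mean(c(ePrimeSeptal, ePrimeLateral))
}
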