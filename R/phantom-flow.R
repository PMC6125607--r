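# In-plane phase-contrast phantom: a circular transmitral "jet" whose speed
# follows the biphasic FlowModel waveform, directed at angle alpha from the
# flow-encode axis.  Phase images encode the component along the encode
# direction (speed * cos alpha) plus a constant background phase offset;
# a stationary-tissue block carries exactly the offset, as required for
# offset-correction testing.

#' Phase-contrast phantom with known E and A
#'
#' @param flow a \code{\link{flowModel}}.
#' @param imageSize c(rows, cols) pixels.
#' @param pixelSpacing c(row, col) mm (in-plane PC resolution).
#' @param nFrames reconstructed timeframes.
#' @param jetCenterFrac jet center as (row, col) fractions of the image.
#' @param jetRadiusMm jet radius, mm.
#' @param encodeDirection in-plane (row, col) encode direction.
#' @return list with \code{pc} (a \linkS4class{PCSeries}) and \code{truth}:
#'   jet center (px), the stationary-tissue mask, encoded peak component
#'   velocities, and the generating flow model.
#' @export
makePCPhantom <- function(flow, imageSize = c(96L, 96L),
                          pixelSpacing = c(1.9, 1.9), nFrames = 30L,
                          jetCenterFrac = c(0.55, 0.55), jetRadiusMm = 14,
                          encodeDirection = c(1, 0)) {
  stopifnot(inherits(flow, "FlowModel"))
  rows <- imageSize[1L]; cols <- imageSize[2L]
  times <- (seq_len(nFrames) - 1L) * flow$rr / nFrames
  cr <- jetCenterFrac[1L] * rows; cc <- jetCenterFrac[2L] * cols
  rPx <- jetRadiusMm / pixelSpacing[1L]
  if (cr - rPx < 1 || cr + rPx > rows || cc - rPx < 1 || cc + rPx > cols)
    stop("geometry error: jet extends outside the field of view")
  rc <- expand.grid(r = seq_len(rows), c = seq_len(cols))
  inJet <- matrix(
    ((rc$r - cr) / (jetRadiusMm / pixelSpacing[1L]))^2 +
      ((rc$c - cc) / (jetRadiusMm / pixelSpacing[2L]))^2 <= 1,
    rows, cols
  )
  # stationary block in the upper-left corner, away from the jet
  statMask <- matrix(FALSE, rows, cols)
  statMask[5:round(0.22 * rows), 5:round(0.22 * cols)] <- TRUE
  if (any(statMask & inJet))
    stop("geometry error: jet overlaps the stationary-tissue region")
  cosA <- cos(flow$alpha * pi / 180)
  speed <- flow$speed(times)                       # cm/sec along inflow
  phase <- array(0, dim = c(rows, cols, nFrames))
  mag <- array(50, dim = c(rows, cols, nFrames))
  for (k in seq_len(nFrames)) {
    venc <- flow$venc
    vEnc <- matrix(flow$phaseOffset, rows, cols)
    vEnc[inJet] <- vEnc[inJet] + speed[k] * cosA
    phase[, , k] <- vEnc / venc * pi
    mk <- matrix(50, rows, cols)
    mk[inJet] <- 200
    mag[, , k] <- mk
  }
  magnitude <- CineSeries(mag, frameTimes = times,
                          pixelSpacing = pixelSpacing,
                          viewLabel = "three_chamber")
  pc <- PCSeries(magnitude, phase, venc = flow$venc,
                 encodeDirection = encodeDirection)
  truth <- list(
    jetCenterPx = c(row = cr, col = cc),
    jetRadiusPx = rPx,
    stationaryMask = statMask,
    encodedPeakE = 100 * flow$E * cosA,
    encodedPeakA = 100 * flow$A * cosA,
    phaseOffset = flow$phaseOffset,
    times = times,
    flow = flow
  )
  list(pc = pc, truth = truth)
}
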