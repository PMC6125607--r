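# strip foreign classes/attributes (e.g. niftiImage) down to a bare array
plainArray <- function(x) {
  array(as.vector(x), dim = dim(x))
}

#' Construct a CineSeries
#'
#' @param frames 3D numeric array (rows, cols, frames).
#' @param frameTimes seconds from R-wave, one per frame; if missing and
#'   \code{rr} is given, uniform spacing \code{rr/nFrames} starting at 0.
#' @param pixelSpacing numeric(2) (row, col) mm.
#' @param viewLabel view name; see \linkS4class{CineSeries}.
#' @param sliceLocation optional slice position, mm.
#' @param rr RR interval in seconds, used only to infer uniform timing.
#' @return a \linkS4class{CineSeries}.
#' @export
CineSeries <- function(frames, frameTimes = NULL, pixelSpacing = c(1.4, 1.4),
                       viewLabel = "four_chamber", sliceLocation = NULL,
                       rr = NULL) {
  frames <- plainArray(frames)
  if (is.null(frameTimes)) {
    if (is.null(rr))
      stop("either frameTimes or rr must be supplied")
    nf <- dim(frames)[3L]
    frameTimes <- (seq_len(nf) - 1L) * rr / nf
  }
  new("CineSeries",
    frames = frames, frameTimes = as.numeric(frameTimes),
    pixelSpacing = as.numeric(pixelSpacing), viewLabel = viewLabel,
    sliceLocation = sliceLocation
  )
}

#' Construct a PCSeries
#'
#' Phase may be supplied in radians (default) or as vendor integer scaling
#' with a declared full scale; integers are normalized to radians on
#' construction so that +fullScale maps to +pi (and hence to +VENC).
#'
#' @param magnitude a \linkS4class{CineSeries}.
#' @param phase array matching the magnitude dimensions.
#' @param venc velocity-encoding limit, cm/sec.
#' @param encodeDirection in-plane (row, col) flow-encode direction;
#'   normalized to unit length.
#' @param phaseUnits \code{"radians"} or \code{"scaled_int"}.
#' @param fullScale full-scale phase value for \code{"scaled_int"} input
#'   (e.g. 4096 for a signed 12-bit export where +/-4096 is +/-pi).
#' @return a \linkS4class{PCSeries}.
#' @export
PCSeries <- function(magnitude, phase, venc, encodeDirection = c(1, 0),
                     phaseUnits = c("radians", "scaled_int"),
                     fullScale = NULL) {
  phaseUnits <- match.arg(phaseUnits)
  phase <- plainArray(phase)
  if (phaseUnits == "scaled_int") {
    if (is.null(fullScale) || fullScale <= 0)
      stop("fullScale must be supplied (positive) for scaled integer phase")
    phase <- phase / fullScale * pi
  }
  if (venc < vencValidRange[1L] || venc > vencValidRange[2L])
    warning(sprintf(
      "venc = %.0f cm/s is outside the usual transmitral window [%.0f, %.0f]",
      venc, vencValidRange[1L], vencValidRange[2L]
    ))
  encodeDirection <- as.numeric(encodeDirection)
  encodeDirection <- encodeDirection / sqrt(sum(encodeDirection^2))
  new("PCSeries",
    magnitude = magnitude, phase = phase, venc = as.numeric(venc),
    encodeDirection = encodeDirection
  )
}

#' Construct an LGEVolume
#'
#' @param voxels 3D intensity array.
#' @param spacing numeric(3) (x, y, z) mm.
#' @param endoMask logical/0-1 array of the LA blood pool.
#' @param artifactMask optional exclusion mask.
#' @return an \linkS4class{LGEVolume}.
#' @export
LGEVolume <- function(voxels, spacing, endoMask, artifactMask = NULL) {
  new("LGEVolume",
    voxels = plainArray(voxels), spacing = as.numeric(spacing),
    endoMask = plainArray(endoMask),
    artifactMask = if (is.null(artifactMask)) NULL else
      plainArray(artifactMask)
  )
}

#' Construct a VelocityCurve
#'
#' @param times seconds; @param values cm/sec (mL/sec for volume_rate);
#' @param label curve label.
#' @return a \linkS4class{VelocityCurve}.
#' @export
VelocityCurve <- function(times, values, label = "flow") {
  new("VelocityCurve",
    times = as.numeric(times), values = as.numeric(values), label = label
  )
}
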