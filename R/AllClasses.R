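#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Time-resolved cine MRI series
#'
#' Container for a single-slice cine acquisition: a stack of 2D frames with
#' per-frame trigger times and in-plane pixel spacing.  The array is stored
#' as (row, col, frame); physical position of a pixel is index times spacing,
#' and times are seconds from the R-wave, so frame 1 is end-diastole.
#'
#' @slot frames numeric array, dim (rows, cols, nFrames); arbitrary
#'   intensity units.
#' @slot frameTimes numeric vector of seconds from the R-wave, strictly
#'   increasing, first entry at (or very near) zero.
#' @slot pixelSpacing numeric(2), (row, col) spacing in mm.
#' @slot viewLabel one of \code{"four_chamber"}, \code{"short_axis"},
#'   \code{"three_chamber"}.
#' @slot sliceLocation slice position in mm (short-axis stacks), or NULL.
#' @export
setClass("CineSeries",
  representation(
    frames = "array",
    frameTimes = "numeric",
    pixelSpacing = "numeric",
    viewLabel = "character",
    sliceLocation = "numericOrNULL"
  ),
  prototype(viewLabel = "four_chamber", sliceLocation = NULL)
)

setValidity("CineSeries", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "frames must be a 3D array (rows, cols, frames)")
  nf <- dim(object@frames)[3L]
  if (length(object@frameTimes) != nf)
    msg <- c(msg, "length(frameTimes) must equal the number of frames")
  if (length(object@frameTimes) > 1L && any(diff(object@frameTimes) <= 0))
    msg <- c(msg, "frameTimes must be strictly increasing")
  if (length(object@frameTimes) && abs(object@frameTimes[1L]) > 0.02)
    msg <- c(msg, "first frame time must be ~0 (R-wave reference)")
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    msg <- c(msg, "pixelSpacing must be two positive values (row, col) in mm")
  if (!object@viewLabel %in% c("four_chamber", "short_axis", "three_chamber"))
    msg <- c(msg, "unknown viewLabel")
  if (length(msg)) msg else TRUE
})

#' Phase-contrast velocity-encoded series
#'
#' A magnitude cine paired with phase images holding the velocity-encoded
#' signal.  Phase is stored in radians; full scale (+/- pi) maps to +/- VENC.
#' The flow-encode direction is an in-plane unit vector in (row, col)
#' components.
#'
#' @slot magnitude a \linkS4class{CineSeries}.
#' @slot phase numeric array with the same dimensions as the magnitude
#'   frames, radians in [-pi, pi].
#' @slot venc velocity-encoding limit, cm/sec.
#' @slot encodeDirection numeric(2) unit vector (row, col components).
#' @export
setClass("PCSeries",
  representation(
    magnitude = "CineSeries",
    phase = "array",
    venc = "numeric",
    encodeDirection = "numeric"
  )
)

#' Valid VENC range accepted when constructing a PCSeries
#'
#' The velocity-encoding window regarded as plausible for transmitral
#' in-plane flow studies; constructors warn outside it.
#' @export
vencValidRange <- c(150, 400)

setValidity("PCSeries", function(object) {
  msg <- character()
  if (!identical(dim(object@phase), dim(object@magnitude@frames)))
    msg <- c(msg, "phase and magnitude arrays must share dimensions")
  if (length(object@venc) != 1L || !is.finite(object@venc) || object@venc <= 0)
    msg <- c(msg, "venc must be a single positive number (cm/sec)")
  if (length(object@encodeDirection) != 2L ||
      abs(sqrt(sum(object@encodeDirection^2)) - 1) > 1e-6)
    msg <- c(msg, "encodeDirection must be a unit 2-vector")
  if (max(abs(object@phase)) > pi + 1e-9)
    msg <- c(msg, "phase must be stored in radians within [-pi, pi]")
  if (length(msg)) msg else TRUE
})

#' 3D late-gadolinium-enhancement volume
#'
#' Interpolated 3D LGE acquisition with voxel spacing, the left-atrial
#' blood-pool (endocardial) mask and an optional artifact-exclusion mask.
#'
#' @slot voxels numeric 3D array of intensities.
#' @slot spacing numeric(3) voxel spacing (x, y, z) mm; z is the axial
#'   slice direction used for slice-wise summation.
#' @slot endoMask logical/0-1 array, same shape: LA blood pool.
#' @slot artifactMask optional logical/0-1 array of voxels to exclude.
#' @export
setClass("LGEVolume",
  representation(
    voxels = "array",
    spacing = "numeric",
    endoMask = "array",
    artifactMask = "arrayOrNULL"
  ),
  prototype(artifactMask = NULL)
)

setValidity("LGEVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive values (mm)")
  if (!identical(dim(object@endoMask), dim(object@voxels)))
    msg <- c(msg, "endoMask must share the voxel array shape")
  if (!is.null(object@artifactMask) &&
      !identical(dim(object@artifactMask), dim(object@voxels)))
    msg <- c(msg, "artifactMask must share the voxel array shape")
  if (length(msg)) msg else TRUE
})

#' Sampled velocity-versus-time curve
#'
#' One cardiac cycle of a velocity trace: annular tissue velocity, ROI
#' maximum blood velocity, or a volumetric filling rate, depending on the
#' label.  Units are cm/sec for tissue and blood velocity and mL/sec for
#' volume rate.
#'
#' @slot times seconds from the R-wave, strictly increasing.
#' @slot values velocities (cm/sec, or mL/sec for label "volume_rate").
#' @slot label one of "septal", "lateral", "flow", "volume_rate".
#' @export
setClass("VelocityCurve",
  representation(times = "numeric", values = "numeric", label = "character"),
  prototype(label = "flow")
)

setValidity("VelocityCurve", function(object) {
  msg <- character()
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have equal length")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (!object@label %in% c("septal", "lateral", "flow", "volume_rate"))
    msg <- c(msg, "unknown curve label")
  if (length(msg)) msg else TRUE
})

#' Left-ventricular volume-time curve
#'
#' Slice-summed LV cavity volume over one cycle with derived end-diastolic
#' and end-systolic volumes and ejection fraction (percent), and optionally
#' myocardial mass (g).
#'
#' @slot times seconds from the R-wave.
#' @slot volumes mL, one per frame, all positive.
#' @slot edv,esv end-diastolic / end-systolic volume, mL.
#' @slot ef ejection fraction, percent, equal to 100 (edv - esv) / edv.
#' @slot mass myocardial mass in g, or NULL when no epicardial contour.
#' @export
setClass("VolumeTimeCurve",
  representation(
    times = "numeric", volumes = "numeric",
    edv = "numeric", esv = "numeric", ef = "numeric",
    mass = "numericOrNULL"
  ),
  prototype(mass = NULL)
)

setValidity("VolumeTimeCurve", function(object) {
  msg <- character()
  if (length(object@times) != length(object@volumes))
    msg <- c(msg, "times and volumes must have equal length")
  if (any(object@volumes <= 0))
    msg <- c(msg, "volumes must be positive")
  if (object@esv > object@edv + 1e-9)
    msg <- c(msg, "esv must not exceed edv")
  if (abs(object@ef - 100 * (object@edv - object@esv) / object@edv) > 1e-6)
    msg <- c(msg, "ef must equal 100*(edv-esv)/edv")
  if (length(msg)) msg else TRUE
})

#' Annular point tracks over one cycle
#'
#' Per-frame septal and lateral mitral-annular positions in physical (mm)
#' coordinates, together with the unit normal of the end-diastolic annular
#' plane (the line through the two frame-1 points).
#'
#' @slot septal,lateral nFrames x 2 matrices of (row, col) positions, mm.
#' @slot planeNormal unit 2-vector normal to the end-diastolic annular line,
#'   oriented apex-ward.
#' @slot times seconds from the R-wave.
#' @slot flags character vector of tracking warnings (drift, low
#'   correlation), empty when tracking was clean.
#' @export
setClass("AnnularTrace",
  representation(
    septal = "matrix", lateral = "matrix",
    planeNormal = "numeric", times = "numeric",
    flags = "character"
  ),
  prototype(flags = character())
)

setValidity("AnnularTrace", function(object) {
  msg <- character()
  if (ncol(object@septal) != 2L || ncol(object@lateral) != 2L)
    msg <- c(msg, "position matrices must have two columns (row, col) mm")
  if (nrow(object@septal) != length(object@times) ||
      nrow(object@lateral) != length(object@times))
    msg <- c(msg, "one position per frame is required")
  if (!all(is.finite(object@septal)) || !all(is.finite(object@lateral)))
    msg <- c(msg, "positions must be finite")
  if (abs(sqrt(sum(object@planeNormal^2)) - 1) > 1e-6)
    msg <- c(msg, "planeNormal must have unit length")
  if (length(msg)) msg else TRUE
})
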