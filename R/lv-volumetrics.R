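# LV volumetry from short-axis endocardial masks: slice summation to a
# volume-time curve, myocardial mass from the end-diastolic epi/endo
# shell, and peak filling rate as the early-diastolic maximum of dV/dt.

#' LV volume-time curve by short-axis slice summation
#'
#' V(t) is the sum over slices of mask area times slice thickness.  A slice
#' contributes whenever its mask is non-empty; no partial-slice correction
#' is applied.  EDV and ESV are the curve extrema and EF their relative
#' difference.
#'
#' @param masks logical array (rows, cols, slices, frames) of endocardial
#'   masks.
#' @param spacing c(row mm, col mm, slice thickness mm).
#' @param times frame times, sec.
#' @return a \linkS4class{VolumeTimeCurve}.
#' @export
sliceSummation <- function(masks, spacing, times) {
  d <- dim(masks)
  if (length(d) != 4L)
    stop("masks must be a 4D array (rows, cols, slices, frames)")
  if (length(times) != d[4L]) stop("one time per frame is required")
  voxMl <- spacing[1L] * spacing[2L] * spacing[3L] / 1000
  volumes <- vapply(seq_len(d[4L]), function(k) {
    sum(masks[, , , k] != 0) * voxMl
  }, numeric(1))
  if (any(volumes == 0))
    stop("a frame has empty masks in all slices")
  edv <- max(volumes); esv <- min(volumes)
  new("VolumeTimeCurve", times = as.numeric(times), volumes = volumes,
      edv = edv, esv = esv, ef = 100 * (edv - esv) / edv, mass = NULL)
}

#' Myocardial mass from end-diastolic contours
#'
#' Mass = (epicardial volume - endocardial volume) x 1.05 g/mL, the
#' standard myocardial density.
#'
#' @param endoMasks,epiMasks logical arrays (rows, cols, slices) at
#'   end-diastole; the endocardial mask must lie inside the epicardial one.
#' @param spacing c(row mm, col mm, slice thickness mm).
#' @param density myocardial density, g/mL.
#' @return mass in g.
#' @export
lvMass <- function(endoMasks, epiMasks, spacing, density = 1.05) {
  endo <- endoMasks != 0; epi <- epiMasks != 0
  if (!identical(dim(endo), dim(epi)))
    stop("endo and epi masks must share dimensions")
  if (any(endo & !epi))
    stop("endocardial mask extends outside the epicardial mask")
  voxMl <- prod(spacing[1:3]) / 1000
  (sum(epi) - sum(endo)) * voxMl * density
}

#' Peak filling rate from a volume-time curve
#'
#' The curve is smoothed with the shared periodic spline engine and dV/dt
#' taken as the spline's analytic derivative.  PFR is the maximum of dV/dt
#' in the early-diastolic window from the ESV time to the midpoint of
#' diastole (the same window convention used for e').
#'
#' @param curve a \linkS4class{VolumeTimeCurve} (>= 10 frames).
#' @param spar optional smoothing parameter.
#' @return list \code{pfr} (mL/sec), \code{tEsv}, \code{flag}, and
#'   \code{rateCurve} (a \linkS4class{VelocityCurve}, label "volume_rate").
#' @export
peakFillingRate <- function(curve, spar = NULL) {
  stopifnot(is(curve, "VolumeTimeCurve"))
  t <- curve@times; v <- curve@volumes
  if (length(t) < 10L) stop("at least 10 frames are required")
  eng <- periodicSplineDerivative(t, v, spar = spar)
  tEsv <- t[which.min(v)]
  wEnd <- (tEsv + eng$period) / 2
  fine <- seq(tEsv, wEnd, length.out = 200L)
  dv <- eng$deriv(fine)
  rate <- VelocityCurve(t, eng$deriv(t), label = "volume_rate")
  if (max(dv) <= 1e-6 * max(v))
    return(list(pfr = 0, tEsv = tEsv, flag = "no early-diastolic filling",
                rateCurve = rate))
  list(pfr = max(dv), tEsv = tEsv, flag = character(), rateCurve = rate)
}
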