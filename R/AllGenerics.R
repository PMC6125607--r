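#' Accessors for image and curve containers
#'
#' Standard accessors for the S4 containers: \code{frames} and
#' \code{frameTimes} return the image stack and trigger times of a cine,
#' \code{pixelSpacing} its in-plane spacing; \code{phaseData} and
#' \code{venc} the phase array and velocity-encoding limit of a
#' phase-contrast series; \code{voxels}, \code{spacing} and \code{endoMask}
#' the components of an LGE volume; \code{curveTimes} and \code{curveValues}
#' the samples of a velocity or volume curve.
#'
#' @param object an S4 object from this package.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setGeneric("viewLabel", function(object) standardGeneric("viewLabel"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("phaseData", function(object) standardGeneric("phaseData"))
#' @rdname accessors
#' @export
setGeneric("venc", function(object) standardGeneric("venc"))
#' @rdname accessors
#' @export
setGeneric("encodeDirection", function(object) standardGeneric("encodeDirection"))
#' @rdname accessors
#' @export
setGeneric("magnitudeSeries", function(object) standardGeneric("magnitudeSeries"))
#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("endoMask", function(object) standardGeneric("endoMask"))
#' @rdname accessors
#' @export
setGeneric("artifactMask", function(object) standardGeneric("artifactMask"))
#' @rdname accessors
#' @export
setGeneric("curveTimes", function(object) standardGeneric("curveTimes"))
#' @rdname accessors
#' @export
setGeneric("curveValues", function(object) standardGeneric("curveValues"))
#' @rdname accessors
#' @export
setGeneric("curveLabel", function(object) standardGeneric("curveLabel"))

#' @rdname accessors
#' @export
setMethod("frames", "CineSeries", function(object) object@frames)
#' @rdname accessors
#' @export
setMethod("frameTimes", "CineSeries", function(object) object@frameTimes)
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "CineSeries", function(object) object@pixelSpacing)
#' @rdname accessors
#' @export
setMethod("viewLabel", "CineSeries", function(object) object@viewLabel)
#' @rdname accessors
#' @export
setMethod("nFrames", "CineSeries", function(object) dim(object@frames)[3L])
#' @rdname accessors
#' @export
setMethod("frames", "PCSeries", function(object) object@magnitude@frames)
#' @rdname accessors
#' @export
setMethod("frameTimes", "PCSeries", function(object) object@magnitude@frameTimes)
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "PCSeries", function(object) object@magnitude@pixelSpacing)
#' @rdname accessors
#' @export
setMethod("nFrames", "PCSeries", function(object) dim(object@phase)[3L])
#' @rdname accessors
#' @export
setMethod("phaseData", "PCSeries", function(object) object@phase)
#' @rdname accessors
#' @export
setMethod("venc", "PCSeries", function(object) object@venc)
#' @rdname accessors
#' @export
setMethod("encodeDirection", "PCSeries", function(object) object@encodeDirection)
#' @rdname accessors
#' @export
setMethod("magnitudeSeries", "PCSeries", function(object) object@magnitude)
#' @rdname accessors
#' @export
setMethod("voxels", "LGEVolume", function(object) object@voxels)
#' @rdname accessors
#' @export
setMethod("spacing", "LGEVolume", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("endoMask", "LGEVolume", function(object) object@endoMask)
#' @rdname accessors
#' @export
setMethod("artifactMask", "LGEVolume", function(object) object@artifactMask)
#' @rdname accessors
#' @export
setMethod("curveTimes", "VelocityCurve", function(object) object@times)
#' @rdname accessors
#' @export
setMethod("curveValues", "VelocityCurve", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("curveLabel", "VelocityCurve", function(object) object@label)
#' @rdname accessors
#' @export
setMethod("curveTimes", "VolumeTimeCurve", function(object) object@times)
#' @rdname accessors
#' @export
setMethod("curveValues", "VolumeTimeCurve", function(object) object@volumes)

setMethod("show", "CineSeries", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "CineSeries (%s): %d x %d px, %d frames, %.2f x %.2f mm, RR ~ %.0f ms\n",
    object@viewLabel, d[1L], d[2L], d[3L],
    object@pixelSpacing[1L], object@pixelSpacing[2L],
    1000 * (max(object@frameTimes) + diff(object@frameTimes)[1L])
  ))
})

setMethod("show", "PCSeries", function(object) {
  d <- dim(object@phase)
  cat(sprintf(
    "PCSeries: %d x %d px, %d frames, VENC %.0f cm/s, encode (%.2f, %.2f)\n",
    d[1L], d[2L], d[3L], object@venc,
    object@encodeDirection[1L], object@encodeDirection[2L]
  ))
})

setMethod("show", "LGEVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf(
    "LGEVolume: %d x %d x %d voxels at %.2f x %.2f x %.2f mm (LA pool: %d voxels)\n",
    d[1L], d[2L], d[3L], object@spacing[1L], object@spacing[2L],
    object@spacing[3L], sum(object@endoMask != 0)
  ))
})

setMethod("show", "VelocityCurve", function(object) {
  unit <- if (object@label == "volume_rate") "mL/s" else "cm/s"
  cat(sprintf(
    "VelocityCurve [%s]: %d samples over %.3f s, range %.2f to %.2f %s\n",
    object@label, length(object@times), max(object@times) - min(object@times),
    min(object@values), max(object@values), unit
  ))
})

setMethod("show", "VolumeTimeCurve", function(object) {
  cat(sprintf(
    "VolumeTimeCurve: %d frames, EDV %.1f mL, ESV %.1f mL, EF %.1f%%%s\n",
    length(object@times), object@edv, object@esv, object@ef,
    if (is.null(object@mass)) "" else sprintf(", mass %.1f g", object@mass)
  ))
})

setMethod("show", "AnnularTrace", function(object) {
  cat(sprintf(
    "AnnularTrace: %d frames, plane normal (%.2f, %.2f)%s\n",
    length(object@times), object@planeNormal[1L], object@planeNormal[2L],
    if (length(object@flags)) paste0(" [", paste(object@flags, collapse = "; "), "]")
    else ""
  ))
})
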