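# Readers/writers for the image dialects used by the pipeline: NIfTI-1
# volumes with a JSON sidecar carrying timing/VENC metadata, and (for cine
# input only) a directory of single-frame DICOM files.  Phantom generators
# emit exactly the NIfTI + sidecar dialect these functions read.

sidecarPath <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

readSidecar <- function(path) {
  sp <- sidecarPath(path)
  if (!file.exists(sp)) return(list())
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

cineArrayFromNifti <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  d <- dim(a)
  if (length(d) == 4L && d[3L] == 1L) a <- a[, , 1L, , drop = TRUE]
  if (length(dim(a)) != 3L)
    stop("format error: expected a 2D+time NIfTI series")
  list(arr = a, pixdim = attr(img, "pixdim"))
}

#' Read a cine series
#'
#' NIfTI input expects a 2D+time volume plus a JSON sidecar; frame times are
#' taken verbatim from \code{frame_times_ms} when present, otherwise
#' inferred as uniform divisions of \code{rr_ms}.  DICOM input expects a
#' directory of single-frame files (explicit-VR little-endian, uncompressed)
#' whose TriggerTime tags give the frame times verbatim.
#'
#' @param path NIfTI file, or a directory of DICOM files.
#' @param format \code{"nifti"} or \code{"dicom"}.
#' @return a \linkS4class{CineSeries}.
#' @export
readCine <- function(path, format = c("nifti", "dicom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (format == "dicom") return(readCineDicom(path))
  x <- cineArrayFromNifti(path)
  meta <- readSidecar(path)
  nf <- dim(x$arr)[3L]
  times <- if (!is.null(meta$frame_times_ms)) {
    if (length(meta$frame_times_ms) != nf)
      stop("integrity error: sidecar frame count does not match the image")
    as.numeric(meta$frame_times_ms) / 1000
  } else if (!is.null(meta$rr_ms)) {
    (seq_len(nf) - 1L) * (meta$rr_ms / 1000) / nf
  } else {
    stop("format error: no frame_times_ms or rr_ms in sidecar")
  }
  spacingMm <- if (!is.null(meta$pixel_spacing_mm)) {
    as.numeric(meta$pixel_spacing_mm)
  } else {
    as.numeric(x$pixdim[1:2])
  }
  CineSeries(x$arr, frameTimes = times, pixelSpacing = spacingMm,
             viewLabel = meta$view_label %||% "four_chamber",
             sliceLocation = meta$slice_location_mm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cine series as NIfTI + JSON sidecar
#'
#' @param cine a \linkS4class{CineSeries}.
#' @param path output NIfTI path (\code{.nii}); the sidecar is written next
#'   to it with extension \code{.json}.
#' @return \code{path}, invisibly.
#' @export
writeCine <- function(cine, path) {
  stopifnot(is(cine, "CineSeries"))
  RNifti::writeNifti(RNifti::asNifti(frames(cine)), path)
  jsonlite::write_json(
    list(
      frame_times_ms = frameTimes(cine) * 1000,
      pixel_spacing_mm = pixelSpacing(cine),
      view_label = viewLabel(cine),
      slice_location_mm = cine@sliceLocation
    ),
    sidecarPath(path), auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read a phase-contrast series (magnitude + phase NIfTI pair)
#'
#' The sidecar of the magnitude image must carry \code{venc_cm_s}; phase
#' scaling is declared there too (\code{phase_units} of \code{"radians"} or
#' \code{"scaled_int"} with \code{phase_full_scale}).
#'
#' @param magPath,phasePath NIfTI paths.
#' @return a \linkS4class{PCSeries}.
#' @export
readPCSeries <- function(magPath, phasePath) {
  magnitude <- readCine(magPath)
  ph <- cineArrayFromNifti(phasePath)$arr
  if (!identical(dim(ph), dim(frames(magnitude))))
    stop("integrity error: phase and magnitude series differ in shape")
  meta <- readSidecar(magPath)
  if (is.null(meta$venc_cm_s)) stop("format error: sidecar lacks venc_cm_s")
  units <- meta$phase_units %||% "radians"
  PCSeries(magnitude, ph, venc = meta$venc_cm_s,
           encodeDirection = meta$encode_direction %||% c(1, 0),
           phaseUnits = units, fullScale = meta$phase_full_scale)
}

#' Write a phase-contrast series
#'
#' @param pc a \linkS4class{PCSeries}.
#' @param magPath,phasePath output NIfTI paths; the magnitude sidecar
#'   carries timing, VENC and encode direction.
#' @return \code{magPath}, invisibly.
#' @export
writePCSeries <- function(pc, magPath, phasePath) {
  stopifnot(is(pc, "PCSeries"))
  writeCine(magnitudeSeries(pc), magPath)
  meta <- jsonlite::read_json(sidecarPath(magPath), simplifyVector = TRUE)
  meta$venc_cm_s <- venc(pc)
  meta$phase_units <- "radians"
  meta$encode_direction <- encodeDirection(pc)
  jsonlite::write_json(meta, sidecarPath(magPath), auto_unbox = TRUE,
                       digits = NA, null = "null")
  RNifti::writeNifti(RNifti::asNifti(phaseData(pc)), phasePath)
  invisible(magPath)
}

#' Convert phase-contrast phase to velocity
#'
#' Standard linear phase-contrast reconstruction: velocity =
#' phase / pi * VENC, so full-scale phase maps to +/- VENC.  Velocities
#' beyond VENC after mapping indicate wraparound and raise a warning; they
#' are flagged, never unwrapped.
#'
#' @param pc a \linkS4class{PCSeries}.
#' @return numeric array of velocities, cm/sec, same shape as the phase.
#' @export
phaseToVelocity <- function(pc) {
  stopifnot(is(pc, "PCSeries"))
  v <- phaseData(pc) / pi * venc(pc)
  if (any(abs(v) > venc(pc) + 1e-9))
    warning("velocity wraparound: |v| exceeds VENC; values flagged, not unwrapped")
  v
}
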