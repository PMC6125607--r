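# Short-axis LV stack phantom: per-slice circular endocardial masks whose
# slice-summed volume follows the analytic V(t) of a VolumeModel, modeled
# as a cylinder of uniform cross-section across slices.  Voxelization uses
# the pixel-center-in-disk rule, matching how binary endocardial masks are
# summed downstream.

#' Short-axis mask-stack phantom with known volume curve and PFR
#'
#' @param model a \code{\link{volumeModel}}.
#' @param nSlices number of short-axis slices.
#' @param imageSize c(rows, cols) pixels per slice.
#' @param pixelSpacing c(row, col) mm.
#' @param sliceThickness mm.
#' @param nFrames reconstructed timeframes.
#' @param wallThicknessMm optional uniform myocardial wall thickness; when
#'   given, end-diastolic epicardial masks and the analytic shell volume are
#'   included for mass testing.
#' @return list with \code{masks} (logical rows x cols x slices x frames),
#'   \code{spacing} c(row mm, col mm, slice mm), \code{times}, and
#'   \code{truth}: analytic V(t), PFR, EDV/ESV, and (optionally) the
#'   epicardial masks plus analytic shell volume.
#' @export
makeLVStack <- function(model, nSlices = 10L, imageSize = c(96L, 96L),
                        pixelSpacing = c(1.4, 1.4), sliceThickness = 8,
                        nFrames = 30L, wallThicknessMm = NULL) {
  stopifnot(inherits(model, "VolumeModel"))
  rows <- imageSize[1L]; cols <- imageSize[2L]
  times <- (seq_len(nFrames) - 1L) * model$rr / nFrames
  vTrue <- model$volume(times)                       # mL
  if (any(vTrue <= 0)) stop("analytic V(t) must stay positive")
  dzCm <- sliceThickness / 10
  areaCm2 <- vTrue / (nSlices * dzCm)                # per-slice area
  radiusMm <- sqrt(areaCm2 / pi) * 10
  if (max(radiusMm) > (min(rows, cols) / 2 - 2) * min(pixelSpacing))
    stop("volume curve requires a radius larger than the field of view")
  rIdx <- seq_len(rows); cIdx <- seq_len(cols)
  # deterministic sub-pixel center offsets per slice (golden-ratio strides)
  # decorrelate the pixel-quantization error across slices, keeping the
  # slice-summed volume within the phantom's 2% contract at small radii
  phi <- (sqrt(5) - 1) / 2
  masks <- array(FALSE, dim = c(rows, cols, nSlices, nFrames))
  d2s <- lapply(seq_len(nSlices), function(s) {
    cr <- rows / 2 + 0.5 + ((s * phi) %% 1) - 0.5
    cc <- cols / 2 + 0.5 + ((s * phi^2) %% 1) - 0.5
    outer((rIdx - cr)^2 * pixelSpacing[1L]^2,
          (cIdx - cc)^2 * pixelSpacing[2L]^2, `+`)
  })
  for (k in seq_len(nFrames)) {
    for (s in seq_len(nSlices))
      masks[, , s, k] <- d2s[[s]] <= radiusMm[k]^2
  }
  truth <- list(vTrue = vTrue, pfr = model$pfr, edv = model$edv,
                esv = model$esv, times = times, model = model)
  out <- list(masks = masks,
              spacing = c(pixelSpacing, sliceThickness),
              times = times, truth = truth)
  if (!is.null(wallThicknessMm)) {
    rEpi <- radiusMm[1L] + wallThicknessMm
    epiMasks <- array(FALSE, dim = c(rows, cols, nSlices))
    for (s in seq_len(nSlices)) epiMasks[, , s] <- d2s[[s]] <= rEpi^2
    out$epiMasksED <- epiMasks
    out$truth$shellVolumeMl <-
      nSlices * dzCm * pi * ((rEpi / 10)^2 - (radiusMm[1L] / 10)^2)
  }
  out
}
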