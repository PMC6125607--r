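# Minimal explicit-VR little-endian DICOM writer used only to build test
# fixtures for the DICOM reading path (one frame per file, 16-bit pixels).

uint16le <- function(x) as.raw(c(x %% 256L, x %/% 256L))
uint32le <- function(x) as.raw(c(x %% 256L, (x %/% 256L) %% 256L,
                                 (x %/% 65536L) %% 256L,
                                 (x %/% 16777216L) %% 256L))

dicomElement <- function(group, elem, vr, value) {
  head <- c(uint16le(group), uint16le(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0L, 0L)), uint32le(length(value)), value)
  } else {
    c(head, uint16le(length(value)), value)
  }
}

dsValue <- function(x) {
  s <- paste(format(x, trim = TRUE), collapse = "\\")
  if (nchar(s) %% 2L == 1L) s <- paste0(s, " ")
  charToRaw(s)
}

writeDicomFrame <- function(path, pixels, triggerTimeMs,
                            pixelSpacing = c(1.4, 1.4)) {
  rows <- nrow(pixels); cols <- ncol(pixels)
  px <- as.integer(round(t(pixels)))     # DICOM order: row by row
  pxRaw <- writeBin(px, raw(), size = 2L, endian = "little")
  body <- c(
    dicomElement(0x0018, 0x1060, "DS", dsValue(triggerTimeMs)),
    dicomElement(0x0028, 0x0010, "US", uint16le(rows)),
    dicomElement(0x0028, 0x0011, "US", uint16le(cols)),
    dicomElement(0x0028, 0x0030, "DS", dsValue(pixelSpacing)),
    dicomElement(0x0028, 0x0100, "US", uint16le(16L)),
    dicomElement(0x0028, 0x0103, "US", uint16le(0L)),
    dicomElement(0x7FE0, 0x0010, "OW", pxRaw)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(rep(0L, 128L)), charToRaw("DICM"), body), con)
  invisible(path)
}

writeDicomSeries <- function(dir, frames, triggerTimesMs,
                             pixelSpacing = c(1.4, 1.4)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(dim(frames)[3L])) {
    writeDicomFrame(file.path(dir, sprintf("frame%03d.dcm", k)),
                    frames[, , k], triggerTimesMs[k], pixelSpacing)
  }
  invisible(dir)
}
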