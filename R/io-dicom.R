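# Minimal DICOM reader for cine ingestion: part-10 files, explicit-VR
# little-endian, uncompressed 16-bit pixel data, one frame per file.
# Only the tags the pipeline needs are interpreted (Rows, Columns,
# PixelSpacing, TriggerTime, BitsAllocated, PixelRepresentation,
# PixelData); everything else is skipped by length.  No installed R
# package reads DICOM, hence this narrow hand-written parser.

readUint16 <- function(raw, at) {
  as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
}

readUint32 <- function(raw, at) {
  sum(as.numeric(raw[at + 0:3]) * 256^(0:3))
}

parseDicomFile <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140L ||
      rawToChar(raw[129:132]) != "DICM")
    stop("format error: not a part-10 DICOM file: ", path)
  pos <- 133L
  longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  out <- list()
  while (pos + 8L <= length(raw)) {
    group <- readUint16(raw, pos); elem <- readUint16(raw, pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% longVRs) {
      len <- readUint32(raw, pos + 8L)
      valAt <- pos + 12L
    } else {
      len <- readUint16(raw, pos + 6L)
      valAt <- pos + 8L
    }
    if (valAt + len - 1L > length(raw))
      stop("integrity error: truncated DICOM element in ", path)
    val <- raw[valAt:(valAt + len - 1L)]
    key <- sprintf("%04x,%04x", group, elem)
    if (key == "0028,0010") out$rows <- readUint16(val, 1L)
    if (key == "0028,0011") out$cols <- readUint16(val, 1L)
    if (key == "0028,0100") out$bits <- readUint16(val, 1L)
    if (key == "0028,0103") out$pixelRep <- readUint16(val, 1L)
    if (key == "0028,0030")
      out$pixelSpacing <- as.numeric(strsplit(trimws(rawToChar(val)),
                                              "\\\\")[[1L]])
    if (key == "0018,1060") out$triggerTime <- as.numeric(trimws(rawToChar(val)))
    if (key == "7fe0,0010") {
      out$pixelRaw <- val
      break
    }
    pos <- valAt + len
  }
  need <- c("rows", "cols", "pixelRaw")
  if (!all(need %in% names(out)))
    stop("format error: missing required DICOM tags in ", path)
  if (!is.null(out$bits) && out$bits != 16L)
    stop("format error: only 16-bit DICOM pixel data is supported")
  signed <- isTRUE(out$pixelRep == 1L)
  px <- readBin(out$pixelRaw, "integer", n = out$rows * out$cols,
                size = 2L, signed = signed, endian = "little")
  if (!signed) px <- px %% 65536L
  # DICOM pixel order: row by row, left to right
  out$pixels <- t(matrix(px, nrow = out$cols, ncol = out$rows))
  out$pixelRaw <- NULL
  out
}

readCineDicom <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  if (!length(files)) stop("format error: no files in DICOM directory")
  parsed <- lapply(files, parseDicomFile)
  dims <- vapply(parsed, function(p) c(p$rows, p$cols), integer(2))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("integrity error: inconsistent frame shapes across DICOM files")
  tt <- vapply(parsed, function(p) p$triggerTime %||% NA_real_, numeric(1))
  if (anyNA(tt))
    stop("format error: TriggerTime missing from one or more DICOM frames")
  ord <- order(tt)
  frames <- array(0, dim = c(dims[1L, 1L], dims[2L, 1L], length(parsed)))
  for (k in seq_along(ord)) frames[, , k] <- parsed[[ord[k]]]$pixels
  spacingMm <- parsed[[1L]]$pixelSpacing %||% c(1, 1)
  CineSeries(frames, frameTimes = tt[ord] / 1000, pixelSpacing = spacingMm)
}
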