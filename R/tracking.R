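# Feature tracking of the mitral-annular insertion points through a
# four-chamber cine.  Sequential frame-to-frame normalized cross-correlation
# block matching: a square template around each point is matched against a
# bounded search window in the next frame, the correlation peak is refined
# to sub-pixel precision by a separable quadratic fit, and the template is
# resampled at the new position (template update).  Cardiac motion is
# cyclic, so the final-frame position is checked against the seed (drift).

# Extract a (2m+1)^2 patch centered at fractional (r, c) by bilinear
# resampling; NA when the patch would leave the image.
samplePatch <- function(img, r, c, m) {
  off <- seq(-m, m)
  rr <- rep(r + off, times = 2 * m + 1)
  cc <- rep(c + off, each = 2 * m + 1)
  if (min(rr) < 1 || max(rr) > nrow(img) || min(cc) < 1 || max(cc) > ncol(img))
    return(NULL)
  matrix(bilinearSample(img, rr, cc), 2 * m + 1, 2 * m + 1)
}

ncc <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb) * length(a) / (length(a) - 1)
}

# Sub-pixel offset of a correlation peak by independent quadratic fits
# along each axis of the 3x3 neighborhood; clamped to half a pixel.
quadraticRefine <- function(surface, peak) {
  refineAxis <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (!is.finite(den) || den >= 0) return(0)
    max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }
  nr <- nrow(surface); nc <- ncol(surface)
  dr <- dc <- 0
  if (peak[1L] > 1 && peak[1L] < nr)
    dr <- refineAxis(surface[peak[1L] - 1L, peak[2L]],
                     surface[peak[1L], peak[2L]],
                     surface[peak[1L] + 1L, peak[2L]])
  if (peak[2L] > 1 && peak[2L] < nc)
    dc <- refineAxis(surface[peak[1L], peak[2L] - 1L],
                     surface[peak[1L], peak[2L]],
                     surface[peak[1L], peak[2L] + 1L])
  c(dr, dc)
}

# Sub-pixel refinement by direct NCC evaluation at fractional shifts:
# coordinate descent with step halving from the integer peak (seeded by
# the quadratic estimate).  Evaluating the true correlation at bilinear
# fractional samples avoids the bias a fitted-surface model shows when the
# template itself carries interpolation blur.
refineSubpixel <- function(img, template, center, m, start = c(0, 0),
                           steps = c(0.5, 0.25, 0.125, 0.0625)) {
  scoreAt <- function(p) {
    cand <- samplePatch(img, p[1L], p[2L], m)
    if (is.null(cand)) -Inf else ncc(template, cand)
  }
  # begin from the better of the integer peak and the quadratic estimate;
  # the integer peak is exact when the scene has not moved sub-pixel
  pos <- center
  best <- scoreAt(pos)
  sQuad <- scoreAt(center + start)
  if (sQuad > best + 1e-12) {
    pos <- center + start
    best <- sQuad
  }
  for (step in steps) {
    repeat {
      moved <- FALSE
      for (d in list(c(step, 0), c(-step, 0), c(0, step), c(0, -step))) {
        p2 <- pos + d
        cand <- samplePatch(img, p2[1L], p2[2L], m)
        if (is.null(cand)) next
        s <- ncc(template, cand)
        if (s > best + 1e-12) {
          best <- s; pos <- p2; moved <- TRUE
        }
      }
      if (!moved) break
    }
  }
  list(pos = pos, score = best)
}

trackOnePoint <- function(stack, seed, templateHalf, searchRadius,
                          corrThreshold) {
  nf <- dim(stack)[3L]
  pos <- matrix(NA_real_, nf, 2L)
  pos[1L, ] <- seed
  flags <- character()
  # The template is always extracted on the integer pixel grid (at the
  # rounded position) so it never carries interpolation blur; the fractional
  # remainder of the estimated position is carried forward explicitly.
  # Resampling the template at fractional positions instead makes the
  # continuous correlation maximum creep a little every frame.
  anchor <- round(seed)
  fracOff <- seed - anchor
  template <- samplePatch(stack[, , 1L], anchor[1L], anchor[2L], templateHalf)
  if (is.null(template))
    stop("seed too close to the image border for the template size")
  for (k in 2:nf) {
    img <- stack[, , k]
    center <- anchor
    offs <- seq(-searchRadius, searchRadius)
    surface <- matrix(-Inf, length(offs), length(offs))
    for (i in seq_along(offs)) {
      for (j in seq_along(offs)) {
        cand <- samplePatch(img, center[1L] + offs[i], center[2L] + offs[j],
                            templateHalf)
        if (!is.null(cand)) surface[i, j] <- ncc(template, cand)
      }
    }
    peak <- which(surface == max(surface), arr.ind = TRUE)[1L, ]
    best <- c(center[1L] + offs[peak[1L]], center[2L] + offs[peak[2L]])
    ref <- refineSubpixel(img, template, best, templateHalf,
                          start = quadraticRefine(surface, peak))
    if (ref$score < corrThreshold)
      flags <- c(flags, sprintf("tracking failure at frame %d (ncc %.2f)",
                                k, ref$score))
    pos[k, ] <- ref$pos + fracOff
    anchor <- round(pos[k, ])
    fracOff <- pos[k, ] - anchor
    newTemplate <- samplePatch(img, anchor[1L], anchor[2L], templateHalf)
    if (!is.null(newTemplate)) template <- newTemplate else anchor <- center
  }
  list(pos = pos, flags = flags)
}

#' Track the septal and lateral annular points through a cine
#'
#' @param cine a \linkS4class{CineSeries} (four-chamber view, >= 10 frames).
#' @param seeds list with \code{septal} and \code{lateral}, each a
#'   (row, col) pixel position in frame 1.
#' @param templateSize odd template edge length, px.
#' @param searchRadius search half-width, px.
#' @param corrThreshold NCC below this flags a tracking failure.
#' @param driftTolerancePx final-frame distance from the seed beyond which a
#'   drift warning is raised (motion is cyclic, so the point must return).
#' @return an \linkS4class{AnnularTrace}; positions in mm.
#' @export
trackPoints <- function(cine, seeds, templateSize = 11L, searchRadius = 8L,
                        corrThreshold = 0.5, driftTolerancePx = 3) {
  stopifnot(is(cine, "CineSeries"))
  if (nFrames(cine) < 10L) stop("at least 10 frames are required")
  stack <- frames(cine)
  d <- dim(stack)
  for (nm in c("septal", "lateral")) {
    s <- seeds[[nm]]
    if (is.null(s) || length(s) != 2L)
      stop("seeds must contain septal and lateral (row, col) positions")
    if (s[1L] < 1 || s[1L] > d[1L] || s[2L] < 1 || s[2L] > d[2L])
      stop("seed outside image bounds: ", nm)
  }
  m <- (templateSize - 1L) %/% 2L
  flags <- character()
  tracks <- lapply(c("septal", "lateral"), function(nm) {
    tr <- trackOnePoint(stack, seeds[[nm]], m, searchRadius, corrThreshold)
    drift <- sqrt(sum((tr$pos[nrow(tr$pos), ] - tr$pos[1L, ])^2))
    if (drift > driftTolerancePx)
      tr$flags <- c(tr$flags,
                    sprintf("drift check: %s endpoint %.1f px from seed",
                            nm, drift))
    tr
  })
  flags <- c(tracks[[1L]]$flags, tracks[[2L]]$flags)
  sp <- pixelSpacing(cine)
  toMm <- function(p) cbind(row = (p[, 1L] - 1) * sp[1L],
                            col = (p[, 2L] - 1) * sp[2L])
  sepMm <- toMm(tracks[[1L]]$pos)
  latMm <- toMm(tracks[[2L]]$pos)
  new("AnnularTrace",
      septal = sepMm, lateral = latMm,
      planeNormal = annularPlaneNormal(sepMm, latMm),
      times = frameTimes(cine), flags = flags)
}

# Unit normal of the end-diastolic annular line (through the two frame-1
# points), oriented so that systolic annular descent projects negatively
# (apex-ward displacement is negative by convention).
annularPlaneNormal <- function(septalMm, lateralMm) {
  u <- lateralMm[1L, ] - septalMm[1L, ]
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) stop("coincident seed points: annular plane undefined")
  n <- c(-u[2L], u[1L]) / nu
  mid <- (septalMm + lateralMm) / 2
  early <- seq_len(max(2L, floor(nrow(mid) / 3)))
  proj <- (mid[early, 1L] - mid[1L, 1L]) * n[1L] +
    (mid[early, 2L] - mid[1L, 2L]) * n[2L]
  if (mean(proj) > 0) n <- -n
  unname(n)
}

#' Perpendicular annular displacement from the end-diastolic plane
#'
#' The annular plane is fixed as the line through the two frame-1 points;
#' displacement of each point at frame t is its signed distance from that
#' line along the plane normal (apex-ward negative, so the systolic descent
#' is negative and the diastolic return has positive velocity).  Frame-1
#' displacement is zero by construction.
#'
#' @param trace an \linkS4class{AnnularTrace}.
#' @return list with \code{times} (sec) and \code{septal}, \code{lateral}
#'   displacement vectors (mm).
#' @export
perpendicularDisplacement <- function(trace) {
  stopifnot(is(trace, "AnnularTrace"))
  n <- trace@planeNormal
  dispOf <- function(p) {
    (p[, 1L] - p[1L, 1L]) * n[1L] + (p[, 2L] - p[1L, 2L]) * n[2L]
  }
  list(times = trace@times,
       septal = unname(dispOf(trace@septal)),
       lateral = unname(dispOf(trace@lateral)))
}

#' Annular velocity from a displacement trace
#'
#' Fits the shared periodic smoothing spline to the displacement samples and
#' returns its analytic first derivative at the frame times, in cm/sec.
#'
#' @param times seconds (>= 10 samples over one cycle).
#' @param displacementMm displacement samples, mm.
#' @param spar optional smoothing parameter (see
#'   \code{\link{periodicSplineDerivative}}).
#' @param label curve label, "septal" or "lateral".
#' @return a \linkS4class{VelocityCurve} (cm/sec).
#' @export
displacementToVelocity <- function(times, displacementMm, spar = NULL,
                                   label = "septal") {
  eng <- periodicSplineDerivative(times, displacementMm, spar = spar)
  VelocityCurve(times, eng$deriv(times) / 10, label = label)
}

# Indices of local maxima of `v` that rise above frac*max as a prominence
# guard; returns integer(0) when the curve is monotone in the window.
# Runs of equal values are compressed first so a flat-topped lobe counts as
# one peak (at the start of its plateau), not one per plateau edge.
findLocalPeaks <- function(v, frac = 0.1) {
  n <- length(v)
  if (n < 3L) return(integer())
  keep <- c(TRUE, diff(v) != 0)
  idxMap <- which(keep)
  vc <- v[keep]
  if (length(vc) < 3L) return(integer())
  pk <- which(diff(sign(diff(vc))) < 0) + 1L
  out <- idxMap[pk]
  out[v[out] >= frac * max(v)]
}

#' Extract e' (and a') from an annular velocity curve
#'
#' Early diastole is the window from the time of peak annular excursion
#' (the displacement extremum, an end-systole surrogate) to the midpoint
#' between that time and cycle end.  e' is the magnitude of the earliest
#' velocity peak in that window; a later peak in the window is reported as
#' a'.  A window with no local maximum raises the "no e-wave detected" flag.
#'
#' @param vel a \linkS4class{VelocityCurve} spanning one cycle.
#' @param systoleEndHint end-systole time, sec; when NULL it must be
#'   supplied via \code{displacementMm}.
#' @param displacementMm displacement samples used to locate the excursion
#'   extremum when no hint is given.
#' @param prominence fraction of the window maximum below which peaks are
#'   ignored.
#' @return list \code{ePrime} (cm/sec, positive magnitude), \code{aPrime}
#'   (cm/sec or NA), \code{window} (sec), \code{flag} (character).
#' @export
extractEPrime <- function(vel, systoleEndHint = NULL, displacementMm = NULL,
                          prominence = 0.1) {
  stopifnot(is(vel, "VelocityCurve"))
  t <- curveTimes(vel); v <- curveValues(vel)
  period <- max(t) + stats::median(diff(t))
  if (is.null(systoleEndHint)) {
    if (is.null(displacementMm))
      stop("either systoleEndHint or displacementMm is required")
    systoleEndHint <- t[which.max(abs(displacementMm))]
  }
  wEnd <- (systoleEndHint + period) / 2
  inWin <- t >= systoleEndHint & t <= wEnd
  if (sum(inWin) < 3L)
    return(list(ePrime = NA_real_, aPrime = NA_real_,
                window = c(systoleEndHint, wEnd), flag = "no e-wave detected"))
  av <- abs(v[inWin])
  peaks <- findLocalPeaks(av, frac = prominence)
  if (!length(peaks))
    return(list(ePrime = NA_real_, aPrime = NA_real_,
                window = c(systoleEndHint, wEnd), flag = "no e-wave detected"))
  list(
    ePrime = av[peaks[1L]],
    aPrime = if (length(peaks) > 1L) av[peaks[length(peaks)]] else NA_real_,
    window = c(systoleEndHint, wEnd),
    flag = character()
  )
}
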