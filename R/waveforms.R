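# Flat-topped velocity lobes shared by all phantom generators.  A lobe
# rises from 0 to `peak` over a quintic-smoothstep ramp of length `ramp`,
# holds `peak` for `plateau`, and falls symmetrically.  The smoothstep ramp
# makes the velocity C2-continuous (so spline smoothing of the sampled
# trace neither rings nor overshoots the plateau), the flat top makes the
# peak exactly resolvable at cine frame rates, and the running integral
# (displacement / volume change) is available in closed form, so every
# phantom's ground truth is analytic.

smoothstep5 <- function(w) w^3 * (10 - 15 * w + 6 * w^2)
# integral of smoothstep5 from 0 to w
smoothstep5Int <- function(w) 2.5 * w^4 - 3 * w^5 + w^6

lobeVelocity <- function(t, peak, t0, ramp, plateau) {
  u <- t - t0
  v <- numeric(length(u))
  up <- u > 0 & u <= ramp
  v[up] <- peak * smoothstep5(u[up] / ramp)
  fl <- u > ramp & u <= ramp + plateau
  v[fl] <- peak
  dn <- u > ramp + plateau & u < 2 * ramp + plateau
  v[dn] <- peak * (1 - smoothstep5((u[dn] - ramp - plateau) / ramp))
  v
}

# Running integral of lobeVelocity from t0; total area = peak*(ramp+plateau).
lobeIntegral <- function(t, peak, t0, ramp, plateau) {
  u <- t - t0
  s <- numeric(length(u))
  up <- u > 0 & u <= ramp
  s[up] <- peak * ramp * smoothstep5Int(u[up] / ramp)
  fl <- u > ramp & u <= ramp + plateau
  s[fl] <- peak * ramp / 2 + peak * (u[fl] - ramp)
  dn <- u > ramp + plateau & u < 2 * ramp + plateau
  w <- (u[dn] - ramp - plateau) / ramp
  s[dn] <- peak * ramp / 2 + peak * plateau +
    peak * ramp * (w - smoothstep5Int(w))
  done <- u >= 2 * ramp + plateau
  s[done] <- peak * (ramp + plateau)
  s
}

lobeArea <- function(peak, ramp, plateau) peak * (ramp + plateau)

# Sum a list of lobes; each lobe is list(peak, t0, ramp, plateau).
lobesVelocity <- function(t, lobes) {
  Reduce(`+`, lapply(lobes, function(l) {
    lobeVelocity(t, l$peak, l$t0, l$ramp, l$plateau)
  }), init = numeric(length(t)))
}

lobesIntegral <- function(t, lobes) {
  Reduce(`+`, lapply(lobes, function(l) {
    lobeIntegral(t, l$peak, l$t0, l$ramp, l$plateau)
  }), init = numeric(length(t)))
}

# Canonical intracycle timing (fractions of RR).  Systolic descent occupies
# roughly the first systoleFraction of the cycle; the early lobe peaks in
# the first half of diastole and the atrial lobe just before the next
# R-wave, mirroring normal annular and transmitral waveforms.
waveTimings <- function(rr, systoleFraction = 0.35) {
  list(
    sys  = list(t0 = 0.01 * rr, ramp = 0.07 * rr,
                plateau = (systoleFraction - 0.02 - 0.14) * rr),
    early = list(t0 = (systoleFraction + 0.02) * rr, ramp = 0.08 * rr,
                 plateau = 0.12 * rr),
    late  = list(t0 = 0.76 * rr, ramp = 0.05 * rr, plateau = 0.07 * rr)
  )
}

#' Annular motion model with analytic ground truth
#'
#' Parameterizes the long-axis displacement of a mitral-annular point over
#' one cycle as a systolic descent followed by a biphasic diastolic return
#' built from cosine-tapered velocity lobes.  The early-diastolic velocity
#' peak equals \code{ePrime} and the late peak \code{aPrime} exactly; the
#' systolic excursion follows from cycle closure (total descent equals total
#' return), so the true e' is a closed-form parameter of the phantom.
#' Displacement is negative toward the apex (systolic descent), returning to
#' zero at the next R-wave.
#'
#' @param ePrime true early-diastolic annular velocity, cm/sec.
#' @param aPrime true late-diastolic (atrial) velocity, cm/sec; default half
#'   of \code{ePrime}.
#' @param rr RR interval, seconds.
#' @param systoleFraction fraction of the cycle occupied by systole.
#' @return an object of class \code{"MotionModel"}: the parameters plus
#'   \code{excursion} (mm), and functions \code{displacement(t)} (mm) and
#'   \code{velocity(t)} (cm/sec).
#' @export
motionModel <- function(ePrime, aPrime = ePrime / 2, rr = 1.0,
                        systoleFraction = 0.35) {
  stopifnot(ePrime >= 0, aPrime >= 0, rr > 0,
            systoleFraction > 0, systoleFraction < 1)
  tm <- waveTimings(rr, systoleFraction)
  areaE <- lobeArea(ePrime, tm$early$ramp, tm$early$plateau)   # cm
  areaA <- lobeArea(aPrime, tm$late$ramp,  tm$late$plateau)    # cm
  descent <- areaE + areaA                                      # cm
  sysWidth <- tm$sys$ramp + tm$sys$plateau
  vSys <- descent / sysWidth                                    # cm/sec
  lobes <- list(
    c(tm$sys,   peak = -vSys),
    c(tm$early, peak = ePrime),
    c(tm$late,  peak = aPrime)
  )
  structure(list(
    ePrime = ePrime, aPrime = aPrime, rr = rr,
    systoleFraction = systoleFraction,
    excursion = 10 * descent,                                   # mm
    peakSystolicVelocity = vSys,
    velocity = function(t) lobesVelocity(t %% rr, lobes),       # cm/sec
    displacement = function(t) 10 * lobesIntegral(t %% rr, lobes) # mm
  ), class = "MotionModel")
}

#' Transmitral flow model with analytic ground truth
#'
#' Biphasic transmitral inflow: an early (E) and an atrial (A) wave, each a
#' cosine-tapered lobe with an exactly known peak, directed at angle
#' \code{alpha} from the in-plane flow-encode axis.  The phase-contrast
#' phantom encodes the component speed * cos(alpha) plus a constant
#' background phase offset.
#'
#' @param E,A true peak inflow speeds, m/sec.
#' @param alpha angle between encode direction and inflow direction, degrees
#'   (0 <= alpha < 90).
#' @param phaseOffset constant background velocity offset, cm/sec.
#' @param venc velocity-encoding limit, cm/sec; must exceed the largest
#'   encoded component plus offset or the generator refuses.
#' @param rr RR interval, seconds.
#' @return an object of class \code{"FlowModel"} with a \code{speed(t)}
#'   function (cm/sec, along the inflow direction).
#' @export
flowModel <- function(E, A = 0.6 * E, alpha = 0, phaseOffset = 0,
                      venc = 200, rr = 1.0) {
  stopifnot(E >= 0, A >= 0, alpha >= 0, alpha < 90, venc > 0, rr > 0)
  tm <- waveTimings(rr)
  lobes <- list(
    c(tm$early, peak = 100 * E),   # cm/sec
    c(tm$late,  peak = 100 * A)
  )
  maxEncoded <- 100 * max(E, A) * cos(alpha * pi / 180) + abs(phaseOffset)
  if (maxEncoded >= venc)
    stop(sprintf(
      "venc = %.0f cm/s does not cover the encoded velocity range (%.0f cm/s)",
      venc, maxEncoded
    ))
  structure(list(
    E = E, A = A, alpha = alpha, phaseOffset = phaseOffset,
    venc = venc, rr = rr,
    speed = function(t) lobesVelocity(t %% rr, lobes)
  ), class = "FlowModel")
}

#' LV volume-curve model with analytic peak filling rate
#'
#' dV/dt over the cycle is an ejection lobe (negative) balanced by an early
#' filling lobe peaking exactly at \code{pfr} and an atrial lobe at
#' \code{pfrAtrial}; V(t) = EDV + running integral.  Stroke volume follows
#' from lobe closure.
#'
#' @param pfr true peak early-diastolic filling rate, mL/sec.
#' @param pfrAtrial atrial filling-rate peak, mL/sec.
#' @param edv end-diastolic volume, mL; default keeps EF physiologic across
#'   the supported pfr range.
#' @param rr RR interval, seconds.
#' @return class \code{"VolumeModel"} with \code{volume(t)} (mL),
#'   \code{dvdt(t)} (mL/sec), \code{sv}, \code{edv}, \code{esv}, \code{pfr}.
#' @export
volumeModel <- function(pfr, pfrAtrial = 0.4 * pfr, edv = NULL, rr = 1.0) {
  stopifnot(pfr >= 0, pfrAtrial >= 0, rr > 0)
  tm <- waveTimings(rr)
  areaE <- lobeArea(pfr,       tm$early$ramp, tm$early$plateau)
  areaA <- lobeArea(pfrAtrial, tm$late$ramp,  tm$late$plateau)
  sv <- areaE + areaA
  if (is.null(edv)) edv <- max(120, 1.6 * sv)
  if (edv <= sv) stop("edv must exceed the stroke volume implied by pfr")
  vEject <- sv / (tm$sys$ramp + tm$sys$plateau)
  lobes <- list(
    c(tm$sys,   peak = -vEject),
    c(tm$early, peak = pfr),
    c(tm$late,  peak = pfrAtrial)
  )
  structure(list(
    pfr = pfr, pfrAtrial = pfrAtrial, edv = edv, esv = edv - sv,
    sv = sv, rr = rr,
    dvdt = function(t) lobesVelocity(t %% rr, lobes),
    volume = function(t) edv + lobesIntegral(t %% rr, lobes)
  ), class = "VolumeModel")
}
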