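test_that("tracking a static cine stays at the seeds", {
  ph <- annulusFixture(ePrime = 0, aPrime = 0)
  seeds <- seedsFromTruth(ph)
  tr <- trackPoints(ph$cine, seeds)
  sp <- pixelSpacing(ph$cine)
  expect_lt(max(abs(tr@septal[, 1] / sp[1] + 1 - seeds$septal[1])), 0.05)
  expect_lt(max(abs(tr@lateral[, 1] / sp[1] + 1 - seeds$lateral[1])), 0.05)
  expect_length(tr@flags, 0)
})

test_that("rigid integer translation is recovered to sub-pixel precision", {
  # a textured patch translating by exactly 1 px per frame, noiseless
  tex <- DiastoleMRI:::makePatchTexture(10L, seed = 31L)
  nf <- 14L
  frames <- array(30, dim = c(64, 64, nf))
  for (k in seq_len(nf)) {
    r0 <- 15L + k
    frames[r0:(r0 + 20L), 20:40, k] <-
      frames[r0:(r0 + 20L), 20:40, k] + tex
  }
  cine <- CineSeries(frames, rr = 1, pixelSpacing = c(1, 1))
  tr <- trackPoints(cine, list(septal = c(26, 30), lateral = c(26, 40)),
                    driftTolerancePx = Inf)
  truthRows <- 26 + seq_len(nf) - 1
  errPx <- tr@septal[, 1] + 1 - truthRows
  expect_lt(sqrt(mean(errPx^2)), 0.2)
})

test_that("phantom tracks are recovered within half a pixel RMS", {
  ph <- annulusFixture(ePrime = 8, seed = 21L)
  tr <- trackPoints(ph$cine, seedsFromTruth(ph))
  sp <- pixelSpacing(ph$cine)
  errPx <- tr@septal[, 1] / sp[1] + 1 - ph$truth$septalPx[, 1]
  errPx <- errPx - errPx[1]
  expect_lt(sqrt(mean(errPx^2)), 0.5)
  expect_lt(abs(mean(errPx)), 0.3)
})

test_that("seed outside the image is a precondition error", {
  ph <- annulusFixture(ePrime = 6)
  expect_error(trackPoints(ph$cine, list(septal = c(-3, 10),
                                         lateral = c(50, 60))),
               "outside image bounds")
})

test_that("perpendicular displacement projects onto the fixed annular plane", {
  times <- (0:14) / 15
  # pure normal motion: both points move 12 mm along the plane normal
  base <- rbind(c(60, 30), c(60, 70))
  mk <- function(shiftRows, shiftCols = rep(0, length(shiftRows))) {
    sep <- cbind(base[1, 1] + shiftRows, base[1, 2] + shiftCols)
    lat <- cbind(base[2, 1] + shiftRows, base[2, 2] + shiftCols)
    new("AnnularTrace", septal = sep, lateral = lat,
        planeNormal = DiastoleMRI:::annularPlaneNormal(sep, lat),
        times = times, flags = character())
  }
  shift <- c(0, -seq(2, 12, length.out = 7), -seq(12, 1, length.out = 7))
  tr <- mk(shift)
  disp <- perpendicularDisplacement(tr)
  expect_equal(min(disp$septal), -12, tolerance = 1e-9)
  expect_equal(disp$septal[1], 0)
  expect_equal(disp$septal, disp$lateral)
  # motion purely along the annular line produces zero displacement
  trPar <- mk(rep(0, 15), c(0, seq(1, 13, length.out = 14)))
  dPar <- perpendicularDisplacement(trPar)
  expect_equal(max(abs(dPar$septal)), 0)
  # coincident seeds leave the plane undefined
  sep <- matrix(rep(c(60, 30), each = 15), ncol = 2)
  expect_error(DiastoleMRI:::annularPlaneNormal(sep, sep), "coincident")
})

test_that("tracked phantom displacement matches generator truth", {
  ph <- annulusFixture(ePrime = 10, seed = 5L)
  tr <- trackPoints(ph$cine, seedsFromTruth(ph))
  disp <- perpendicularDisplacement(tr)
  rms <- sqrt(mean((disp$septal - ph$truth$displacementMm)^2))
  expect_lt(rms, 0.3)
})

test_that("spline differentiation handles linear and constant traces", {
  times <- (0:29) * 0.036
  # 1 mm per 36 ms frame is ~2.78 cm/s; interior frames see the constant slope
  vel <- displacementToVelocity(times, times / 0.036)
  mid <- curveValues(vel)[8:22]
  expect_equal(mid, rep(1 / 0.036 / 10, 15), tolerance = 0.05)
  flat <- displacementToVelocity(times, rep(3.2, 30))
  expect_lt(max(abs(curveValues(flat))), 1e-8)
})

test_that("smoothing derivative of a sinusoid returns amplitude x omega", {
  times <- (0:29) / 30
  eng <- periodicSplineDerivative(times, 3 * sin(2 * pi * times), period = 1)
  expect_equal(max(eng$deriv(seq(0, 1, by = 1e-3))), 3 * 2 * pi,
               tolerance = 0.02)
})

test_that("e' extraction picks the early peak and reports a' separately", {
  ph <- annulusFixture(ePrime = 10, aPrime = 5, seed = 9L)
  res <- ePrimeFromCine(ph)
  expect_equal(res$ePrime, 10, tolerance = 0.05)
  expect_false(isTRUE(all.equal(res$ePrime, 5, tolerance = 0.2)))
  # AF-like phantom without atrial kick still yields e'
  phAf <- annulusFixture(ePrime = 8, aPrime = 0, seed = 10L)
  resAf <- ePrimeFromCine(phAf)
  expect_equal(resAf$ePrime, 8, tolerance = 0.05)
})

test_that("monotone diastolic velocity raises the no-e-wave flag", {
  times <- (0:29) / 30
  vel <- VelocityCurve(times, seq(0, 3, length.out = 30), label = "septal")
  res <- extractEPrime(vel, systoleEndHint = 0.4)
  expect_identical(res$flag, "no e-wave detected")
  expect_true(is.na(res$ePrime))
})
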