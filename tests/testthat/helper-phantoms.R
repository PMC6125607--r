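# Shared fixture builders: small, seeded phantoms used across test files.

annulusFixture <- function(ePrime = 10, aPrime = ePrime / 2, seed = 1L,
                           noiseSd = 0) {
  makeAnnulusCine(motionModel(ePrime, aPrime), textureSeed = seed,
                  noiseSd = noiseSd)
}

seedsFromTruth <- function(ph) {
  list(septal = round(ph$truth$septalPx[1L, ]),
       lateral = round(ph$truth$lateralPx[1L, ]))
}

ePrimeFromCine <- function(ph, point = "septal", spar = NULL) {
  tr <- trackPoints(ph$cine, seedsFromTruth(ph))
  disp <- perpendicularDisplacement(tr)
  vel <- displacementToVelocity(disp$times, disp[[point]], spar = spar,
                                label = point)
  extractEPrime(vel, displacementMm = disp[[point]])
}

# uniform-velocity PC series: every voxel at `vel` cm/s plus offset
uniformPCSeries <- function(vel = 80, offset = 0, venc = 200,
                            nFrames = 12L, size = 48L) {
  arr <- array((vel + offset) / venc * pi, dim = c(size, size, nFrames))
  mag <- CineSeries(array(100, dim = c(size, size, nFrames)), rr = 1,
                    pixelSpacing = c(1.9, 1.9), viewLabel = "three_chamber")
  PCSeries(mag, arr, venc = venc)
}
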