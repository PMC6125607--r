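test_that("slice summation reproduces simple closed-form volumes", {
  # single slice, constant 100-pixel mask at 1.4 x 1.4 mm, 8 mm thickness
  masks <- array(FALSE, dim = c(20, 20, 1, 3))
  masks[1:10, 1:10, 1, ] <- TRUE
  cv <- sliceSummation(masks, c(1.4, 1.4, 8), times = c(0, 0.3, 0.6))
  expect_equal(cv@volumes, rep(100 * 1.4 * 1.4 * 8 / 1000, 3))
  expect_equal(cv@ef, 0)           # rigid phantom: EDV = ESV
  # cylinder phantom within 2% of pi r^2 h
  st <- makeLVStack(volumeModel(300))
  cvc <- sliceSummation(st$masks, st$spacing, st$times)
  expect_lt(max(abs(cvc@volumes - st$truth$vTrue) / st$truth$vTrue), 0.02)
  expect_equal(cvc@ef, 100 * (cvc@edv - cvc@esv) / cvc@edv)
})

test_that("slice summation is additive under mask splitting", {
  masks <- array(FALSE, dim = c(16, 16, 2, 2))
  masks[4:12, 4:12, 1, ] <- TRUE
  whole <- sliceSummation(masks, c(1, 1, 5), c(0, 0.5))
  split <- array(FALSE, dim = c(16, 16, 3, 2))
  split[4:12, 4:7, 1, ] <- TRUE     # left half in one slice
  split[4:12, 8:12, 2, ] <- TRUE    # right half in another
  halves <- sliceSummation(split, c(1, 1, 5), c(0, 0.5))
  expect_equal(halves@volumes, whole@volumes)
})

test_that("LV mass uses the 1.05 g/mL myocardial density", {
  endo <- array(FALSE, dim = c(10, 10, 2))
  epi <- endo
  epi[2:9, 2:9, ] <- TRUE
  endo[4:7, 4:7, ] <- TRUE
  # volumes in mL with 10 mm cubic voxels: epi 128 mL, endo 32 mL
  expect_equal(lvMass(endo, epi, c(10, 10, 10)), (128 - 32) * 1.05)
  expect_equal(lvMass(epi, epi, c(10, 10, 10)), 0)
  bad <- endo; bad[1, 1, 1] <- TRUE
  expect_error(lvMass(bad, epi, c(10, 10, 10)), "outside")
  # concentric-shell phantom within 3% of the analytic shell volume
  st <- makeLVStack(volumeModel(350), wallThicknessMm = 9)
  edF <- which.max(st$truth$vTrue)
  m <- lvMass(st$masks[, , , edF], st$epiMasksED, st$spacing)
  expect_lt(abs(m - st$truth$shellVolumeMl * 1.05) /
              (st$truth$shellVolumeMl * 1.05), 0.03)
})

test_that("peak filling rate recovers the analytic early-diastolic dV/dt", {
  st <- makeLVStack(volumeModel(400))
  cv <- sliceSummation(st$masks, st$spacing, st$times)
  pf <- peakFillingRate(cv)
  expect_equal(pf$pfr, 400, tolerance = 0.05)
  expect_length(pf$flag, 0)
})

test_that("a filling-free curve is flagged with zero PFR", {
  cv <- new("VolumeTimeCurve", times = (0:19) / 20, volumes = rep(120, 20),
            edv = 120, esv = 120, ef = 0, mass = NULL)
  pf <- peakFillingRate(cv)
  expect_equal(pf$pfr, 0)
  expect_match(pf$flag, "no early-diastolic filling")
})

test_that("a steep linear refill reads out as its slope", {
  # sawtooth V(t): 50 mL rise over 0.125 s is 400 mL/s
  t <- (0:29) / 30
  v <- numeric(30)
  v[1:12] <- seq(150, 100, length.out = 12)
  v[13:16] <- seq(100, 150, length.out = 4)   # rise 50 mL over 4 frames
  v[17:30] <- 150
  cv <- new("VolumeTimeCurve", times = t, volumes = v, edv = 150, esv = 100,
            ef = 100 * 50 / 150, mass = NULL)
  pf <- peakFillingRate(cv)
  expect_equal(pf$pfr, 400, tolerance = 0.15)
})
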