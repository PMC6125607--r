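test_that("phase offset is recovered from stationary tissue", {
  ph <- makePCPhantom(flowModel(1.0, alpha = 30, phaseOffset = 5, venc = 200))
  est <- estimatePhaseOffset(ph$pc, ph$truth$stationaryMask)
  expect_lt(abs(est$offset - 5), 0.2)
  expect_length(est$flag, 0)
  ph0 <- makePCPhantom(flowModel(1.0, alpha = 30, phaseOffset = 0, venc = 200))
  expect_lt(abs(estimatePhaseOffset(ph0$pc, ph0$truth$stationaryMask)$offset),
            0.2)
  expect_error(estimatePhaseOffset(ph$pc, ph$truth$stationaryMask & FALSE),
               "empty")
})

test_that("a mask over the moving jet is flagged as misuse", {
  ph <- makePCPhantom(flowModel(1.0, alpha = 0, venc = 200))
  d <- dim(phaseData(ph$pc))
  jetMask <- matrix(FALSE, d[1], d[2])
  cp <- round(ph$truth$jetCenterPx)
  jetMask[(cp[1] - 3):(cp[1] + 3), (cp[2] - 3):(cp[2] + 3)] <- TRUE
  est <- estimatePhaseOffset(ph$pc, jetMask)
  expect_match(est$flag, "biased")
})

test_that("ROI Vmax picks the largest-magnitude signed velocity", {
  pc <- uniformPCSeries(vel = 80)
  vm <- roiVmaxCurve(pc, center = c(24, 24))
  expect_equal(curveValues(vm), rep(80, 12), tolerance = 1e-9)
  # 10 cm^2 at 1.9 mm pixels: radius ~ 17.8 mm ~ 9.4 px
  expect_equal(sqrt(10 * 100 / pi), 17.8412, tolerance = 1e-4)
  expect_error(roiVmaxCurve(pc, center = c(3, 24)), "outside")
})

test_that("angle correction modes satisfy the projection identities", {
  vm <- VelocityCurve((0:11) / 12, c(0, 10, 30, 50, 30, 10, 0, 5, 20, 5, 0, 0))
  expect_equal(curveValues(angleCorrect(vm, 0)), curveValues(vm))
  expect_equal(curveValues(angleCorrect(vm, 0, mode = "as_printed")),
               curveValues(vm))
  v60 <- angleCorrect(vm, 60)
  expect_equal(max(curveValues(v60)), 100, tolerance = 1e-12)
  # consistency identity: v_printed = v_true cos^2(alpha)
  for (al in c(15, 46, 70)) {
    vTrue <- curveValues(angleCorrect(vm, al))
    vPrinted <- curveValues(angleCorrect(vm, al, mode = "as_printed"))
    expect_equal(vPrinted, vTrue * cos(al * pi / 180)^2, tolerance = 1e-14)
  }
  expect_error(angleCorrect(vm, 90), "undefined")
})

test_that("noiseless uniform fields are corrected exactly", {
  # offset + angle pipeline recovers the analytic value to < 0.1%
  pc <- uniformPCSeries(vel = 60 * cos(46 * pi / 180), offset = 4)
  stat <- matrix(TRUE, 48, 48)
  off <- estimatePhaseOffset(pc, stat)$offset - 60 * cos(46 * pi / 180)
  vm <- roiVmaxCurve(pc, center = c(24, 24), offset = off)
  vc <- angleCorrect(vm, 46)
  expect_lt(max(abs(curveValues(vc) - 60)) / 60, 0.001)
})

test_that("E and A peaks are detected with their ratio", {
  fm <- flowModel(1.0, 0.6, alpha = 46, phaseOffset = 3, venc = 250)
  ph <- makePCPhantom(fm)
  off <- estimatePhaseOffset(ph$pc, ph$truth$stationaryMask)$offset
  vm <- roiVmaxCurve(ph$pc, ph$truth$jetCenterPx, offset = off)
  vc <- angleCorrect(vm, 46)
  ea <- detectEA(vc)
  expect_equal(ea$E, 1.0, tolerance = 0.03)
  expect_equal(ea$A, 0.6, tolerance = 0.03)
  expect_equal(ea$EoverA, 1 / 0.6, tolerance = 0.05)
})

test_that("a missing atrial wave leaves A and E/A missing", {
  ph <- makePCPhantom(flowModel(1.1, A = 0, alpha = 20, venc = 200))
  vm <- roiVmaxCurve(ph$pc, ph$truth$jetCenterPx)
  ea <- detectEA(angleCorrect(vm, 20))
  expect_equal(ea$E, 1.1, tolerance = 0.03)
  expect_true(is.na(ea$A))
  expect_true(is.na(ea$EoverA))
})

test_that("two equal peaks give E = A and unit ratio", {
  ph <- makePCPhantom(flowModel(0.8, A = 0.8, alpha = 0, venc = 200))
  ea <- detectEA(roiVmaxCurve(ph$pc, ph$truth$jetCenterPx))
  expect_equal(ea$E, 0.8, tolerance = 0.02)
  expect_equal(ea$A, 0.8, tolerance = 0.02)
  expect_equal(ea$EoverA, 1, tolerance = 0.02)
})

test_that("E/e' follows the cm/s-consistent arithmetic", {
  expect_equal(eOverEprime(1.0, 10, 10), 10)
  expect_equal(eOverEprime(0.8, 6, 10), 10)
  expect_error(eOverEprime(0.8, 0, 10), "positive")
})
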