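test_that("annular motion model has the prescribed analytic velocity peaks", {
  m <- motionModel(10, aPrime = 5, rr = 1.0)
  tf <- seq(0, 1, by = 1e-4)
  v <- m$velocity(tf)
  # early-diastolic peak is exactly e', late peak exactly a'
  expect_equal(max(v[tf > 0.35 & tf < 0.7]), 10, tolerance = 1e-12)
  expect_equal(max(v[tf > 0.7]), 5, tolerance = 1e-12)
  # cycle closure: displacement returns to zero
  expect_equal(m$displacement(0), 0)
  expect_lt(abs(m$displacement(0.999999)), 1e-6)
  # peak descent equals the closed-form excursion
  expect_equal(-min(m$displacement(tf)), m$excursion, tolerance = 1e-6)
})

test_that("finite difference of truth tracks recovers e' within 2%", {
  ph <- annulusFixture(ePrime = 8)
  d <- ph$truth$displacementMm
  t <- ph$truth$times
  fd <- diff(d) / diff(t) / 10                 # cm/s between frames
  expect_lt(abs(max(fd) - 8) / 8, 0.02)
})

test_that("degenerate zero-motion model renders a static cine", {
  ph <- annulusFixture(ePrime = 0, aPrime = 0)
  expect_equal(ph$truth$displacementMm, rep(0, 30))
  expect_equal(frames(ph$cine)[, , 1], frames(ph$cine)[, , 15])
})

test_that("temporal undersampling is refused", {
  m <- motionModel(40, rr = 1.0)   # per-frame motion beyond half the search radius
  expect_error(makeAnnulusCine(m), "temporal undersampling")
})

test_that("phantom generators are deterministic given the seed", {
  a <- annulusFixture(ePrime = 9, seed = 7L, noiseSd = 5)
  b <- annulusFixture(ePrime = 9, seed = 7L, noiseSd = 5)
  expect_identical(frames(a$cine), frames(b$cine))
  g1 <- makeLALGEPhantom(0.3, noiseSd = 15, seed = 4L)
  g2 <- makeLALGEPhantom(0.3, noiseSd = 15, seed = 4L)
  expect_identical(voxels(g1$lge), voxels(g2$lge))
})

test_that("PC phantom encodes the projected component plus offset", {
  # alpha = 0: no projection
  ph0 <- makePCPhantom(flowModel(1.0, alpha = 0, venc = 200))
  v0 <- phaseToVelocity(ph0$pc)
  expect_equal(max(v0), 100, tolerance = 1e-9)
  # alpha = 60: cos 60 = 1/2
  ph60 <- makePCPhantom(flowModel(1.0, alpha = 60, venc = 200))
  expect_equal(max(phaseToVelocity(ph60$pc)), 50, tolerance = 1e-9)
  # stationary region carries exactly the offset
  ph <- makePCPhantom(flowModel(1.0, alpha = 30, phaseOffset = 5, venc = 200))
  v <- phaseToVelocity(ph$pc)
  statVals <- apply(v, 3, function(fr) fr[ph$truth$stationaryMask])
  expect_equal(unique(round(as.vector(statVals), 9)), 5)
})

test_that("flow generator refuses a VENC below the encoded range", {
  expect_error(flowModel(2.0, alpha = 0, venc = 150), "venc")
})

test_that("LV stack volume matches the analytic curve within 2%", {
  st <- makeLVStack(volumeModel(400))
  vox <- sliceSummation(st$masks, st$spacing, st$times)
  relErr <- abs(vox@volumes - st$truth$vTrue) / st$truth$vTrue
  expect_lt(max(relErr), 0.02)
})

test_that("constant-volume phantom has zero true filling rate", {
  vm <- volumeModel(0, pfrAtrial = 0)
  expect_equal(vm$sv, 0)
  tt <- (0:29) / 30
  expect_equal(vm$volume(tt), rep(vm$edv, 30))
})

test_that("LGE phantom discretizes the enhancement fraction faithfully", {
  z <- makeLALGEPhantom(0)
  expect_equal(z$truth$nEnhanced, 0)
  q <- makeLALGEPhantom(0.25)
  expect_equal(q$truth$nEnhanced / q$truth$nWall, 0.25,
               tolerance = 1 / q$truth$nWall * 2)
  expect_equal(q$truth$lgeSqrtPct, 5, tolerance = 0.01)
  expect_error(makeLALGEPhantom(0.2, wallThicknessMm = 1.0),
               "unresolvable")
})

test_that("implied cohort correlation matches large-n simulation", {
  m <- cohortModel(nSubjects = 10000L, seed = 11L)
  expect_equal(impliedCorrelation(m, "lge_sqrt_pct", "pcwp"), 0.8,
               tolerance = 0.001)
  tab <- simulateCohort(m)
  emp <- cor(tab$lge_sqrt_pct, tab$pcwp)
  expect_lt(abs(emp - 0.8), 0.02)
  # independence limit: negligible slopes against huge noise
  m0 <- cohortModel(nSubjects = 500L, loadings = list(
    x = c(0, 0.01, 10), y = c(0, 0.01, 10)), seed = 3L)
  t0 <- simulateCohort(m0)
  expect_lt(abs(cor(t0$x, t0$y)), 0.15)
  # perfect collinearity: identical loadings, zero noise
  m1 <- cohortModel(nSubjects = 50L, loadings = list(
    x = c(1, 2, 0), y = c(1, 2, 0)), seed = 5L)
  t1 <- simulateCohort(m1)
  expect_equal(cor(t1$x, t1$y), 1)
})

test_that("degenerate cohort models are refused", {
  expect_error(cohortModel(loadings = list(x = c(0, 0, 0), y = c(0, 0, 0))),
               "degenerate")
  expect_error(cohortModel(nSubjects = 2L), "nSubjects")
})
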