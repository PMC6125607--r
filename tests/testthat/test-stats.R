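bruteForcePearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

test_that("Pearson matches the brute-force covariance computation", {
  set.seed(14)
  for (i in 1:10) {
    x <- rnorm(50); y <- 0.4 * x + rnorm(50)
    pb <- pearsonBand(x, y)
    expect_equal(pb$r, bruteForcePearson(x, y), tolerance = 1e-12)
  }
  # exact linear relation
  x <- 1:20
  pb <- pearsonBand(x, 2 * x + 1)
  expect_equal(pb$r, 1)
  expect_identical(pb$band, "very strong")
  # orthogonalized pair
  x <- rnorm(100)
  y <- residuals(lm(rnorm(100) ~ x))
  expect_lt(abs(pearsonBand(x, y)$r), 1e-10)
  expect_error(pearsonBand(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("strength-band boundaries are assigned to the upper band", {
  mkxy <- function(r) {
    # construct an exact sample correlation r
    n <- 400
    x <- scale(rnorm(n))[, 1]
    e <- scale(residuals(lm(rnorm(n) ~ x)))[, 1]
    list(x = x, y = r * x + sqrt(1 - r^2) * e)
  }
  set.seed(5)
  for (r in c(0.3, 0.5, 0.7, 0.9)) {
    d <- mkxy(r)
    pb <- pearsonBand(d$x, d$y)
    expect_equal(pb$r, r, tolerance = 1e-10)
  }
  bandOf <- function(r) { d <- mkxy(r); pearsonBand(d$x, d$y)$band }
  expect_identical(bandOf(0.3), "weak")
  expect_identical(bandOf(0.5), "moderate")
  expect_identical(bandOf(0.7), "strong")
  expect_identical(bandOf(0.9), "very strong")
  expect_identical(bandOf(0.29), "negligible")
})

test_that("Bland-Altman bias and limits follow the differences", {
  a <- c(10, 12, 14, 16)
  ba0 <- blandAltman(a, a)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$sdDiff, 0)
  ba2 <- blandAltman(a, a + 2)
  expect_equal(ba2$bias, -2)
  expect_equal(ba2$sdDiff, 0)
  expect_equal(ba2$loaLow, -2)
  expect_error(blandAltman(1:4, 1:5), "equal length")
  # independent unit noise on both arms: sd of differences ~ sqrt(2)
  set.seed(31)
  truth <- rnorm(1000, 50, 5)
  ba <- blandAltman(truth + rnorm(1000), truth + rnorm(1000))
  expect_lt(abs(ba$sdDiff - sqrt(2)) / sqrt(2), 0.05)
})

test_that("Bland-Altman limits contain about 95% of differences", {
  set.seed(8)
  truth <- rnorm(10000, 0, 3)
  ba <- blandAltman(truth + rnorm(10000), truth + rnorm(10000))
  inside <- mean(ba$diffs >= ba$loaLow & ba$diffs <= ba$loaHigh)
  expect_gt(inside, 0.93)
  expect_lt(inside, 0.97)
})

test_that("ICC(2,1) recovers variance-components ground truth", {
  # identical columns: perfect agreement
  m <- cbind(1:10, 1:10)
  expect_equal(icc(m)$icc, 1)
  # no subject variance: ICC ~ 0
  set.seed(12)
  m0 <- cbind(rnorm(200), rnorm(200))
  expect_lt(abs(icc(m0)$icc), 0.1)
  # subject SD 2, rater noise SD 1 -> ICC = 4 / 5
  set.seed(13)
  subj <- rnorm(500, 0, 2)
  m2 <- cbind(subj + rnorm(500), subj + rnorm(500))
  res <- icc(m2)
  expect_lt(abs(res$icc - 0.8), 0.05)
  expect_match(res$modelLabel, "absolute agreement")
  expect_error(icc(cbind(c(1, 2, NA), c(1, 2, 3))), "incomplete")
})

test_that("ICC estimator is consistent at large n", {
  set.seed(17)
  subj <- rnorm(2000, 0, 2)
  m <- cbind(subj + rnorm(2000), subj + rnorm(2000), subj + rnorm(2000))
  expect_lt(abs(icc(m)$icc - 0.8), 0.02)
})

test_that("study-table grid handles diagonals, missingness and small n", {
  m <- cohortModel(nSubjects = 500L, seed = 19L)
  tab <- simulateCohort(m)
  tab$pcwp[sample.int(500, 30)] <- NA    # pairwise-complete handling
  pairs <- data.frame(
    a = c("lge_sqrt_pct", "lge_sqrt_pct", "e_prime"),
    b = c("pcwp", "lge_sqrt_pct", "pcwp")
  )
  grid <- runStudyTables(tab, pairs)
  expect_equal(grid$n[1], sum(is.finite(tab$pcwp)))
  expect_lt(abs(grid$r[1] - 0.8), 0.05)
  expect_identical(grid$band[1], "strong")
  expect_true(grid$significant[1])
  expect_equal(grid$r[2], 1)            # variable against itself
  # all-missing overlap is unavailable
  tab2 <- tab
  tab2$pcwp <- NA_real_
  grid2 <- runStudyTables(tab2, pairs[1, , drop = FALSE])
  expect_true(is.na(grid2$r))
  expect_equal(grid2$n, 0)
  expect_error(runStudyTables(tab, data.frame(a = "nope", b = "pcwp")),
               "not in cohort")
})
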