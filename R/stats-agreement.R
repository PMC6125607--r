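# Agreement and correlation statistics for method-validation studies:
# Pearson correlation with conventional strength bands, Bland-Altman
# limits of agreement, two-way random-effects intraclass correlation, and
# a pairwise correlation grid over a cohort table.

correlationBands <- c("negligible", "weak", "moderate", "strong",
                      "very strong")

#' Pearson correlation with a strength band
#'
#' Sample Pearson r with the two-sided p-value from the t distribution on
#' n - 2 degrees of freedom.  The strength band follows the conventional
#' absolute-r intervals 0-0.3 negligible, 0.3-0.5 weak, 0.5-0.7 moderate,
#' 0.7-0.9 strong, 0.9-1.0 very strong; shared endpoints are assigned to
#' the upper band (|r| = 0.3 is "weak", 0.7 is "strong").
#'
#' @param x,y paired numeric vectors (n >= 3, finite, non-constant).
#' @return list \code{r}, \code{p}, \code{band}, \code{n}.
#' @export
pearsonBand <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("at least 3 complete pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, p = ct$p.value, band = correlationBand(r), n = n)
}

# Band assignment for |r|; shared endpoints go to the upper band.  The
# small tolerance keeps a floating-point |r| sitting at a printed boundary
# (0.3, 0.5, ...) in the band the convention assigns it to.
correlationBand <- function(r) {
  correlationBands[
    findInterval(abs(r) + 1e-12, c(0.3, 0.5, 0.7, 0.9)) + 1L
  ]
}

#' Bland-Altman agreement between two methods
#'
#' Differences a - b: bias is their mean, and the limits of agreement are
#' bias +/- 1.96 times their sample SD.
#'
#' @param a,b paired measurements.
#' @return object of class \code{"blandAltman"}: \code{bias},
#'   \code{sdDiff}, \code{loaLow}, \code{loaHigh}, \code{means},
#'   \code{diffs}, \code{n}.
#' @export
blandAltman <- function(a, b) {
  if (length(a) != length(b)) stop("paired inputs must have equal length")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) stop("at least 3 complete pairs are required")
  d <- a - b
  bias <- mean(d)
  sdDiff <- stats::sd(d)
  structure(list(
    bias = bias, sdDiff = sdDiff,
    loaLow = bias - 1.96 * sdDiff, loaHigh = bias + 1.96 * sdDiff,
    means = (a + b) / 2, diffs = d, n = length(d)
  ), class = "blandAltman")
}

#' Bland-Altman plot
#'
#' Differences against pair means with the bias (dashed) and the limits of
#' agreement (solid).
#'
#' @param x a \code{\link{blandAltman}} result.
#' @param ... passed to \code{plot}.
#' @export
plot.blandAltman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, xlab = "Mean of methods",
                 ylab = "Difference (a - b)", ...)
  graphics::abline(h = x$bias, lty = 2)
  graphics::abline(h = c(x$loaLow, x$loaHigh), lty = 1)
  invisible(x)
}

#' Intraclass correlation (two-way random, absolute agreement, single
#' measure)
#'
#' ICC(2,1) from the two-way ANOVA mean squares (between subjects, between
#' raters, residual): (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n).
#' The matrix must be complete; no imputation is performed.
#'
#' @param ratings numeric matrix, subjects x raters (>= 3 x >= 2).
#' @return list \code{icc}, \code{modelLabel}, \code{nSubjects},
#'   \code{nRaters}.
#' @export
icc <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3L || k < 2L) stop("at least 3 subjects and 2 raters are required")
  if (anyNA(ratings)) stop("incomplete ratings matrix: no imputation")
  df <- data.frame(
    y = as.vector(ratings),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1L]][, "Mean Sq"]
  msr <- ms[1L]; msc <- ms[2L]; mse <- ms[3L]
  val <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(icc = unname(val),
       modelLabel = "two-way random effects, absolute agreement, single measure (ICC(2,1))",
       nSubjects = n, nRaters = k)
}

#' Pairwise correlation grid over a cohort table
#'
#' For every requested variable pair, the Pearson correlation over
#' pairwise-complete observations with its n, p-value, band, and a
#' significance mark at p < 0.05.  Pairs with fewer than 3 complete
#' observations are marked unavailable (NA).
#'
#' @param cohort data.frame of per-subject parameters.
#' @param pairs data.frame with columns \code{a} and \code{b} naming
#'   cohort columns.
#' @return data.frame: a, b, n, r, p, band, significant.
#' @export
runStudyTables <- function(cohort, pairs) {
  stopifnot(all(c("a", "b") %in% names(pairs)))
  missing <- setdiff(unique(c(pairs$a, pairs$b)), names(cohort))
  if (length(missing))
    stop("columns not in cohort: ", paste(missing, collapse = ", "))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$a[i]; b <- pairs$b[i]
    x <- cohort[[a]]; y <- cohort[[b]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L)
      return(data.frame(a = a, b = b, n = sum(ok), r = NA_real_,
                        p = NA_real_, band = NA_character_,
                        significant = NA, stringsAsFactors = FALSE))
    if (identical(a, b)) {
      return(data.frame(a = a, b = b, n = sum(ok), r = 1, p = 0,
                        band = "very strong", significant = TRUE,
                        stringsAsFactors = FALSE))
    }
    pb <- pearsonBand(x[ok], y[ok])
    data.frame(a = a, b = b, n = pb$n, r = pb$r, p = pb$p, band = pb$band,
               significant = pb$p < 0.05, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
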