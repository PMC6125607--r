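# Cohort simulator: a single latent "diastolic severity" factor drives all
# observables through linear loadings plus independent Gaussian noise, so
# every pairwise population correlation is available in closed form and can
# be dialed to the structure observed in clinical cohorts (e.g. a strong
# positive fibrosis-wedge-pressure correlation, a weak negative
# fibrosis-e' correlation).

#' Latent-factor cohort model
#'
#' Each observable o is generated as
#' \code{intercept_o + slope_o * z + N(0, noiseSd_o)} with a shared latent
#' severity \code{z ~ N(0, latentSd)}.  The implied population Pearson
#' correlation between observables i and j is
#' \code{slope_i slope_j latentSd^2 / sqrt((slope_i^2 latentSd^2 + s_i^2)
#' (slope_j^2 latentSd^2 + s_j^2))}.
#'
#' The default loadings emulate a mixed clinical diastolic cohort: atrial
#' fibrosis burden (sqrt-percent scale, marginal mean 8.7, SD 10), wedge
#' pressure (mean 15 mmHg, SD 6) with an implied fibrosis-pressure
#' correlation of 0.80, a mildly negatively loaded annular e' (mean
#' 9 cm/sec, SD 3), and a positively loaded E/e' (mean 10, SD 4).
#'
#' @param nSubjects number of subjects (>= 3).
#' @param latentSd SD of the latent severity factor.
#' @param loadings named list; each element is \code{c(intercept, slope,
#'   noiseSd)} for one observable.
#' @param seed RNG seed.
#' @return an object of class \code{"CohortModel"}.
#' @export
cohortModel <- function(nSubjects = 20L, latentSd = 1,
                        loadings = list(
                          lge_sqrt_pct  = c(intercept = 8.7, slope = 8.944,
                                            noiseSd = 4.472),
                          pcwp          = c(intercept = 15, slope = 5.367,
                                            noiseSd = 2.683),
                          e_prime       = c(intercept = 9, slope = -1.5,
                                            noiseSd = 2.598),
                          E_over_eprime = c(intercept = 10, slope = 2.4,
                                            noiseSd = 3.2)
                        ),
                        seed = 1L) {
  stopifnot(nSubjects >= 3L, latentSd > 0)
  for (nm in names(loadings)) {
    l <- loadings[[nm]]
    if (length(l) != 3L) stop("each loading needs (intercept, slope, noiseSd)")
    if (l[[3L]] < 0) stop("noiseSd must be non-negative")
  }
  slopes <- vapply(loadings, function(l) l[[2L]], numeric(1))
  noises <- vapply(loadings, function(l) l[[3L]], numeric(1))
  if (all(slopes == 0) && all(noises == 0))
    stop("degenerate model: all slopes and noise SDs are zero")
  structure(list(nSubjects = as.integer(nSubjects), latentSd = latentSd,
                 loadings = loadings, seed = as.integer(seed)),
            class = "CohortModel")
}

#' Closed-form implied correlation between two observables
#'
#' @param model a \code{\link{cohortModel}}.
#' @param a,b observable names present in the model loadings.
#' @return the population Pearson correlation implied by the loadings.
#' @export
impliedCorrelation <- function(model, a, b) {
  stopifnot(inherits(model, "CohortModel"))
  la <- model$loadings[[a]]; lb <- model$loadings[[b]]
  if (is.null(la) || is.null(lb)) stop("unknown observable name")
  v <- model$latentSd^2
  num <- la[[2L]] * lb[[2L]] * v
  den <- sqrt((la[[2L]]^2 * v + la[[3L]]^2) * (lb[[2L]]^2 * v + lb[[3L]]^2))
  if (den == 0) stop("degenerate observable with zero variance")
  num / den
}

#' Simulate a cohort table from a latent-factor model
#'
#' @param model a \code{\link{cohortModel}}.
#' @return data.frame with column \code{id} plus one column per observable;
#'   attribute \code{"truth"} holds the latent draws and the full implied
#'   correlation matrix.
#' @export
simulateCohort <- function(model) {
  stopifnot(inherits(model, "CohortModel"))
  set.seed(model$seed)
  n <- model$nSubjects
  z <- stats::rnorm(n, 0, model$latentSd)
  obs <- lapply(model$loadings, function(l) {
    l[[1L]] + l[[2L]] * z + stats::rnorm(n, 0, l[[3L]])
  })
  tab <- data.frame(id = sprintf("S%03d", seq_len(n)), obs,
                    stringsAsFactors = FALSE)
  nms <- names(model$loadings)
  implied <- diag(length(nms))
  dimnames(implied) <- list(nms, nms)
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (i != j) implied[i, j] <- impliedCorrelation(model, nms[i], nms[j])
  }
  attr(tab, "truth") <- list(latent = z, impliedR = implied)
  tab
}
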