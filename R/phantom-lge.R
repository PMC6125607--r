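# 3D LA LGE phantom: an ellipsoidal blood pool, a wall shell of given
# physical thickness (built with the same physical-ball dilation rule the
# analysis stage uses, so the wall definition is shared geometry, not
# leaked truth), and a contiguous enhanced cap covering a prescribed
# fraction of the wall volume.  Intensities are bimodal with optional
# Gaussian noise; exact enhanced- and wall-voxel counts are returned.

#' LA LGE phantom with known fibrosis fraction
#'
#' @param enhancementFraction fraction of wall voxels enhanced, in [0, 1].
#' @param semiAxesMm ellipsoid semi-axes of the blood pool (x, y, z), mm.
#' @param wallThicknessMm wall thickness, mm; must be at least the largest
#'   voxel dimension.
#' @param spacing voxel spacing (x, y, z), mm; default the interpolated 3D
#'   LGE resolution 0.7 x 0.7 x 1.5.
#' @param intensities named vector: \code{background}, \code{blood},
#'   \code{wall}, \code{enhanced} mean intensities.
#' @param noiseSd additive Gaussian intensity noise SD.
#' @param seed RNG seed (noise only; geometry is deterministic).
#' @return list with \code{lge} (an \linkS4class{LGEVolume}) and
#'   \code{truth}: wall and enhanced voxel counts, the exact enhanced
#'   fraction after discretization, its percent and square-root-percent,
#'   and the wall mask used.
#' @export
makeLALGEPhantom <- function(enhancementFraction,
                             semiAxesMm = c(28, 24, 20),
                             wallThicknessMm = 2.1,
                             spacing = c(0.7, 0.7, 1.5),
                             intensities = c(background = 50, blood = 120,
                                             wall = 100, enhanced = 300),
                             noiseSd = 0, seed = 1L) {
  stopifnot(enhancementFraction >= 0, enhancementFraction <= 1)
  if (wallThicknessMm < max(spacing))
    stop("wall thickness below the voxel size: shell unresolvable")
  margin <- wallThicknessMm + 3
  dims <- ceiling((2 * (semiAxesMm + margin)) / spacing)
  ax <- (seq_len(dims[1L]) - (dims[1L] + 1) / 2) * spacing[1L]
  ay <- (seq_len(dims[2L]) - (dims[2L] + 1) / 2) * spacing[2L]
  az <- (seq_len(dims[3L]) - (dims[3L] + 1) / 2) * spacing[3L]
  q <- outer(outer((ax / semiAxesMm[1L])^2, (ay / semiAxesMm[2L])^2, `+`),
             (az / semiAxesMm[3L])^2, `+`)
  endo <- q <= 1
  wall <- dilatePhysicalBall(endo, spacing, wallThicknessMm) & !endo
  nWall <- sum(wall)
  # contiguous cap: wall voxels ranked by angular proximity to +x
  idx <- which(wall, arr.ind = TRUE)
  px <- ax[idx[, 1L]]; py <- ay[idx[, 2L]]; pz <- az[idx[, 3L]]
  cosang <- px / sqrt(px^2 + py^2 + pz^2)
  nEnh <- round(enhancementFraction * nWall)
  enhanced <- array(FALSE, dims)
  if (nEnh > 0L) {
    sel <- order(cosang, decreasing = TRUE)[seq_len(nEnh)]
    enhanced[idx[sel, , drop = FALSE]] <- TRUE
  }
  vox <- array(intensities[["background"]], dims)
  vox[endo] <- intensities[["blood"]]
  vox[wall] <- intensities[["wall"]]
  vox[enhanced] <- intensities[["enhanced"]]
  if (noiseSd > 0) {
    set.seed(seed)
    vox <- vox + array(stats::rnorm(prod(dims), 0, noiseSd), dims)
  }
  lge <- LGEVolume(vox, spacing = spacing, endoMask = endo)
  fracExact <- nEnh / nWall
  truth <- list(
    nWall = nWall, nEnhanced = nEnh,
    enhancedFraction = fracExact,
    lgePct = 100 * fracExact,
    lgeSqrtPct = sqrt(100 * fracExact),
    wallMask = wall,
    semiAxesMm = semiAxesMm,
    wallThicknessMm = wallThicknessMm
  )
  list(lge = lge, truth = truth)
}
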