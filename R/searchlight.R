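# Cubic searchlight enumeration and the within/between-image representational
# stability analysis with subsampled nulls.

#' Enumerate cubic searchlights over a mask
#'
#' One searchlight per in-mask voxel: the cube of half-width `halfWidth`
#' around the center (7x7x7 at the default), clipped at the grid borders and
#' intersected with the mask.
#'
#' @param mask logical 3D array (nonempty).
#' @param halfWidth cube half-width in voxels (default 3).
#' @return List of searchlights, each `list(center = c(x, y, z),
#'   centerId = <linear index>, voxelIds = <linear indices>)`.
#' @export
enumerateSearchlights <- function(mask, halfWidth = 3L) {
  if (!any(mask)) stop("empty mask")
  d <- dim(mask)
  centers <- which(mask)
  coords <- arrayInd(centers, d)
  lapply(seq_along(centers), function(i) {
    cc <- coords[i, ]
    xs <- max(1L, cc[1] - halfWidth):min(d[1], cc[1] + halfWidth)
    ys <- max(1L, cc[2] - halfWidth):min(d[2], cc[2] + halfWidth)
    zs <- max(1L, cc[3] - halfWidth):min(d[3], cc[3] + halfWidth)
    g <- expand.grid(x = xs, y = ys, z = zs)
    lin <- g$x + (g$y - 1L) * d[1] + (g$z - 1L) * (d[1] * d[2])
    list(center = cc, centerId = centers[i], voxelIds = lin[mask[lin]])
  })
}

#' Searchlight RSM
#'
#' Correlates per-image beta vectors restricted to the searchlight's voxels.
#'
#' @param betas a [BetaMaps-class].
#' @param sl one searchlight from [enumerateSearchlights()], or an integer
#'   vector of in-mask column indices.
#' @return A [LayerRSM-class] over images.
#' @export
searchlightRSM <- function(betas, sl) {
  cols <- .slColumns(betas, sl)
  if (length(cols) < 2L) stop("searchlight has fewer than 2 voxels")
  computeRSM(betaValues(betas)[, cols, drop = FALSE], layerId = "searchlight")
}

# Map a searchlight's grid voxel ids to column indices of a BetaMaps matrix.
.slColumns <- function(betas, sl) {
  if (is.list(sl)) {
    inMask <- which(maskArray(betas))
    match(sl$voxelIds, inMask)
  } else {
    as.integer(sl)
  }
}

#' Within/between pairing counts
#'
#' Within-image pairings: every unordered run pair for every image,
#' `C(n_runs, 2) * n_images`. Between-image pairings: ordered image pairs
#' across unordered run pairs, `C(n_runs, 2) * n_images * (n_images - 1)`.
#'
#' @param nImages number of images (>= 2).
#' @param nRuns number of runs (>= 2).
#' @return Named numeric vector `c(within = ..., between = ...)`.
#' @export
countPairings <- function(nImages, nRuns) {
  stopifnot(nImages >= 2, nRuns >= 2)
  rp <- choose(nRuns, 2)
  c(within = rp * nImages, between = rp * nImages * (nImages - 1))
}

# Pools of within- and between-image cross-run correlations for one
# searchlight: for every unordered run pair, the full image-by-image
# cross-correlation matrix contributes its diagonal to the within pool and
# both off-diagonal triangles (ordered image pairs) to the between pool.
.similarityPools <- function(runBetas, cols) {
  R <- length(runBetas)
  if (R < 2L) stop("need at least 2 runs")
  pats <- lapply(runBetas, function(b)
    t(betaValues(b)[, cols, drop = FALSE]))   # voxels x images
  if (any(vapply(pats, function(p) any(apply(p, 2, stats::sd) == 0),
                 logical(1))))
    stop("degenerate input: constant beta vector in a searchlight")
  within <- c(); between <- c()
  for (r in 1:(R - 1)) for (s in (r + 1):R) {
    C <- stats::cor(pats[[r]], pats[[s]])
    within <- c(within, diag(C))
    between <- c(between, C[row(C) != col(C)])
  }
  # canonical (sorted) pool order makes the subsampled null invariant to
  # image relabeling and run order
  list(within = within, between = sort(between))
}

#' Representational stability z-score for one searchlight
#'
#' The within-image similarity (mean correlation over all same-image cross-run
#' pairs) is z-scored against a null distribution formed by repeatedly
#' subsampling, without replacement, as many between-image correlations as
#' there are within-image pairings and averaging them.
#'
#' @param runBetas list of [BetaMaps-class], one per run (>= 2 runs).
#' @param sl searchlight (see [searchlightRSM()]); default: all voxels.
#' @param nResamples number of subsampled null means (default 5000).
#' @param seed integer seed for the subsampling.
#' @return Scalar z-score.
#' @export
stabilityZ <- function(runBetas, sl = NULL, nResamples = 5000L, seed = 1L) {
  cols <- if (is.null(sl)) seq_len(ncol(betaValues(runBetas[[1]])))
          else .slColumns(runBetas[[1]], sl)
  pools <- .similarityPools(runBetas, cols)
  k <- length(pools$within)
  withinMean <- mean(pools$within)
  nullMeans <- withSeed(seed,
    vapply(seq_len(nResamples), function(i)
      mean(sample(pools$between, k)), numeric(1)))
  nullSd <- stats::sd(nullMeans)
  if (nullSd == 0) stop("degenerate null: zero spread of subsampled means")
  (withinMean - mean(nullMeans)) / nullSd
}

#' Whole-mask representational stability map
#'
#' Applies [stabilityZ()] at every searchlight center. Per-center seeds are
#' derived from the master seed with a counter, so maps are reproducible
#' regardless of evaluation order. Centers whose searchlight is degenerate
#' (fewer than 2 voxels, or a degenerate null) are recorded as `NA`.
#'
#' @param runBetas list of [BetaMaps-class], one per run.
#' @param mask optional analysis mask (default: the beta maps' mask).
#' @param halfWidth searchlight half-width (default 3).
#' @param nResamples subsampled null size per center.
#' @param seed master seed.
#' @return A [StatMap-class] of z-scores.
#' @export
stabilityMap <- function(runBetas, mask = NULL, halfWidth = 3L,
                         nResamples = 5000L, seed = 1L) {
  mask <- mask %||% maskArray(runBetas[[1]])
  sls <- enumerateSearchlights(mask, halfWidth)
  inMaskBeta <- which(maskArray(runBetas[[1]]))
  vals <- vapply(seq_along(sls), function(i) {
    cols <- match(sls[[i]]$voxelIds, inMaskBeta)
    cols <- cols[!is.na(cols)]
    if (length(cols) < 2L) return(NA_real_)
    tryCatch(stabilityZ(runBetas, cols, nResamples,
                        seed = deriveSeed(seed, i)),
             error = function(e) NA_real_)
  }, numeric(1))
  new("StatMap", values = vals, mask = mask, statisticName = "stability_z")
}
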