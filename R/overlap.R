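# Layer-overlap statistics: asymmetric significant-voxel sharing ratios and
# bootstrap comparison of mean overlap across image sets.

#' Directed overlap ratio of two significant-voxel sets
#'
#' `|M intersect N| / |M|`: the proportion of the base map M shared with N.
#' Undefined (NA) when the base map is empty — never silently 0.
#'
#' @param mapM base-map voxel indices.
#' @param mapN comparison-map voxel indices.
#' @return Scalar in `[0, 1]`, or `NA` if `mapM` is empty.
#' @export
overlapRatio <- function(mapM, mapN) {
  if (length(mapM) == 0L) return(NA_real_)
  length(intersect(mapM, mapN)) / length(unique(mapM))
}

#' Layer-by-layer overlap matrix
#'
#' All ordered pairs of layers' significant-voxel sets. Rows for layers with
#' no significant voxels are undefined and excluded from summary means.
#'
#' @param sigMaps named list (per layer) of significant voxel index vectors.
#' @return An [OverlapMatrix-class].
#' @export
overlapMatrix <- function(sigMaps) {
  L <- length(sigMaps)
  if (L < 2L) stop("need at least 2 layers")
  ids <- names(sigMaps) %||% paste0("layer", seq_len(L))
  v <- matrix(NA_real_, L, L)
  for (i in seq_len(L)) for (j in seq_len(L))
    v[i, j] <- overlapRatio(sigMaps[[i]], sigMaps[[j]])
  new("OverlapMatrix", values = v, layerIds = ids)
}

#' Mean overlap over a band of the matrix
#'
#' Mean of the defined entries of either all off-diagonal elements or only
#' the adjacent-layer band (one off the diagonal, above and below).
#'
#' @param mat an [OverlapMatrix-class] or square matrix.
#' @param mode `"all_offdiag"` or `"adjacent"`.
#' @return Scalar mean, or `NA` if no entry in the band is defined.
#' @export
meanOverlap <- function(mat, mode = c("all_offdiag", "adjacent")) {
  mode <- match.arg(mode)
  m <- if (is(mat, "OverlapMatrix")) mat@values else as.matrix(mat)
  sel <- if (mode == "all_offdiag") row(m) != col(m)
         else abs(row(m) - col(m)) == 1
  vals <- m[sel]
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Bootstrap comparison of an observed mean overlap
#'
#' Resamples the per-image-set mean overlaps with replacement, takes the
#' grand mean of each resample, and locates the observed mean in that
#' distribution. The default tail tests whether the observed overlap is
#' *lower* than the comparison distribution; the add-one estimator keeps the
#' p-value strictly positive.
#'
#' @param observedMean observed mean overlap (scalar).
#' @param perSetMeans per-image-set mean overlaps (e.g. 16 values).
#' @param nBoot bootstrap resamples (default 5000).
#' @param seed integer seed.
#' @param alternative `"less"` (default) or `"two.sided"`.
#' @return List: `p`, `distribution` (the bootstrap grand means), `nBoot`,
#'   `seed`.
#' @export
bootstrapCompare <- function(observedMean, perSetMeans, nBoot = 5000L,
                             seed = 1L, alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!length(perSetMeans)) stop("perSetMeans must be nonempty")
  k <- length(perSetMeans)
  boots <- withSeed(seed, vapply(seq_len(nBoot), function(i)
    mean(sample(perSetMeans, k, replace = TRUE)), numeric(1)))
  pLess <- (1 + sum(boots <= observedMean)) / (1 + nBoot)
  p <- if (alternative == "less") pLess else {
    pGreater <- (1 + sum(boots >= observedMean)) / (1 + nBoot)
    min(1, 2 * min(pLess, pGreater))
  }
  list(p = p, distribution = boots, nBoot = nBoot, seed = seed)
}
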