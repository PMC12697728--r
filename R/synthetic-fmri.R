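# Synthetic fMRI: seeded beta maps (and raw BOLD) in which designated voxel
# regions carry the representational geometry of designated model layers, so
# every searchlight analysis can be tested against known ground truth.

#' Embed a target RSM into voxel patterns
#'
#' Draws voxel columns i.i.d. from a zero-mean multivariate normal across
#' images with covariance equal to the target correlation matrix, so the
#' expected image-by-image correlation matrix of the returned patterns equals
#' the target.
#'
#' @param target a [LayerRSM-class] or positive semidefinite correlation
#'   matrix.
#' @param nVoxels number of voxel columns (>= 1).
#' @param seed integer seed.
#' @return `n_images x nVoxels` pattern matrix.
#' @export
embedRSM <- function(target, nVoxels, seed = 1L) {
  m <- if (is(target, "LayerRSM")) target@values else as.matrix(target)
  m <- (m + t(m)) / 2
  eg <- eigen(m, symmetric = TRUE)
  if (min(eg$values) < -1e-8)
    stop("target matrix is not positive semidefinite (min eigenvalue ",
         format(min(eg$values)), ")")
  lam <- pmax(eg$values, 0)
  half <- eg$vectors %*% (sqrt(lam) * t(eg$vectors))
  n <- nrow(m)
  withSeed(seed, half %*% matrix(stats::rnorm(n * nVoxels), n, nVoxels))
}

#' Random layer RSMs from independent unit patterns
#'
#' Convenience generator of `L` layer RSMs computed from independent Gaussian
#' activation patterns; with many units their upper triangles are nearly
#' mutually decorrelated.
#'
#' @param L number of layers.
#' @param nImages images per RSM.
#' @param nUnits units per simulated pattern.
#' @param seed integer seed.
#' @return Named list of [LayerRSM-class] objects (`layer01, ...`).
#' @export
randomLayerRSMs <- function(L, nImages = 16L, nUnits = 200L, seed = 1L) {
  ids <- sprintf("layer%02d", seq_len(L))
  out <- withSeed(seed, lapply(seq_len(L), function(l)
    computeRSM(matrix(stats::rnorm(nImages * nUnits), nImages, nUnits),
               ids[l])))
  names(out) <- ids
  out
}

#' Mutually orthogonalized layer RSMs
#'
#' Builds `L` correlation matrices whose upper-triangle vectors are exactly
#' mutually orthogonal after centering (Gram-Schmidt on random triangles),
#' shrunk toward the identity until positive semidefinite. These emulate the
#' geometry of a successfully orthogonalized synthesized image set and are
#' the standard ground-truth input of the recovery simulations.
#'
#' @param L number of layers.
#' @param nImages images per RSM.
#' @param amplitude target maximum absolute off-diagonal entry (default 0.4).
#' @param seed integer seed.
#' @return Named list of [LayerRSM-class] objects.
#' @export
orthogonalLayerRSMs <- function(L, nImages = 16L, amplitude = 0.4, seed = 1L) {
  m <- nImages * (nImages - 1) / 2
  if (L >= m) stop("too many layers for the triangle dimension")
  V <- withSeed(seed, matrix(stats::rnorm(m * L), m, L))
  V <- scale(V, center = TRUE, scale = FALSE)
  # Gram-Schmidt across layers: triangles become exactly orthogonal (columns
  # are mean-centered, so zero dot product = zero correlation)
  for (k in seq_len(L)) {
    if (k > 1) {
      prev <- V[, 1:(k - 1), drop = FALSE]
      V[, k] <- V[, k] - prev %*% crossprod(prev, V[, k])
    }
    V[, k] <- V[, k] / sqrt(sum(V[, k]^2))
  }
  ids <- sprintf("layer%02d", seq_len(L))
  out <- lapply(seq_len(L), function(k) {
    v <- V[, k] * amplitude / max(abs(V[, k]))
    R <- fromUpperTriangle(v, nImages)
    # shrink toward identity until PSD
    for (a in seq(1, 0.05, by = -0.05)) {
      Ra <- a * R + (1 - a) * diag(nImages)
      diag(Ra) <- 1
      if (min(eigen(Ra, symmetric = TRUE, only.values = TRUE)$values) >= 0)
        return(layerRSM(Ra, ids[k]))
    }
    stop("could not reach a positive semidefinite matrix")
  })
  names(out) <- ids
  out
}

#' Simulate beta maps with known regional layer geometry
#'
#' For each region in the ground-truth layout, a group-level voxel pattern carrying the
#' region's source-layer RSM is drawn once ([embedRSM()]); each participant
#' receives that pattern plus Gaussian jitter (`participantSd`), shared across
#' their runs; each run adds i.i.d. noise (`noiseSd`). Non-region voxels are
#' pure noise.
#'
#' @param spec a [GroundTruthSpec-class].
#' @param layerRsms named list of [LayerRSM-class] covering every region's
#'   `layerId`.
#' @param imageIds optional image labels.
#' @return List with `betamaps` (participants, each a list of
#'   [BetaMaps-class] per run) and `groundTruth` (regions, seed).
#' @export
simulateBetaMaps <- function(spec, layerRsms, imageIds = NULL) {
  stopifnot(is(spec, "GroundTruthSpec"))
  regLayers <- vapply(spec@regions, `[[`, character(1), "layerId")
  missing <- setdiff(regLayers, names(layerRsms))
  if (length(missing))
    stop("layer(s) missing from layerRsms: ", paste(missing, collapse = ", "))
  nImg <- if (length(spec@regions)) nImages(layerRsms[[regLayers[1]]]) else
    nImages(layerRsms[[1]])
  if (is.null(imageIds)) imageIds <- sprintf("img%02d", seq_len(nImg))
  grid <- spec@gridShape
  nVox <- prod(grid)
  mask <- array(TRUE, dim = grid)

  groupPatterns <- lapply(seq_along(spec@regions), function(r) {
    reg <- spec@regions[[r]]
    embedRSM(layerRsms[[reg$layerId]], length(reg$voxels),
             seed = deriveSeed(spec@seed, r))
  })

  participants <- vector("list", spec@nParticipants)
  names(participants) <- sprintf("sub%02d", seq_len(spec@nParticipants))
  for (p in seq_len(spec@nParticipants)) {
    partPatterns <- lapply(seq_along(spec@regions), function(r) {
      jit <- withSeed(deriveSeed(spec@seed, 1000L + p * 100L + r),
                      matrix(stats::rnorm(length(groupPatterns[[r]])),
                             nrow(groupPatterns[[r]])))
      groupPatterns[[r]] + spec@participantSd * jit
    })
    runs <- vector("list", spec@nRuns)
    names(runs) <- sprintf("run%d", seq_len(spec@nRuns))
    for (rn in seq_len(spec@nRuns)) {
      vals <- withSeed(deriveSeed(spec@seed, 2000000L + p * 1000L + rn),
                       matrix(stats::rnorm(nImg * nVox, sd = spec@noiseSd),
                              nImg, nVox))
      for (r in seq_along(spec@regions)) {
        reg <- spec@regions[[r]]
        vals[, reg$voxels] <- vals[, reg$voxels] +
          reg$signalScale * partPatterns[[r]]
      }
      runs[[rn]] <- betaMaps(vals, mask = mask, imageIds = imageIds,
                             runId = sprintf("run%d", rn))
    }
    participants[[p]] <- runs
  }
  list(betamaps = participants,
       groundTruth = list(regions = spec@regions, seed = spec@seed,
                          gridShape = grid))
}

#' Simulate a BOLD time series from known betas
#'
#' `bold = design %*% betas + noise`; optional AR(1) temporal structure.
#' Feeding the result through [fitGLM()] recovers the betas (exactly, at zero
#' noise).
#'
#' @param betas `n_images x n_voxels` true coefficient matrix.
#' @param trialSeq a [TrialSequence-class].
#' @param trS repetition time in seconds.
#' @param nVolumes volumes (default from [buildDesign()]).
#' @param noiseSd Gaussian noise SD (default 0).
#' @param ar1 AR(1) coefficient applied to the noise (default 0).
#' @param seed integer seed.
#' @param imageIds regressor order; default `rownames`-style `img01, ...`.
#' @return List with `bold` (`n_volumes x n_voxels`) and the
#'   [DesignMatrix-class] used.
#' @export
simulateBOLD <- function(betas, trialSeq, trS = 1.5, nVolumes = NULL,
                         noiseSd = 0, ar1 = 0, seed = 1L, imageIds = NULL) {
  if (is.null(imageIds)) imageIds <- sprintf("img%02d", seq_len(nrow(betas)))
  design <- buildDesign(trialSeq, trS = trS, nVolumes = nVolumes,
                        imageIds = imageIds)
  Y <- as.matrix(design) %*% betas
  if (noiseSd > 0) {
    eps <- withSeed(seed, matrix(stats::rnorm(length(Y), sd = noiseSd),
                                 nrow(Y)))
    if (ar1 != 0)
      eps <- apply(eps, 2, function(e)
        as.numeric(stats::filter(e, ar1, method = "recursive")))
    Y <- Y + eps
  }
  list(bold = Y, design = design)
}
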